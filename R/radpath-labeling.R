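# TP/FP/FN lesion labeling under configurable MRI-positive and
# pathology-positive criteria, with per-sector weights.

#' Positivity criterion pair
#'
#' A lesion is MRI-positive when its PI-RADS score is at least
#' `min_pirads`, and pathology-positive when its ISUP grade group is at
#' least `min_isup`. Common pairs: (3, 1) for all prostate cancer, (3, 2)
#' or (4, 2) for clinically significant cancer.
#'
#' @param min_pirads Integer in 3..5.
#' @param min_isup Integer in 1..5.
#' @return List of class `criterion`.
#' @export
criterion <- function(min_pirads = 3L, min_isup = 1L) {
  min_pirads <- as.integer(min_pirads); min_isup <- as.integer(min_isup)
  if (is.na(min_pirads) || min_pirads < 3L || min_pirads > 5L)
    stop("min_pirads must be in 3..5")
  if (is.na(min_isup) || min_isup < 1L || min_isup > 5L)
    stop("min_isup must be in 1..5")
  structure(list(min_pirads = min_pirads, min_isup = min_isup),
            class = "criterion")
}

#' Label lesions TP/FP/FN under a criterion
#'
#' Deterministic truth table: MRI-positive and pathology-positive is a true
#' positive (TP); MRI-positive only is a false positive (FP); pathology-
#' positive only is a false negative (FN); a lesion below both criteria is
#' EXCLUDED and never enters any count (its sector weight is zero).
#'
#' @param lesions `data.frame` with at least `pirads`, `isup`, `sectors`
#'   columns (as produced by [generate_lesions()]).
#' @param crit A [criterion()].
#' @return The input with added columns `label` (factor TP/FP/FN/EXCLUDED)
#'   and `n_sectors`; each non-excluded lesion contributes weight
#'   `1/n_sectors` to each of its sectors.
#' @export
label_lesions <- function(lesions, crit = criterion()) {
  stopifnot(inherits(crit, "criterion"),
            all(c("pirads", "isup", "sectors") %in% names(lesions)))
  if (any(lesions$pirads == 0 & lesions$isup == 0))
    stop("lesions must be MRI-positive and/or pathology-positive")
  mri_pos <- lesions$pirads >= crit$min_pirads
  path_pos <- lesions$isup >= crit$min_isup
  label <- ifelse(mri_pos & path_pos, "TP",
                  ifelse(mri_pos, "FP", ifelse(path_pos, "FN", "EXCLUDED")))
  out <- lesions
  out$label <- factor(label, levels = c("TP", "FP", "FN", "EXCLUDED"))
  ns <- lengths(split_sectors(lesions$sectors))
  if (any(ns == 0L)) stop("every lesion needs a non-empty sector set")
  out$n_sectors <- ns
  out
}

#' Per-sector weights of a lesion
#'
#' Each sector a lesion spans receives weight `1/n_sectors`, so the lesion's
#' total weight is exactly 1 and per-sector tallies are normalized by the
#' number of sectors the lesion is distributed on.
#'
#' @param sectors A ';'-separated sector string or character vector of ids.
#' @return Named numeric vector of weights summing to 1.
#' @export
sector_weights <- function(sectors) {
  if (length(sectors) == 1L && is.character(sectors) && grepl(";", sectors))
    sectors <- split_sectors(sectors)[[1L]]
  sectors <- as.character(sectors)
  if (length(sectors) == 0L || any(!nzchar(sectors)))
    stop("empty sector set")
  stats::setNames(rep(1 / length(sectors), length(sectors)), sectors)
}

# long (lesion x sector) weight table for labeled lesions; EXCLUDED lesions
# carry zero weight
sector_weight_table <- function(labeled) {
  stopifnot("label" %in% names(labeled))
  secs <- split_sectors(labeled$sectors)
  ns <- lengths(secs)
  idx <- rep(seq_len(nrow(labeled)), ns)
  data.frame(
    lesion_id = labeled$lesion_id[idx],
    label = labeled$label[idx],
    sector = unlist(secs, use.names = FALSE),
    weight = ifelse(labeled$label[idx] == "EXCLUDED", 0, 1 / ns[idx]),
    stringsAsFactors = FALSE)
}
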