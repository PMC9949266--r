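# Zone-stratified diagnostic statistics from sector-weighted lesion labels,
# plus the comparison tests (weighted Pearson chi-square, Mann-Whitney U).

#' Sector-weighted diagnostic summary
#'
#' Weighted TP/FP/FN counts restricted to a scope (whole gland or one zone),
#' where each lesion contributes `1/n_sectors` per sector it spans. Over the
#' whole gland the weighted counts equal the integer lesion counts, since
#' every non-excluded lesion carries total weight 1. Detection rate is
#' `TP/(TP+FN)`, positive predictive value `TP/(TP+FP)`; an undefined ratio
#' is reported as `NA`, never 0.
#'
#' @param labeled Output of [label_lesions()].
#' @param map A [sector_map()]; every sector appearing in `labeled` must be
#'   in the map.
#' @param scope `"whole_gland"`, `"TZ"` or `"PZ"`.
#' @return List of class `diag_summary`: `scope`, `tp_w`, `fp_w`, `fn_w`,
#'   `dr`, `ppv`, `cp` (the scope's share of weighted pathology-positive
#'   lesions; 1 for the whole gland).
#' @export
summarize_diagnostics <- function(labeled, map = default_sector_map(),
                                  scope = c("whole_gland", "TZ", "PZ")) {
  scope <- match.arg(scope)
  stopifnot(inherits(map, "sector_map"))
  wt <- sector_weight_table(labeled)
  unknown <- setdiff(unique(wt$sector), map$sector_ids)
  if (length(unknown) > 0L)
    stop("unknown sector id(s): ", paste(unknown, collapse = ", "))
  path_tot <- sum(wt$weight[wt$label %in% c("TP", "FN")])
  if (scope != "whole_gland")
    wt <- wt[map$zone_of[wt$sector] == scope, , drop = FALSE]
  cnt <- function(lbl) sum(wt$weight[wt$label == lbl])
  tp <- cnt("TP"); fp <- cnt("FP"); fn <- cnt("FN")
  structure(list(
    scope = scope, tp_w = tp, fp_w = fp, fn_w = fn,
    dr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    cp = if (scope == "whole_gland") {
      if (path_tot > 0) 1 else NA_real_
    } else if (path_tot > 0) (tp + fn) / path_tot else NA_real_),
    class = "diag_summary")
}

#' @export
print.diag_summary <- function(x, ...) {
  cat(sprintf("<diag_summary %s> TP %.2f / FP %.2f / FN %.2f | DR %.1f%% PPV %.1f%% CP %.1f%%\n",
              x$scope, x$tp_w, x$fp_w, x$fn_w,
              100 * x$dr, 100 * x$ppv, 100 * x$cp))
  invisible(x)
}

#' Zonal cancer prevalence
#'
#' Share of the weighted pathology-positive lesion mass (labels TP and FN)
#' falling in each zone. Shares sum to 1 when every sector belongs to TZ or
#' PZ.
#'
#' @inheritParams summarize_diagnostics
#' @return Named numeric `c(TZ =, PZ =)`; `NA` when there is no
#'   pathology-positive lesion.
#' @export
cancer_prevalence <- function(labeled, map = default_sector_map()) {
  wt <- sector_weight_table(labeled)
  wt <- wt[wt$label %in% c("TP", "FN"), , drop = FALSE]
  tot <- sum(wt$weight)
  if (tot == 0) return(c(TZ = NA_real_, PZ = NA_real_))
  zn <- map$zone_of[wt$sector]
  c(TZ = sum(wt$weight[zn == "TZ"]) / tot,
    PZ = sum(wt$weight[zn == "PZ"]) / tot)
}

#' Weighted Pearson chi-square test for two proportions
#'
#' Pearson X^2 on a 2x2 table of (possibly non-integer) weighted
#' success/failure counts, df = 1, upper-tail p-value. On integer tables
#' this is the classical Pearson chi-square; scaling all weights by a
#' constant k scales the statistic by k. No continuity correction unless
#' requested.
#'
#' @param a,b Numeric `c(successes, failures)` weighted counts (each >= 0,
#'   totals > 0) for the two groups.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `df`. A zero expected cell
#'   yields `NA` with a warning.
#' @export
weighted_chisq <- function(a, b, correct = FALSE) {
  tab <- rbind(as.numeric(a), as.numeric(b))
  if (any(tab < 0)) stop("weighted counts must be >= 0")
  if (any(rowSums(tab) <= 0)) stop("row totals must be > 0")
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expct == 0)) {
    warning("zero expected cell; p-value undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L))
  }
  dev <- abs(tab - expct)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expct)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact p-value when the
#' pooled sample has at most 20 observations and no ties, otherwise the
#' normal approximation with tie correction. `U` counts the pairs
#' `(x_i, y_j)` with `x_i < y_j` plus half the ties (so `U = 0` when every
#' x exceeds every y).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p_value`. A degenerate pooled sample (all
#'   values equal) returns `p_value = 1`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(y, x, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
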