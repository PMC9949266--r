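# Plain-text interchange: cohort tables, DCE curves and configuration.

#' Write / read a cohort as CSV
#'
#' `patients.csv` holds `patient_id, race_group, age, psa, pv, psad`;
#' `lesions.csv` holds `lesion_id, patient_id, race_group, isup, pirads,
#' zone, sectors, ktrans, kep, adc` with sectors ';'-separated.
#'
#' @param patients,lesions Cohort `data.frame`s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(patients, lesions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  lp <- file.path(dir, "lesions.csv")
  utils::write.csv(patients, pp, row.names = FALSE)
  utils::write.csv(lesions, lp, row.names = FALSE)
  invisible(c(patients = pp, lesions = lp))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(patients = utils::read.csv(file.path(dir, "patients.csv"),
                                  stringsAsFactors = FALSE),
       lesions = utils::read.csv(file.path(dir, "lesions.csv"),
                                 stringsAsFactors = FALSE))
}

#' Write / read DCE curves in long CSV format
#'
#' Columns: `lesion_id`, `t_seconds`, `concentration_mM`. The reader also
#' accepts a `t_minutes` column (auto-detected by header) and returns curves
#' on a minutes grid.
#'
#' @param curves Named list of [conc_curve()] (names = lesion ids).
#' @param path CSV file path.
#' @return `write_dce_curves` returns the path invisibly; `read_dce_curves`
#'   a named list of [conc_curve()].
#' @export
write_dce_curves <- function(curves, path) {
  stopifnot(length(curves) > 0, !is.null(names(curves)))
  df <- do.call(rbind, lapply(names(curves), function(id) {
    cc <- curves[[id]]
    data.frame(lesion_id = id, t_seconds = cc$t * 60,
               concentration_mM = cc$conc, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dce_curves
#' @export
read_dce_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("t_seconds" %in% names(df)) {
    df$t_min <- df$t_seconds / 60
  } else if ("t_minutes" %in% names(df)) {
    df$t_min <- df$t_minutes
  } else {
    stop("curve CSV needs a t_seconds or t_minutes column")
  }
  if (!"concentration_mM" %in% names(df))
    stop("curve CSV needs a concentration_mM column")
  lapply(split(df, df$lesion_id),
         function(d) conc_curve(d$t_min[order(d$t_min)],
                                d$concentration_mM[order(d$t_min)]))
}

#' Save / load a cohort configuration as JSON
#'
#' @param config A [cohort_config()].
#' @param path JSON file path.
#' @return The path (write) or a [cohort_config()] (read).
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  # jsonlite drops names of atomic vectors; promote them to objects
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(named_to_list(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path)  # keep nested named lists; unlist below
  relist_quant <- function(q) lapply(q, function(g) lapply(g, function(cat)
    lapply(cat, function(v) unlist(v))))
  num <- function(x) vapply(x, as.numeric, numeric(1L))
  cohort_config(
    covariates = lapply(raw$covariates, function(g) lapply(g, unlist)),
    lesions_per_patient = num(raw$lesions_per_patient),
    isup_freq = lapply(raw$isup_freq, unlist),
    occult_prob = lapply(raw$occult_prob, unlist),
    mri_only_rate = num(raw$mri_only_rate),
    pirads_freq = lapply(raw$pirads_freq, unlist),
    zone_prob_tz = raw$zone_prob_tz,
    span_freq = unlist(raw$span_freq),
    quant = relist_quant(raw$quant),
    seed = raw$seed)
}

# minimal GitHub-flavored markdown table renderer for reports
render_md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "fg") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(hdr, sep, rows), collapse = "\n")
}
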