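# Propensity-score caliper matching of AA cases to W controls (1:ratio)
# on age, PSA and prostate volume.

logit <- function(p) log(p / (1 - p))

#' Estimate propensity scores
#'
#' Logistic regression of race-group membership (AA = 1) on the clinical
#' covariates, fitted by maximum likelihood. Deterministic for fixed input.
#'
#' @param patients `data.frame` with `patient_id`, `race_group` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age, PSA, prostate volume).
#' @return Named numeric vector of probabilities in (0, 1), named by
#'   `patient_id`. Near-perfect separation raises an error with guidance.
#' @export
estimate_propensity <- function(patients,
                                covariates = c("age", "psa", "pv")) {
  stopifnot(all(c("patient_id", "race_group", covariates) %in% names(patients)))
  if (length(unique(patients$race_group)) < 2L)
    stop("both race groups must be present")
  dat <- patients[, covariates, drop = FALSE]
  if (any(!vapply(dat, is.numeric, logical(1L))) || anyNA(dat) ||
      any(!is.finite(as.matrix(dat))))
    stop("covariates must be finite numeric")
  dat$.y <- as.integer(patients$race_group == "AA")
  fml <- stats::reformulate(covariates, response = ".y")
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop(paste("(near-)perfect separation between groups;",
                   "propensity scores are degenerate - reconsider the",
                   "covariate set or pool"), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  # complete separation drives the deviance to 0 and the fitted probabilities
  # to the group indicators
  if (fit$deviance < 1e-6 ||
      (min(p[dat$.y == 1]) > max(p[dat$.y == 0])))
    stop(paste("(near-)perfect separation between groups;",
               "propensity scores are degenerate - reconsider the",
               "covariate set or pool"), call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  stats::setNames(as.numeric(p), patients$patient_id)
}

#' Standardized mean difference
#'
#' Difference in group means over the pooled (unweighted average of the two
#' group variances) standard deviation; the usual covariate-balance metric.
#'
#' @param x Numeric covariate values.
#' @param group Group labels (two levels).
#' @return Signed standardized mean difference (first level minus second).
#' @export
smd <- function(x, group) {
  g <- unique(group)
  if (length(g) != 2L) stop("exactly two groups required")
  x1 <- x[group == g[1]]; x2 <- x[group == g[2]]
  s <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  if (s == 0) return(0)
  (mean(x1) - mean(x2)) / s
}

#' Greedy 1:ratio caliper matching on the logit propensity scale
#'
#' Cases are processed in descending propensity order (ties broken by id);
#' each receives its `ratio` nearest unmatched controls whose logit
#' propensity lies within the caliper. Matching is without replacement;
#' cases with fewer than `ratio` in-caliper controls are dropped and
#' reported.
#'
#' @param propensity Named probability vector from [estimate_propensity()].
#' @param cases,controls Character vectors of case (AA) and control (W)
#'   patient ids.
#' @param ratio Controls per case (default 2).
#' @param caliper Caliper width on the logit scale; default 0.2 times the SD
#'   of the logit propensity over all cases and controls (the conventional
#'   choice).
#' @return List of class `match_result`: `matched_sets` (list of
#'   `list(case=, controls=)`), `dropped_cases`, `caliper`, `propensity`.
#' @export
caliper_match <- function(propensity, cases, controls, ratio = 2L,
                          caliper = NULL) {
  if (length(cases) == 0L || length(controls) == 0L)
    stop("case and control pools must be non-empty")
  if (ratio < 1L) stop("ratio must be >= 1")
  if (!all(c(cases, controls) %in% names(propensity)))
    stop("propensity missing for some patients")
  lp <- logit(propensity[c(cases, controls)])
  if (is.null(caliper)) caliper <- 0.2 * stats::sd(lp)
  if (caliper <= 0) stop("caliper must be > 0")
  ord <- order(-propensity[cases], cases)
  avail <- stats::setNames(rep(TRUE, length(controls)), controls)
  lpc <- lp[controls]
  matched <- list()
  dropped <- character(0)
  for (cs in cases[ord]) {
    d <- abs(lpc - lp[cs])
    ok <- avail & d <= caliper
    if (sum(ok) >= ratio) {
      pick <- controls[ok][order(d[ok], controls[ok])][seq_len(ratio)]
      avail[pick] <- FALSE
      matched[[length(matched) + 1L]] <- list(case = cs, controls = pick)
    } else {
      dropped <- c(dropped, cs)
    }
  }
  structure(list(matched_sets = matched, dropped_cases = dropped,
                 caliper = caliper, propensity = propensity),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched sets (%d controls each), %d cases dropped, caliper %.4f (logit)\n",
              length(x$matched_sets),
              if (length(x$matched_sets)) length(x$matched_sets[[1]]$controls) else NA,
              length(x$dropped_cases), x$caliper))
  invisible(x)
}

#' Patient ids retained by a match
#'
#' @param match A `match_result` from [caliper_match()].
#' @return Character vector: matched cases followed by matched controls.
#' @export
matched_ids <- function(match) {
  stopifnot(inherits(match, "match_result"))
  c(vapply(match$matched_sets, `[[`, character(1L), "case"),
    unlist(lapply(match$matched_sets, `[[`, "controls"), use.names = FALSE))
}

#' Covariate balance before and after matching
#'
#' Per-covariate medians and IQRs by group, standardized mean difference,
#' and a Mann-Whitney p-value, computed on the full cohort and on the
#' matched subset.
#'
#' @param patients Patient `data.frame`.
#' @param match A `match_result`.
#' @param covariates Covariate column names.
#' @return `data.frame` with one row per (stage, covariate).
#' @export
balance_table <- function(patients, match, covariates = c("age", "psa", "pv")) {
  one_stage <- function(dat, stage) {
    do.call(rbind, lapply(covariates, function(v) {
      x_aa <- dat[[v]][dat$race_group == "AA"]
      x_w <- dat[[v]][dat$race_group == "W"]
      data.frame(stage = stage, covariate = v,
                 median_aa = stats::median(x_aa), iqr_aa = stats::IQR(x_aa),
                 median_w = stats::median(x_w), iqr_w = stats::IQR(x_w),
                 smd = smd(dat[[v]], dat$race_group),
                 p_value = mann_whitney(x_aa, x_w)$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one_stage(patients, "pre"),
        one_stage(patients[patients$patient_id %in% matched_ids(match), ,
                           drop = FALSE], "post"))
}
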