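# K-trans-threshold PI-RADS update rule and brute-force threshold search:
# upgrade MRI-negative scores when K-trans is high, downgrade MRI-positive
# scores when it is low, and pick the thresholds maximizing detection rate
# without compromising PPV.

#' K-trans threshold pair
#'
#' @param t_low,t_high Lower/upper K-trans cutoffs in 1/min,
#'   `0 <= t_low <= t_high` (`t_high` may be `Inf`; the pair `(0, Inf)` is
#'   the no-op sentinel that leaves every score unchanged).
#' @return List of class `threshold_pair`.
#' @export
threshold_pair <- function(t_low, t_high) {
  if (!is.numeric(t_low) || !is.numeric(t_high) || is.na(t_low) || is.na(t_high))
    stop("thresholds must be numeric")
  if (t_low < 0 || t_low > t_high) stop("need 0 <= t_low <= t_high")
  structure(list(t_low = t_low, t_high = t_high), class = "threshold_pair")
}

#' K-trans search grid
#'
#' Equally spaced candidate threshold values; the brute-force search
#' evaluates every ordered pair on the grid plus the no-op sentinel.
#' Defaults cover 0 to 0.35 1/min, matching the physiologic prostate
#' K-trans range, at the 0.001 resolution of reported thresholds.
#'
#' @param lower,upper Grid bounds in 1/min.
#' @param step Grid step in 1/min (> 0).
#' @return List of class `search_grid` with element `values`.
#' @export
search_grid <- function(lower = 0, upper = 0.35, step = 0.001) {
  if (step <= 0 || upper < lower || lower < 0) stop("invalid grid")
  structure(list(lower = lower, upper = upper, step = step,
                 values = seq(lower, upper, by = step)),
            class = "search_grid")
}

#' Update a PI-RADS score with K-trans thresholds
#'
#' MRI-negative scores (0-2) are upgraded to 3 when K-trans is strictly
#' above `t_high`; MRI-positive scores (3-5) are downgraded to 2 when
#' K-trans is strictly below `t_low`. The rule is idempotent and monotone
#' in K-trans for a fixed initial score.
#'
#' @param pirads Integer score(s) in 0..5 (0 = MRI-occult).
#' @param ktrans K-trans value(s) in 1/min, >= 0.
#' @param thresholds A [threshold_pair()].
#' @return Updated integer score(s).
#' @export
update_pirads <- function(pirads, ktrans, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  pirads <- as.integer(pirads)
  if (any(is.na(pirads)) || any(pirads < 0L | pirads > 5L))
    stop("pirads must be in 0..5")
  if (any(is.na(ktrans)) || any(ktrans < 0)) stop("ktrans must be >= 0")
  out <- pirads
  out[pirads <= 2L & ktrans > thresholds$t_high] <- 3L
  out[pirads >= 3L & ktrans < thresholds$t_low] <- 2L
  out
}

#' Re-label lesions after the K-trans PI-RADS update
#'
#' Applies [update_pirads()] to every lesion's score, then re-runs
#' [label_lesions()] under the same criterion. A false negative with high
#' K-trans can become a true positive (upgrade); a false positive with low
#' K-trans leaves the MRI-positive pool (downgrade).
#'
#' @param lesions Lesion `data.frame` (labeled or not) with `pirads`,
#'   `isup`, `sectors`, `ktrans`.
#' @param thresholds A [threshold_pair()].
#' @param crit A [criterion()].
#' @return Labeled `data.frame` as from [label_lesions()], with the updated
#'   scores in `pirads` (the original score is kept in `pirads_original`).
#' @export
relabel_with_qdce <- function(lesions, thresholds, crit = criterion()) {
  if (!"ktrans" %in% names(lesions) || anyNA(lesions$ktrans)) {
    bad <- if ("ktrans" %in% names(lesions))
      lesions$lesion_id[is.na(lesions$ktrans)] else lesions$lesion_id
    stop("missing ktrans for lesion(s): ", paste(bad, collapse = ", "))
  }
  out <- lesions
  out$pirads_original <- lesions$pirads
  out$pirads <- update_pirads(lesions$pirads, lesions$ktrans, thresholds)
  label_lesions(out, crit)
}

#' Brute-force K-trans threshold search
#'
#' Exhaustively evaluates every `(t_low, t_high)` pair with
#' `t_low <= t_high` on the grid, plus the no-op sentinel `(0, Inf)`, and
#' returns the pair maximizing whole-gland detection rate subject to PPV not
#' falling below its baseline (no-update) value. The sentinel guarantees a
#' feasible solution reproducing the baseline. Ties are broken by higher
#' PPV, then fewer re-scored lesions, then the sentinel (prefer not
#' re-thresholding at all when it is just as good), then smaller `t_high`,
#' then smaller `t_low`.
#'
#' The evaluation exploits that, for a fixed criterion, the post-update
#' MRI-positive status of a lesion with baseline score >= 3 depends only on
#' `t_low` and that of a lesion with score <= 2 only on `t_high`, so the DR
#' and PPV surfaces decompose into sums of two step functions.
#'
#' @param lesions Lesion `data.frame` with `pirads`, `isup`, `ktrans` (and
#'   `sectors`, ignored here: the objective is whole-gland, where weighted
#'   and integer counts coincide).
#' @param grid A [search_grid()].
#' @param crit A [criterion()]; default PI-RADS >= 3 with ISUP >= 2
#'   (clinically significant cancer).
#' @return List of class `threshold_search`: `thresholds`
#'   ([threshold_pair()]), `dr`, `ppv`, `baseline_dr`, `baseline_ppv`,
#'   `n_rescored`, and the full `dr_surface` / `ppv_surface` matrices
#'   (rows = `t_low_values`, cols = `t_high_values`, `NA` where
#'   `t_low > t_high`).
#' @export
brute_force_thresholds <- function(lesions, grid = search_grid(),
                                   crit = criterion(3L, 2L)) {
  stopifnot(inherits(grid, "search_grid"), inherits(crit, "criterion"))
  if (nrow(lesions) == 0L) stop("empty lesion set")
  if (anyNA(lesions$ktrans)) stop("missing ktrans values")
  k <- lesions$ktrans
  path <- lesions$isup >= crit$min_isup
  base_hi <- lesions$pirads >= 3L                 # affected by t_low only
  pos_hi <- lesions$pirads >= crit$min_pirads     # positive among base_hi
  upgradable <- lesions$pirads <= 2L              # affected by t_high only
  up_becomes_pos <- crit$min_pirads <= 3L         # upgraded score is 3

  lows <- unique(c(0, grid$values))
  highs <- c(grid$values, Inf)

  # step-function components of TP / FP over the grid
  stepcount <- function(vals, cmp, thr) vapply(thr, function(x)
    sum(cmp(vals, x)), numeric(1L))
  a_tp <- stepcount(k[pos_hi & path], `>=`, lows)
  a_fp <- stepcount(k[pos_hi & !path], `>=`, lows)
  if (up_becomes_pos) {
    b_tp <- stepcount(k[upgradable & path], `>`, highs)
    b_fp <- stepcount(k[upgradable & !path], `>`, highs)
  } else {
    b_tp <- b_fp <- numeric(length(highs))
  }
  tp <- outer(a_tp, b_tp, `+`)
  fp <- outer(a_fp, b_fp, `+`)
  n_path <- sum(path)
  if (n_path == 0L) stop("no pathology-positive lesion under the criterion")
  dr <- tp / n_path
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  resc <- outer(stepcount(k[base_hi], `<`, lows),
                stepcount(k[upgradable], `>`, highs), `+`)
  invalid <- outer(lows, highs, `>`)
  dr[invalid] <- NA_real_
  ppv[invalid] <- NA_real_

  i0 <- match(0, lows); j0 <- match(Inf, highs)
  baseline_dr <- dr[i0, j0]
  baseline_ppv <- ppv[i0, j0]

  feasible <- !invalid & (if (is.na(baseline_ppv)) TRUE
                          else !is.na(ppv) & ppv >= baseline_ppv - 1e-12)
  cand <- which(feasible, arr.ind = TRUE)
  not_sentinel <- !(cand[, 1L] == i0 & cand[, 2L] == j0)
  ord <- order(-dr[cand], -ppv[cand], resc[cand], not_sentinel,
               highs[cand[, 2L]], lows[cand[, 1L]])
  best <- cand[ord[1L], ]
  structure(list(
    thresholds = threshold_pair(lows[best[1L]], highs[best[2L]]),
    dr = dr[best[1L], best[2L]], ppv = ppv[best[1L], best[2L]],
    baseline_dr = baseline_dr, baseline_ppv = baseline_ppv,
    n_rescored = resc[best[1L], best[2L]],
    dr_surface = dr, ppv_surface = ppv,
    t_low_values = lows, t_high_values = highs),
    class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> t_low = %.3f, t_high = %s /min | DR %.1f%% -> %.1f%%, PPV %.1f%% -> %.1f%%\n",
              x$thresholds$t_low,
              if (is.finite(x$thresholds$t_high))
                sprintf("%.3f", x$thresholds$t_high) else "Inf",
              100 * x$baseline_dr, 100 * x$dr,
              100 * x$baseline_ppv, 100 * x$ppv))
  invisible(x)
}
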