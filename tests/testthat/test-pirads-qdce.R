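test_that("the update rule applies the published thresholds as stated", {
  thr <- threshold_pair(0.102, 0.206)  # AA-tuned cutoffs
  expect_equal(update_pirads(2L, 0.250, thr), 3L)   # upgrade: 250 > 206
  expect_equal(update_pirads(4L, 0.050, thr), 2L)   # downgrade: 50 < 102
  expect_equal(update_pirads(3L, 0.150, thr), 3L)   # inside the band
  # strict inequalities: equality at a threshold never re-scores
  expect_equal(update_pirads(2L, 0.206, thr), 2L)
  expect_equal(update_pirads(4L, 0.102, thr), 4L)
  expect_error(threshold_pair(0.3, 0.2), "t_low")
  expect_error(update_pirads(6L, 0.1, thr), "0..5")
})

test_that("the update rule is idempotent and monotone in ktrans", {
  thr <- threshold_pair(0.08, 0.22)
  set.seed(41)
  pirads <- sample(0:5, 200, replace = TRUE)
  k <- stats::runif(200, 0, 0.4)
  once <- update_pirads(pirads, k, thr)
  expect_identical(update_pirads(once, k, thr), once)
  for (p0 in 0:5) {
    ks <- sort(stats::runif(50, 0, 0.4))
    up <- update_pirads(rep(p0, 50), ks, thr)
    expect_true(all(diff(up) >= 0))
  }
})

test_that("relabeling with the sentinel is the identity; upgrades flip FN to TP", {
  les <- fig2_lesions(ktrans = c(0.20, 0.15, 0.25))
  crit <- criterion(3, 1)
  base <- label_lesions(les, crit)
  same <- relabel_with_qdce(les, threshold_pair(0, Inf), crit)
  expect_identical(as.character(same$label), as.character(base$label))
  # the MRI-occult ISUP 1 lesion has ktrans 0.25 > t_high 0.206: FN -> TP
  thr <- threshold_pair(0.102, 0.206)
  up <- relabel_with_qdce(les, thr, crit)
  expect_equal(as.character(up$label), c("TP", "FP", "TP"))
  expect_equal(summarize_diagnostics(up)$dr, 1)
  expect_equal(summarize_diagnostics(base)$dr, 0.5)
  # downgrading an FP below criterion removes it from the PPV denominator
  down <- relabel_with_qdce(les, threshold_pair(0.18, 0.206), crit)
  expect_equal(as.character(down$label)[2], "EXCLUDED")
  expect_gte(summarize_diagnostics(down)$ppv, summarize_diagnostics(base)$ppv)
  les$ktrans[2] <- NA
  expect_error(relabel_with_qdce(les, thr, crit), "L2")
})

test_that("brute force returns the sentinel when no move improves DR", {
  les <- rbind(make_lesion("T1", 4, 2, ktrans = 0.20),
               make_lesion("F1", 0, 2, ktrans = 0.05))  # FN below any t_high
  res <- brute_force_thresholds(les, search_grid(0.1, 0.2, 0.05),
                                criterion(3, 2))
  expect_equal(res$dr, res$baseline_dr)
  expect_equal(res$thresholds$t_low, 0)
  expect_equal(res$thresholds$t_high, Inf)
  expect_equal(res$n_rescored, 0)
})

test_that("a constructed cohort yields strictly improving thresholds", {
  les <- rbind(
    make_lesion("FN1", 0, 2, ktrans = 0.30),
    make_lesion("FN2", 2, 3, ktrans = 0.30),
    make_lesion("FP1", 3, 0, ktrans = 0.02),
    make_lesion("TP1", 4, 2, ktrans = 0.15),
    make_lesion("TP2", 4, 3, ktrans = 0.18),
    make_lesion("TP3", 5, 2, ktrans = 0.22))
  res <- brute_force_thresholds(les, search_grid(0, 0.34, 0.02),
                                criterion(3, 2))
  expect_lt(res$thresholds$t_high, 0.30)
  expect_gt(res$thresholds$t_low, 0.02)
  expect_gt(res$dr, res$baseline_dr)
  expect_gt(res$ppv, res$baseline_ppv)
  # self-consistency: reported DR/PPV equal relabel + summarize
  lab <- relabel_with_qdce(les, res$thresholds, criterion(3, 2))
  s <- summarize_diagnostics(lab)
  expect_equal(res$dr, s$dr)
  expect_equal(res$ppv, s$ppv)
})

test_that("search agrees exactly with the independent nested-loop oracle", {
  grid <- search_grid(0, 0.3, 0.06)
  for (s in c(301L, 302L, 303L)) {
    les <- random_cohort(s)
    crit <- criterion(3, 2)
    res <- brute_force_thresholds(les, grid, crit)
    orc <- oracle_search(les, grid, crit)
    expect_equal(res$thresholds$t_low, orc$t_low)
    expect_equal(res$thresholds$t_high, orc$t_high)
    expect_equal(res$dr, orc$dr)
    expect_equal(res$ppv, orc$ppv)
  }
})

test_that("achieved DR and PPV never fall below baseline", {
  grid <- search_grid(0, 0.3, 0.05)
  for (s in 501:510) {
    les <- random_cohort(s)
    res <- brute_force_thresholds(les, grid, criterion(3, 2))
    expect_gte(res$dr, res$baseline_dr)
    expect_gte(res$ppv, res$baseline_ppv - 1e-12)
  }
})

test_that("DR/PPV surfaces carry the baseline at the sentinel cell", {
  les <- random_cohort(99L)
  res <- brute_force_thresholds(les, search_grid(0, 0.2, 0.1), criterion(3, 2))
  i <- match(0, res$t_low_values); j <- match(Inf, res$t_high_values)
  expect_equal(res$dr_surface[i, j], res$baseline_dr)
  expect_equal(res$ppv_surface[i, j], res$baseline_ppv)
  expect_true(all(is.na(res$dr_surface[outer(res$t_low_values,
                                             res$t_high_values, `>`)])))
})
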