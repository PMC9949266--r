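test_that("whole-gland DR/PPV reproduce the worked example", {
  lab <- label_lesions(fig2_lesions(), criterion(3, 1))
  s <- summarize_diagnostics(lab)
  expect_equal(s$dr, 0.5)
  expect_equal(s$ppv, 0.5)
  lab2 <- label_lesions(fig2_lesions(), criterion(4, 2))
  s2 <- summarize_diagnostics(lab2)
  expect_equal(s2$dr, 1)
  expect_equal(s2$ppv, 1)
})

test_that("zone summaries use sector weights (hand-computed cross-zone case)", {
  les <- rbind(make_lesion("A", 4, 2, "TZ_mid_L;PZ_mid_L"),  # TP split TZ/PZ
               make_lesion("B", 0, 2, "PZ_base_L"))          # FN wholly PZ
  lab <- label_lesions(les, criterion(3, 2))
  tz <- summarize_diagnostics(lab, scope = "TZ")
  pz <- summarize_diagnostics(lab, scope = "PZ")
  expect_equal(tz$tp_w, 0.5); expect_equal(tz$fn_w, 0)
  expect_equal(tz$dr, 1)
  expect_equal(pz$tp_w, 0.5); expect_equal(pz$fn_w, 1)
  expect_equal(pz$dr, 0.5 / 1.5)
  # undefined ratios are NA, not zero
  none <- label_lesions(make_lesion("C", 4, 0, "PZ_mid_L"), criterion(3, 2))
  expect_true(is.na(summarize_diagnostics(none, scope = "TZ")$ppv))
  expect_true(is.na(summarize_diagnostics(none)$dr))
  expect_error(summarize_diagnostics(
    label_lesions(make_lesion("D", 4, 2, "nowhere"), criterion(3, 2))),
    "unknown sector")
})

test_that("cancer prevalence partitions the pathology-positive weight by zone", {
  les <- rbind(make_lesion("A", 4, 2, "PZ_mid_L"),
               make_lesion("B", 0, 3, "PZ_base_R"))
  cp <- cancer_prevalence(label_lesions(les, criterion(3, 2)))
  expect_equal(unname(cp), c(0, 1))
  split <- make_lesion("C", 4, 2, "TZ_mid_L;PZ_mid_L")
  cp2 <- cancer_prevalence(label_lesions(split, criterion(3, 2)))
  expect_equal(unname(cp2), c(0.5, 0.5))
  expect_true(all(is.na(cancer_prevalence(
    label_lesions(make_lesion("E", 4, 0, "PZ_mid_L"), criterion(3, 2))))))
  # zonal shares of a generated cohort track the configured TZ probability
  lab <- label_lesions(random_cohort(55L, 400L, 400L), criterion(3, 2))
  cp3 <- cancer_prevalence(lab)
  expect_equal(sum(cp3), 1, tolerance = 1e-12)
  expect_lt(abs(cp3[["TZ"]] - 0.28), 0.04)
})

test_that("DR and PPV are invariant under sector refinement within a zone", {
  les <- random_cohort(77L)
  refine <- les
  refine$sectors <- vapply(strsplit(les$sectors, ";"), function(s)
    paste(c(paste0(s, "_a"), paste0(s, "_b")), collapse = ";"), character(1))
  base_ids <- default_sector_map()
  fine_map <- sector_map(c(outer(base_ids$sector_ids, c("_a", "_b"), paste0)),
                         rep(base_ids$zone_of, 2))
  for (sc in c("whole_gland", "TZ", "PZ")) {
    s0 <- summarize_diagnostics(label_lesions(les, criterion(3, 2)),
                                scope = sc)
    s1 <- summarize_diagnostics(label_lesions(refine, criterion(3, 2)),
                                fine_map, scope = sc)
    expect_equal(s1$dr, s0$dr)
    expect_equal(s1$ppv, s0$ppv)
  }
})

test_that("weighted chi-square equals the classical Pearson test on integers", {
  a <- c(30, 10); b <- c(45, 40)
  ours <- weighted_chisq(a, b)
  ref <- stats::chisq.test(rbind(a, b), correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  withc <- weighted_chisq(a, b, correct = TRUE)
  refc <- stats::chisq.test(rbind(a, b), correct = TRUE)
  expect_equal(withc$statistic, unname(refc$statistic))
  # identical proportions
  same <- weighted_chisq(c(10, 20), c(30, 60))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # scaling all weighted counts by k scales the statistic by k
  k <- 2.7
  expect_equal(weighted_chisq(k * a, k * b)$statistic, k * ours$statistic,
               tolerance = 1e-12)
  # degenerate margins
  expect_warning(z <- weighted_chisq(c(0, 5), c(0, 3)), "zero expected")
  expect_true(is.na(z$p_value))
  expect_error(weighted_chisq(c(0, 0), c(1, 1)), "row totals")
})

test_that("Mann-Whitney: documented convention, exact and degenerate cases", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 9)  # every x below every y
  expect_equal(mw$p_value, 0.1)  # 2/choose(6,3) * ... = 2 * 1/20
  # identical multisets force ties, hence the (conservative, continuity-
  # corrected) normal approximation: p is large but not exactly 1
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.7)
  expect_equal(mann_whitney(rep(2, 4), rep(2, 6))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration for small samples", {
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    m <- length(x)
    u_obs <- sum(outer(x, y, `<`))
    combs <- utils::combn(length(pooled), m)
    us <- apply(combs, 2, function(ix)
      sum(outer(pooled[ix], pooled[-ix], `<`)))
    mu <- m * (length(y)) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(13)
  for (r in 1:5) {
    x <- round(stats::rnorm(4), 2)
    y <- round(stats::rnorm(4) + 0.5, 2)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney(x, y)$p_value, enum_p(x, y), tolerance = 1e-12)
  }
  expect_equal(mann_whitney(c(0.1, 0.7), c(0.4, 0.9, 1.4))$p_value,
               enum_p(c(0.1, 0.7), c(0.4, 0.9, 1.4)), tolerance = 1e-12)
})
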