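# End-to-end orchestration: simulate -> (fit) -> match -> label -> evaluate
# -> tune -> report.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()]; its seed drives every random stage.
#' @param n_aa,n_w Pool sizes to simulate before matching (the control pool
#'   is deliberately larger than `ratio * n_aa` so caliper matching has
#'   slack).
#' @param criteria List of [criterion()] pairs to evaluate (default: all
#'   cancer at PI-RADS >= 3 / ISUP >= 1, and clinically significant cancer
#'   at PI-RADS >= 3 / ISUP >= 2).
#' @param grid [search_grid()] for the threshold search.
#' @param ratio Controls per case in matching.
#' @param fit_curves Simulate a noisy DCE curve per lesion and re-estimate
#'   K-trans/k_ep by Tofts fitting (slower; exercises the full quantitation
#'   path). When FALSE the generator's values are used directly.
#' @param noise_sd DCE noise SD in mmol/L for the fit stage.
#' @param dt,n_pre,n_post DCE acquisition: temporal resolution (s) and
#'   pre-/post-contrast frame counts.
#' @param alpha Significance level used when flagging comparisons.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), n_aa = 37L, n_w = 120L,
                            criteria = list(all_pca = criterion(3L, 1L),
                                            cspca = criterion(3L, 2L)),
                            grid = search_grid(), ratio = 2L,
                            fit_curves = FALSE, noise_sd = 0.02,
                            dt = 5, n_pre = 5, n_post = 70, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(grid, "search_grid"),
            all(vapply(criteria, inherits, logical(1L), "criterion")))
  if (is.null(names(criteria)) || any(!nzchar(names(criteria))))
    stop("criteria must be a named list")
  structure(list(cohort = cohort, n_aa = as.integer(n_aa),
                 n_w = as.integer(n_w), criteria = criteria, grid = grid,
                 ratio = as.integer(ratio), fit_curves = fit_curves,
                 noise_sd = noise_sd, dt = dt, n_pre = n_pre, n_post = n_post,
                 alpha = alpha),
            class = "pipeline_config")
}

# per-group x scope diagnostic table for one criterion
evaluate_groups <- function(lesions, crit, map) {
  rows <- list()
  for (g in c("AA", "W")) {
    lab <- label_lesions(lesions[lesions$race_group == g, , drop = FALSE], crit)
    cp <- cancer_prevalence(lab, map)
    for (sc in c("whole_gland", "TZ", "PZ")) {
      s <- summarize_diagnostics(lab, map, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, scope = sc, tp_w = s$tp_w, fp_w = s$fp_w, fn_w = s$fn_w,
        cp = if (sc == "whole_gland") NA_real_ else unname(cp[sc]),
        dr = s$dr, ppv = s$ppv, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # group comparisons per scope: weighted chi-square on DR and PPV tables
  cmp <- do.call(rbind, lapply(c("whole_gland", "TZ", "PZ"), function(sc) {
    a <- tab[tab$group == "AA" & tab$scope == sc, ]
    w <- tab[tab$group == "W" & tab$scope == sc, ]
    pval <- function(x, y) {
      if (sum(x) <= 0 || sum(y) <= 0) return(NA_real_)
      suppressWarnings(weighted_chisq(x, y)$p_value)
    }
    data.frame(scope = sc,
               p_dr = pval(c(a$tp_w, a$fn_w), c(w$tp_w, w$fn_w)),
               p_ppv = pval(c(a$tp_w, a$fp_w), c(w$tp_w, w$fp_w)),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, comparisons = cmp)
}

#' Run the full analysis pipeline
#'
#' Simulates a seeded synthetic cohort, optionally re-derives K-trans/k_ep
#' from noisy Tofts curves, performs 1:ratio propensity caliper matching of
#' AA to W patients on age/PSA/PV, labels lesions under each configured
#' criterion, computes zone-stratified CP/DR/PPV with group comparisons,
#' runs the per-group brute-force K-trans threshold search, and writes a
#' report (Markdown tables + JSON metrics + CSV intermediates) to
#' `out_dir`. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param map A [sector_map()].
#' @return Invisibly, a list with every stage's output (`patients`,
#'   `lesions`, `match`, `balance`, `evaluation`, `tuning`, `quant_summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         map = default_sector_map()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message(sprintf(...))

  log_msg("[simulate] %d AA + %d W patients", config$n_aa, config$n_w)
  patients <- generate_patients(config$cohort, config$n_aa, config$n_w)
  lesions <- generate_lesions(patients, config$cohort, map)
  log_msg("[simulate] %d lesions", nrow(lesions))

  if (config$fit_curves) {
    log_msg("[fit] Tofts fit of %d simulated curves (noise %.3f mmol/L)",
            nrow(lesions), config$noise_sd)
    fits <- lapply(seq_len(nrow(lesions)), function(i) {
      cc <- generate_dce_curve(lesions$ktrans[i], lesions$kep[i],
                               dt = config$dt, n_pre = config$n_pre,
                               n_post = config$n_post,
                               noise_sd = config$noise_sd,
                               seed = config$cohort$seed + 100L + i)
      post <- (config$n_pre + 1L):length(cc$t)
      tau <- cc$t[post] - cc$t[config$n_pre + 1L]
      fit_tofts(conc_curve(tau, cc$conc[post]), parker_aif(tau))
    })
    lesions$ktrans_fit <- vapply(fits, `[[`, numeric(1L), "ktrans")
    lesions$kep_fit <- vapply(fits, `[[`, numeric(1L), "kep")
    lesions$fit_converged <- vapply(fits, `[[`, logical(1L), "converged")
  }

  log_msg("[match] 1:%d propensity caliper matching on age/PSA/PV", config$ratio)
  prop <- estimate_propensity(patients)
  match <- caliper_match(prop,
                         cases = patients$patient_id[patients$race_group == "AA"],
                         controls = patients$patient_id[patients$race_group == "W"],
                         ratio = config$ratio)
  balance <- balance_table(patients, match)
  keep <- matched_ids(match)
  log_msg("[match] %d matched sets, %d cases dropped",
          length(match$matched_sets), length(match$dropped_cases))
  m_patients <- patients[patients$patient_id %in% keep, , drop = FALSE]
  m_lesions <- lesions[lesions$patient_id %in% keep, , drop = FALSE]
  log_msg("[match] cohort: %d patients, %d lesions",
          nrow(m_patients), nrow(m_lesions))

  evaluation <- lapply(config$criteria, function(cr) {
    evaluate_groups(m_lesions, cr, map)
  })

  quant_summary <- quant_by_group(m_lesions)

  log_msg("[tune] brute-force K-trans threshold search per group")
  tune_crit <- if ("cspca" %in% names(config$criteria))
    config$criteria[["cspca"]] else config$criteria[[1L]]
  tuning <- lapply(c(AA = "AA", W = "W"), function(g) {
    brute_force_thresholds(m_lesions[m_lesions$race_group == g, , drop = FALSE],
                           grid = config$grid, crit = tune_crit)
  })

  result <- list(patients = patients, lesions = lesions, match = match,
                 balance = balance, matched_patients = m_patients,
                 matched_lesions = m_lesions, evaluation = evaluation,
                 quant_summary = quant_summary, tuning = tuning,
                 config = config)
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

# per-(group, category) mean +/- SD of quantitative MRI values in the
# matched cohort, the analogue of a quantitative-characteristics table
quant_by_group <- function(lesions) {
  cat <- ifelse(lesions$isup == 0, "mri_only",
                ifelse(lesions$isup >= 3, "isup3plus",
                       ifelse(lesions$isup == 2, "isup2", "isup1")))
  agg <- function(v) do.call(rbind, lapply(split(seq_len(nrow(lesions)),
                                                 list(lesions$race_group, cat)),
                                           function(ix) {
    if (length(ix) == 0L) return(NULL)
    data.frame(group = lesions$race_group[ix[1]], category = cat[ix[1]],
               variable = v, n = length(ix), mean = mean(lesions[[v]][ix]),
               sd = stats::sd(lesions[[v]][ix]), stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(c("ktrans", "kep", "adc"), agg))
  rownames(out) <- NULL
  out
}

# render the pipeline report: markdown summary + JSON metrics + CSVs
write_report <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort(result$patients, result$lesions, out_dir)
  utils::write.csv(result$balance, file.path(out_dir, "balance.csv"),
                   row.names = FALSE)
  md <- c("# Synthetic cohort mpMRI analysis report", "",
          sprintf("Seed: %d. Matched cohort: %d patients (%d AA + %d W), %d lesions.",
                  result$config$cohort$seed, nrow(result$matched_patients),
                  sum(result$matched_patients$race_group == "AA"),
                  sum(result$matched_patients$race_group == "W"),
                  nrow(result$matched_lesions)),
          "", "## Covariate balance (pre/post matching)", "",
          render_md_table(result$balance))
  metrics <- list(seed = result$config$cohort$seed,
                  n_matched_patients = nrow(result$matched_patients),
                  n_matched_lesions = nrow(result$matched_lesions))
  for (nm in names(result$evaluation)) {
    ev <- result$evaluation[[nm]]
    utils::write.csv(ev$table,
                     file.path(out_dir, sprintf("diagnostics_%s.csv", nm)),
                     row.names = FALSE)
    md <- c(md, "", sprintf("## Diagnostic performance (%s)", nm), "",
            render_md_table(ev$table), "",
            "Group comparisons (weighted chi-square p-values):", "",
            render_md_table(ev$comparisons))
    metrics[[paste0("diagnostics_", nm)]] <- ev$table
  }
  md <- c(md, "", "## Quantitative MRI by group", "",
          render_md_table(result$quant_summary),
          "", "## K-trans threshold search (csPCa objective)", "")
  for (g in names(result$tuning)) {
    tn <- result$tuning[[g]]
    md <- c(md, sprintf(
      "- %s: t_low = %.3f, t_high = %s /min; DR %.1f%% -> %.1f%%, PPV %.1f%% -> %.1f%%",
      g, tn$thresholds$t_low,
      if (is.finite(tn$thresholds$t_high))
        sprintf("%.3f", tn$thresholds$t_high) else "none",
      100 * tn$baseline_dr, 100 * tn$dr, 100 * tn$baseline_ppv, 100 * tn$ppv))
    metrics[[paste0("thresholds_", g)]] <- list(
      t_low = tn$thresholds$t_low, t_high = tn$thresholds$t_high,
      dr_before = tn$baseline_dr, dr_after = tn$dr,
      ppv_before = tn$baseline_ppv, ppv_after = tn$ppv)
  }
  writeLines(md, file.path(out_dir, "report.md"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(out_dir)
}
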