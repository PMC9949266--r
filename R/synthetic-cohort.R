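# Seeded synthetic cohort generator: patients, lesions, and DCE curves with
# the statistical structure of a matched prostatectomy cohort, so the full
# pipeline is testable without patient data.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Log-normal draws matched to a printed median and IQR
#'
#' Clinical covariates (age, PSA, prostate volume) are strictly positive and
#' right-skewed; a log-normal matched to the reported median and
#' inter-quartile range is the sampling model. The median maps to
#' `exp(mu)` and the IQR to `2 exp(mu) sinh(z75 * sigma)` with
#' `z75 = qnorm(0.75)`.
#'
#' @param n Number of draws.
#' @param median,iqr Target median and inter-quartile range (> 0).
#' @return Numeric vector of length `n`.
#' @export
rlnorm_med_iqr <- function(n, median, iqr) {
  stopifnot(median > 0, iqr > 0)
  mu <- log(median)
  sigma <- asinh(iqr / (2 * median)) / stats::qnorm(0.75)
  stats::rlnorm(n, mu, sigma)
}

#' @rdname rlnorm_med_iqr
#' @param p Probabilities for the quantile function.
#' @export
qlnorm_med_iqr <- function(p, median, iqr) {
  stopifnot(median > 0, iqr > 0)
  mu <- log(median)
  sigma <- asinh(iqr / (2 * median)) / stats::qnorm(0.75)
  stats::qlnorm(p, mu, sigma)
}

#' Zero-truncated normal draws
#'
#' Samples from a normal distribution truncated below at 0, by inverse-CDF
#' transform (one uniform per draw, so the stream is reproducible). Used for
#' quantitative MRI values, which are reported as mean +/- SD but must be
#' non-negative.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal (`sd > 0`).
#' @return Non-negative numeric vector of length `n`.
#' @export
rnorm_trunc0 <- function(n, mean, sd) {
  stopifnot(sd > 0)
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# default per-(group, category) quantitative MRI parameters; ktrans/kep in
# 1/min, adc in 1e-6 mm^2/s; categories key lesions by pathology grade
# (mri_only = MRI-positive without a pathology correlate)
default_quant_params <- function() {
  q <- function(kt_m, kt_s, kp_m, kp_s, a_m, a_s)
    list(ktrans = c(mean = kt_m, sd = kt_s) / 1000,
         kep = c(mean = kp_m, sd = kp_s) / 1000,
         adc = c(mean = a_m, sd = a_s))
  list(
    AA = list(
      isup1     = q(207.0, 120.6, 613.7, 196.1,  953.0,  96.9),
      isup2     = q(226.9,  77.7, 724.6, 182.4,  909.0, 211.0),
      isup3plus = q(242.3, 141.5, 595.2, 174.7,  952.0, 229.0),
      mri_only  = q(213.7,  94.6, 731.6, 200.7, 1155.0, 205.7)),
    W = list(
      isup1     = q(189.8, 149.9, 583.6, 268.2,  954.0, 191.0),
      isup2     = q(186.3,  72.0, 634.8, 238.9,  899.0, 171.0),
      isup3plus = q(190.3,  94.4, 711.4, 231.5,  848.0, 165.0),
      mri_only  = q(194.5, 142.9, 632.5, 265.8, 1009.2,  60.7))
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every distribution the generator draws from. Defaults reproduce
#' the structure of a 1:2 matched prostatectomy cohort of African American
#' (AA) and White (W) men: covariate medians/IQRs, lesion multiplicity
#' (about 1.6 pathology lesions per patient), ISUP grade and PI-RADS
#' frequencies, the fraction of pathology lesions that are MRI-occult, the
#' per-patient rate of MRI-only findings, zone placement, sector span, and
#' per-group zero-truncated-normal parameters for K-trans, k_ep and ADC.
#'
#' @param covariates Per-group list of `c(median=, iqr=)` for `age`, `psa`,
#'   `pv`.
#' @param lesions_per_patient Named vector, mean pathology lesions per patient
#'   per group; lesion count is modeled as `1 + Poisson(mean - 1)` since
#'   every prostatectomy specimen carries at least one pathology lesion.
#' @param isup_freq Per-group probabilities over ISUP categories
#'   `c("1","2","3","4plus")`.
#' @param occult_prob Per-group probabilities that a pathology lesion is
#'   MRI-occult (PI-RADS recorded as 0), split by `isup1` vs `cs` (ISUP >= 2).
#' @param mri_only_rate Per-group Poisson rate of MRI-positive lesions with no
#'   pathology correlate, per patient.
#' @param pirads_freq Per-group probabilities over visible scores
#'   `c("3","4","5")`.
#' @param zone_prob_tz Probability a lesion sits in the transition zone.
#' @param span_freq Probabilities over sector-span counts `1, 2, 3`.
#' @param quant Per-(group, category) truncated-normal `c(mean, sd)` for
#'   `ktrans`, `kep` (1/min) and `adc` (1e-6 mm^2/s); see
#'   the package vignette for the default parameterization.
#' @param seed Integer seed giving full determinism of the generated cohort.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(
    covariates = list(
      AA = list(age = c(median = 61, iqr = 9.75),
                psa = c(median = 6.7, iqr = 2.5),
                pv  = c(median = 41, iqr = 23)),
      W  = list(age = c(median = 62, iqr = 10),
                psa = c(median = 5.95, iqr = 4.6),
                pv  = c(median = 40, iqr = 22.5))),
    lesions_per_patient = c(AA = 1.7, W = 1.5),
    isup_freq = list(AA = c("1" = 22, "2" = 27, "3" = 9, "4plus" = 5) / 63,
                     W  = c("1" = 28, "2" = 55, "3" = 19, "4plus" = 9) / 111),
    occult_prob = list(AA = c(isup1 = 18 / 22, cs = 9 / 41),
                       W  = c(isup1 = 18 / 28, cs = 19 / 83)),
    mri_only_rate = c(AA = 8 / 37, W = 9 / 74),
    pirads_freq = list(AA = c("3" = 0.25, "4" = 0.50, "5" = 0.25),
                       W  = c("3" = 0.22, "4" = 0.52, "5" = 0.26)),
    zone_prob_tz = 0.28,
    span_freq = c("1" = 0.5, "2" = 0.35, "3" = 0.15),
    quant = default_quant_params(),
    seed = 20230215L) {
  cfg <- list(covariates = covariates,
              lesions_per_patient = lesions_per_patient,
              isup_freq = isup_freq, occult_prob = occult_prob,
              mri_only_rate = mri_only_rate, pirads_freq = pirads_freq,
              zone_prob_tz = zone_prob_tz, span_freq = span_freq,
              quant = quant, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (g in c("AA", "W")) {
    for (v in c("age", "psa", "pv")) {
      p <- cfg$covariates[[g]][[v]]
      if (p[["median"]] <= 0 || p[["iqr"]] <= 0)
        stop(sprintf("non-positive %s distribution parameters for group %s", v, g))
    }
    if (abs(sum(cfg$isup_freq[[g]]) - 1) > 1e-9)
      stop("ISUP frequencies must sum to 1")
    if (abs(sum(cfg$pirads_freq[[g]]) - 1) > 1e-9)
      stop("PI-RADS frequencies must sum to 1")
    if (any(cfg$occult_prob[[g]] < 0 | cfg$occult_prob[[g]] > 1))
      stop("occult probabilities must be in [0, 1]")
    if (cfg$lesions_per_patient[[g]] < 1)
      stop("mean lesions/patient must be >= 1")
    if (cfg$mri_only_rate[[g]] < 0) stop("mri_only_rate must be >= 0")
    for (cat in names(cfg$quant[[g]])) {
      for (par in c("ktrans", "kep", "adc")) {
        if (cfg$quant[[g]][[cat]][[par]][["sd"]] <= 0)
          stop("quantitative scale parameters must be > 0")
      }
    }
  }
  if (abs(sum(cfg$span_freq) - 1) > 1e-9) stop("span frequencies must sum to 1")
  if (cfg$zone_prob_tz < 0 || cfg$zone_prob_tz > 1)
    stop("zone_prob_tz must be in [0, 1]")
  invisible(cfg)
}

#' Generate synthetic patients
#'
#' Draws clinical covariates per race group from log-normals matched to the
#' configured medians/IQRs; PSA density is derived as `psa / pv`.
#'
#' @param config A [cohort_config()].
#' @param n_aa,n_w Number of AA and W patients (> 0).
#' @param seed Seed; defaults to `config$seed`. The same seed always yields
#'   an identical cohort.
#' @return `data.frame` with columns `patient_id`, `race_group`, `age`,
#'   `psa`, `pv`, `psad`.
#' @export
generate_patients <- function(config, n_aa, n_w, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), n_aa > 0, n_w > 0)
  validate_cohort_config(config)
  with_seed(seed, {
    one_group <- function(g, n, prefix) {
      cv <- config$covariates[[g]]
      age <- rlnorm_med_iqr(n, cv$age[["median"]], cv$age[["iqr"]])
      psa <- rlnorm_med_iqr(n, cv$psa[["median"]], cv$psa[["iqr"]])
      pv <- rlnorm_med_iqr(n, cv$pv[["median"]], cv$pv[["iqr"]])
      data.frame(patient_id = sprintf("%s%04d", prefix, seq_len(n)),
                 race_group = g, age = age, psa = psa, pv = pv,
                 psad = psa / pv, stringsAsFactors = FALSE)
    }
    rbind(one_group("AA", n_aa, "AA"), one_group("W", n_w, "W"))
  })
}

# sample ISUP value from category label
sample_isup <- function(n, freq) {
  cat <- sample(names(freq), n, replace = TRUE, prob = freq)
  val <- integer(n)
  hi <- cat == "4plus"
  val[!hi] <- as.integer(cat[!hi])
  val[hi] <- 4L + stats::rbinom(sum(hi), 1L, 0.3)
  val
}

#' Generate synthetic lesions for a patient cohort
#'
#' Each patient receives `1 + Poisson` pathology lesions with configured ISUP
#' frequencies, a configured chance of being MRI-occult (PI-RADS 0), plus a
#' Poisson number of MRI-only findings (ISUP 0). Every lesion gets a zone, a
#' contiguous-free random set of sectors within that zone, and K-trans /
#' k_ep / ADC values from zero-truncated normals keyed by race group and
#' grade category.
#'
#' @param patients `data.frame` from [generate_patients()].
#' @param config A [cohort_config()].
#' @param map A [sector_map()].
#' @param seed Seed; defaults to `config$seed + 1` so lesions vary
#'   independently of the patient draw.
#' @return `data.frame` with columns `lesion_id`, `patient_id`, `race_group`,
#'   `isup` (0 = no pathology correlate), `pirads` (0 = MRI-occult), `zone`,
#'   `sectors` (';'-separated sector ids), `ktrans`, `kep`, `adc`.
#' @export
generate_lesions <- function(patients, config, map = default_sector_map(),
                             seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"), inherits(map, "sector_map"))
  if (nrow(patients) == 0L) stop("patients must be non-empty")
  validate_cohort_config(config)
  with_seed(seed, {
    grp <- patients$race_group
    lam <- config$lesions_per_patient[grp] - 1
    n_path <- 1L + stats::rpois(nrow(patients), lam)
    n_mri <- stats::rpois(nrow(patients), config$mri_only_rate[grp])
    n_tot <- n_path + n_mri
    pat_idx <- rep(seq_len(nrow(patients)), n_tot)
    is_path <- unlist(lapply(seq_len(nrow(patients)), function(i)
      rep(c(TRUE, FALSE), c(n_path[i], n_mri[i]))), use.names = FALSE)
    g <- grp[pat_idx]
    n <- length(pat_idx)

    isup <- integer(n)
    pirads <- integer(n)
    for (gg in c("AA", "W")) {
      sel <- g == gg & is_path
      isup[sel] <- sample_isup(sum(sel), config$isup_freq[[gg]])
      occ <- config$occult_prob[[gg]]
      p_occ <- ifelse(isup[sel] >= 2, occ[["cs"]], occ[["isup1"]])
      occult <- stats::runif(sum(sel)) < p_occ
      vis <- sum(sel) - sum(occult)
      pr <- integer(sum(sel))
      pr[!occult] <- as.integer(sample(names(config$pirads_freq[[gg]]), vis,
                                       replace = TRUE,
                                       prob = config$pirads_freq[[gg]]))
      pirads[sel] <- pr
      selm <- g == gg & !is_path
      pirads[selm] <- as.integer(sample(names(config$pirads_freq[[gg]]),
                                        sum(selm), replace = TRUE,
                                        prob = config$pirads_freq[[gg]]))
    }

    zone <- ifelse(stats::runif(n) < config$zone_prob_tz, "TZ", "PZ")
    span <- as.integer(sample(names(config$span_freq), n, replace = TRUE,
                              prob = config$span_freq))
    tz_ids <- zone_sectors(map, "TZ")
    pz_ids <- zone_sectors(map, "PZ")
    span <- pmin(span, ifelse(zone == "TZ", length(tz_ids), length(pz_ids)))
    sectors <- vapply(seq_len(n), function(i) {
      pool <- if (zone[i] == "TZ") tz_ids else pz_ids
      paste(sort(sample(pool, span[i])), collapse = ";")
    }, character(1L))

    category <- ifelse(!is_path, "mri_only",
                       ifelse(isup >= 3, "isup3plus",
                              ifelse(isup == 2, "isup2", "isup1")))
    ktrans <- kep <- adc <- numeric(n)
    for (gg in c("AA", "W")) {
      for (cat in c("isup1", "isup2", "isup3plus", "mri_only")) {
        sel <- g == gg & category == cat
        if (!any(sel)) next
        qp <- config$quant[[gg]][[cat]]
        ktrans[sel] <- rnorm_trunc0(sum(sel), qp$ktrans[["mean"]], qp$ktrans[["sd"]])
        kep[sel] <- rnorm_trunc0(sum(sel), qp$kep[["mean"]], qp$kep[["sd"]])
        adc[sel] <- rnorm_trunc0(sum(sel), qp$adc[["mean"]], qp$adc[["sd"]])
      }
    }

    les_no <- unlist(lapply(n_tot, seq_len), use.names = FALSE)
    data.frame(
      lesion_id = sprintf("%s_L%d", patients$patient_id[pat_idx], les_no),
      patient_id = patients$patient_id[pat_idx],
      race_group = g, isup = isup, pirads = pirads, zone = zone,
      sectors = sectors, ktrans = ktrans, kep = kep, adc = adc,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a DCE concentration-time curve for a lesion
#'
#' Baseline frames at zero concentration followed by the Tofts forward model
#' driven by the Parker population AIF, with optional additive zero-mean
#' Gaussian noise. The acquisition mimics an ultrafast spoiled gradient-echo
#' DCE protocol: 5-6 s temporal resolution, a handful of pre-contrast frames
#' and on the order of 70 post-contrast frames.
#'
#' @param ktrans,kep Tofts parameters of the lesion (1/min).
#' @param dt Temporal resolution in seconds, within [4, 8].
#' @param n_pre Number of pre-contrast frames (>= 1).
#' @param n_post Number of post-contrast frames.
#' @param noise_sd Additive Gaussian noise SD in mmol/L (>= 0).
#' @param aif_params [parker_aif_params()].
#' @param seed Optional seed for the noise draw.
#' @return A [conc_curve()] of length `n_pre + n_post`; time in minutes from
#'   the first frame, injection at the end of frame `n_pre`.
#' @export
generate_dce_curve <- function(ktrans, kep, dt = 5, n_pre = 5, n_post = 70,
                               noise_sd = 0, aif_params = parker_aif_params(),
                               seed = NULL) {
  if (dt < 4 || dt > 8) stop("dt must be in [4, 8] seconds")
  if (n_pre < 1) stop("n_pre must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dt_min <- dt / 60
  tau <- (seq_len(n_post) - 1L) * dt_min
  ct_post <- tofts_forward(tofts_params(ktrans, kep), parker_aif(tau, aif_params))$conc
  t_all <- (seq_len(n_pre + n_post) - 1L) * dt_min
  conc <- c(rep(0, n_pre), ct_post)
  if (noise_sd > 0) {
    conc <- conc + with_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
  }
  structure(list(t = t_all, conc = conc), class = "conc_curve")
}
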