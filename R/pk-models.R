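# Pharmacokinetic core: Parker population AIF, standard Tofts model
# (forward convolution + bounded nonlinear least-squares fit), and
# monoexponential ADC estimation.

#' Concentration-time curve
#'
#' Constructs a gadolinium concentration-time curve, the common container for
#' arterial input functions (plasma concentration) and tissue curves.
#'
#' @param t Time grid in minutes, strictly increasing, length >= 2.
#' @param conc Concentration in mmol/L, same length as `t`.
#' @return An object of class `conc_curve`: a list with elements `t` and `conc`.
#' @export
conc_curve <- function(t, conc) {
  t <- as.numeric(t)
  conc <- as.numeric(conc)
  if (length(t) < 2L) stop("a concentration curve needs at least 2 samples")
  if (length(t) != length(conc)) stop("time and concentration lengths differ")
  if (anyNA(t) || anyNA(conc)) stop("NA in concentration curve")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  structure(list(t = t, conc = conc), class = "conc_curve")
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve> %d samples, t = [%.3f, %.3f] min, peak %.4f mmol/L\n",
              length(x$t), x$t[1], x$t[length(x$t)], max(x$conc)))
  invisible(x)
}

#' Parker population arterial input function parameters
#'
#' Population-average AIF of Parker et al.: a sum of two Gaussians plus an
#' exponentially decaying sigmoid washout term,
#' \deqn{C_p(t) = \sum_{i=1,2} \frac{A_i}{\sigma_i\sqrt{2\pi}}
#'   e^{-(t-T_i)^2/2\sigma_i^2} + \frac{\alpha e^{-\beta t}}{1+e^{-s(t-\tau)}}.}
#' Amplitudes `A1`, `A2` are in mmol.min, centers `T1`, `T2` and widths
#' `sigma1`, `sigma2` in minutes, `alpha` in mmol, `beta` and `s` in 1/min,
#' `tau` in minutes.
#'
#' @param A1,A2,T1,T2,sigma1,sigma2,alpha,beta,s,tau Numeric scalars; defaults
#'   are the published population averages.
#' @return A named list of class `parker_aif_params`.
#' @export
parker_aif_params <- function(A1 = 0.809, A2 = 0.330,
                              T1 = 0.17046, T2 = 0.365,
                              sigma1 = 0.0563, sigma2 = 0.132,
                              alpha = 1.050, beta = 0.1685,
                              s = 38.078, tau = 0.483) {
  p <- list(A1 = A1, A2 = A2, T1 = T1, T2 = T2, sigma1 = sigma1,
            sigma2 = sigma2, alpha = alpha, beta = beta, s = s, tau = tau)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1L))))
    stop("all Parker AIF parameters must be finite numeric scalars")
  if (p$sigma1 <= 0 || p$sigma2 <= 0) stop("Gaussian widths must be positive")
  structure(p, class = "parker_aif_params")
}

#' Evaluate the Parker population AIF
#'
#' @param t Time since contrast injection, minutes, non-negative.
#' @param params AIF parameters from [parker_aif_params()].
#' @return A [conc_curve()] with the plasma concentration C_p(t) in mmol/L
#'   (tiny negative numerical values clipped to 0). For a single time point a
#'   bare numeric is returned.
#' @export
parker_aif <- function(t, params = parker_aif_params()) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("Parker AIF is defined for t >= 0 (minutes post-injection)")
  g <- function(A, Tc, sg) A / (sg * sqrt(2 * pi)) * exp(-(t - Tc)^2 / (2 * sg^2))
  cp <- g(params$A1, params$T1, params$sigma1) +
    g(params$A2, params$T2, params$sigma2) +
    params$alpha * exp(-params$beta * t) / (1 + exp(-params$s * (t - params$tau)))
  cp <- pmax(cp, 0)
  if (length(t) < 2L) return(cp)
  conc_curve(t, cp)
}

#' Tofts model parameters
#'
#' @param ktrans Volume transfer (wash-in) constant, 1/min, >= 0.
#' @param kep Efflux (wash-out) rate constant, 1/min, >= 0.
#' @return List of class `tofts_params`.
#' @export
tofts_params <- function(ktrans, kep) {
  if (!is.finite(ktrans) || ktrans < 0) stop("ktrans must be finite and >= 0")
  if (!is.finite(kep) || kep < 0) stop("kep must be finite and >= 0")
  structure(list(ktrans = ktrans, kep = kep), class = "tofts_params")
}

# Exponentially-weighted running integral J(t_i) = int_0^{t_i} f(tau)
# exp(-kep (t_i - tau)) dtau by trapezoid, computed with the stable
# interval recursion J_{i+1} = J_i e^{-kep dt} + dt/2 (f_i e^{-kep dt} + f_{i+1}).
exp_conv_trapz <- function(t, f, kep) {
  n <- length(t)
  dt <- diff(t)
  if (n == 1L) return(0)
  if (diff(range(dt)) < 1e-12 * max(dt)) {
    h <- dt[1]
    E <- exp(-kep * h)
    incr <- c(0, h / 2 * (f[-n] * E + f[-1]))
    as.numeric(stats::filter(incr, E, method = "recursive"))
  } else {
    J <- numeric(n)
    for (i in seq_len(n - 1L)) {
      E <- exp(-kep * dt[i])
      J[i + 1L] <- J[i] * E + dt[i] / 2 * (f[i] * E + f[i + 1L])
    }
    J
  }
}

#' Tofts forward model
#'
#' Tissue concentration under the standard Tofts model,
#' \deqn{C_t(t) = K^{trans} \int_0^t C_p(\tau)\, e^{-k_{ep}(t-\tau)}\, d\tau,}
#' evaluated by trapezoidal quadrature on an internally upsampled grid
#' (linear interpolation of the AIF) and decimated back to the acquisition
#' grid. Upsampling matters because 5-6 s sampling under-resolves the AIF
#' first pass.
#'
#' When the AIF is supplied as a sampled curve its values on the fine grid
#' are linearly interpolated; supplying it as a function (e.g.
#' `function(t) parker_aif(t)$conc`) evaluates it exactly there, removing
#' the input-sampling error of the first-pass peak.
#'
#' @param params [tofts_params()].
#' @param aif A [conc_curve()] holding the plasma input C_p(t), or a
#'   function of time (minutes) returning C_p; in the latter case `t_grid`
#'   gives the output grid.
#' @param upsample Integer >= 1, internal grid refinement factor (default 10).
#' @param t_grid Output time grid in minutes, required when `aif` is a
#'   function.
#' @return A [conc_curve()] with C_t on the same grid as `aif`; C_t(0) is 0
#'   when the grid starts at the injection.
#' @export
tofts_forward <- function(params, aif, upsample = 10L, t_grid = NULL) {
  aif_fun <- NULL
  if (is.function(aif)) {
    if (is.null(t_grid)) stop("t_grid is required when aif is a function")
    aif_fun <- aif
    aif <- conc_curve(t_grid, aif(t_grid))
  }
  stopifnot(inherits(aif, "conc_curve"))
  if (!is.finite(upsample) || upsample < 1) stop("upsample must be >= 1")
  upsample <- as.integer(upsample)
  t <- aif$t
  n <- length(t)
  if (upsample > 1L) {
    t_fine <- unique(c(t, as.vector(vapply(
      seq_len(n - 1L),
      function(i) t[i] + (t[i + 1L] - t[i]) * seq_len(upsample - 1L) / upsample,
      numeric(upsample - 1L)))))
    t_fine <- sort(t_fine)
    cp_fine <- if (is.null(aif_fun)) stats::approx(t, aif$conc, xout = t_fine)$y
               else aif_fun(t_fine)
  } else {
    t_fine <- t
    cp_fine <- aif$conc
  }
  J <- exp_conv_trapz(t_fine, cp_fine, params$kep)
  ct_fine <- params$ktrans * J
  idx <- match(t, t_fine)
  conc_curve(t, pmax(ct_fine[idx], 0))
}

#' Fit the Tofts model to a tissue concentration curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the Tofts forward model against a measured tissue
#' curve, sharing a time grid with the supplied AIF.
#'
#' @param curve Tissue [conc_curve()].
#' @param aif Plasma input [conc_curve()] on the same time grid.
#' @param init Numeric `c(ktrans, kep)` starting values (default `c(0.1, 0.5)`,
#'   a mid-physiologic prostate value).
#' @param lower,upper Box bounds on `(ktrans, kep)`; defaults `c(0, 0)` and
#'   `c(2, 10)` 1/min span the physiologic range.
#' @param upsample Passed to [tofts_forward()].
#' @return List of class `tofts_fit`: `ktrans`, `kep`, `rss` (residual sum of
#'   squares), `converged` (logical), `boundary` (logical, TRUE when an
#'   estimate sits on a bound), `message`. Non-convergence is flagged, not an
#'   error; an all-zero curve returns `ktrans = 0` at the boundary.
#' @export
fit_tofts <- function(curve, aif, init = c(0.1, 0.5),
                      lower = c(0, 0), upper = c(2, 10), upsample = 10L) {
  stopifnot(inherits(curve, "conc_curve"), inherits(aif, "conc_curve"))
  if (length(curve$t) != length(aif$t) ||
      any(abs(curve$t - aif$t) > 1e-9 * max(abs(aif$t), 1)))
    stop("tissue curve and AIF must share a time grid")
  if (any(init < lower) || any(init > upper))
    stop("init must lie inside the bounds")
  if (all(curve$conc == 0)) {
    return(structure(list(ktrans = 0, kep = init[2], rss = 0, converged = TRUE,
                          boundary = TRUE,
                          message = "all-zero tissue curve; ktrans at lower bound"),
                     class = "tofts_fit"))
  }
  resid_fn <- function(p) {
    curve$conc - tofts_forward(tofts_params(p[1], p[2]), aif,
                               upsample = upsample)$conc
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  tol <- 1e-8
  structure(list(
    ktrans = p[1], kep = p[2],
    rss = sum(fit$fvec^2),
    converged = fit$info %in% 1:4,
    boundary = any(p - lower < tol) || any(upper - p < tol),
    message = fit$message), class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf("<tofts_fit> ktrans = %.4f /min, kep = %.4f /min, rss = %.3g%s\n",
              x$ktrans, x$kep, x$rss,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Monoexponential ADC fit
#'
#' Apparent diffusion coefficient from diffusion-weighted signal intensities
#' at multiple b-values by ordinary least squares on the log signal:
#' ln S(b) = ln S0 - b * ADC.
#'
#' @param b_values b-values in s/mm^2 (at least 2 distinct values).
#' @param signals Positive signal intensities (arbitrary units), same length.
#' @return ADC in 1e-6 mm^2/s (so a decay of 1e-3 mm^2/s returns 1000).
#' @export
adc_fit <- function(b_values, signals) {
  b_values <- as.numeric(b_values); signals <- as.numeric(signals)
  if (length(b_values) != length(signals)) stop("b_values/signals length mismatch")
  if (length(unique(b_values)) < 2L) stop("need at least 2 distinct b-values")
  if (any(signals <= 0)) stop("signals must be positive for log-linear fitting")
  slope <- stats::coef(stats::lm(log(signals) ~ b_values))[["b_values"]]
  # slope is -ADC in mm^2/s; report in 1e-6 mm^2/s
  -slope * 1e6
}

#' ROI summary of a quantitative map
#'
#' Lesion-level quantitative MRI values are volumetric ROI averages; the
#' median variant is exposed for robustness checks.
#'
#' @param values Non-empty numeric vector of voxel values.
#' @return Scalar mean (or median).
#' @export
roi_mean <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty ROI")
  mean(values)
}

#' @rdname roi_mean
#' @export
roi_median <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty ROI")
  stats::median(values)
}
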