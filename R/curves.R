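# Biosensor data reductions: BRET ratio, two-Gaussian spectral
# decomposition, 4-parameter logistic dose-response (EC50) and Boltzmann
# thermal melt (Tm, slope).

#' BRET ratio
#'
#' Ratio of acceptor to donor emission (e.g. GFP2 / RLuc).
#'
#' @param donor_emission donor intensity (> 0).
#' @param acceptor_emission acceptor intensity.
#' @return acceptor / donor.
#' @export
bret_ratio <- function(donor_emission, acceptor_emission) {
  if (any(donor_emission <= 0)) stop("donor emission must be positive")
  acceptor_emission / donor_emission
}

#' Percentage change in BRET relative to basal
#' @param bret BRET ratio(s) after treatment.
#' @param basal basal BRET ratio.
#' @return 100 * (bret - basal) / basal.
#' @export
bret_percent_change <- function(bret, basal) {
  if (any(basal <= 0)) stop("basal BRET must be positive")
  100 * (bret - basal) / basal
}

#' Fit a bioluminescence spectrum with 1 or 2 Gaussian components
#'
#' Nonlinear least squares of
#' `sum_k A_k exp(-(lambda - mu_k)^2 / (2 sigma_k^2))` with amplitude
#' bounds at 0, width bounds above 0 and centers bounded to the measured
#' wavelength window. Components are reported sorted by center.
#'
#' @param wavelengths wavelengths in nm.
#' @param intensities measured intensities.
#' @param n_components 1 or 2.
#' @return a `spectrum_fit`: list with `components` (data frame:
#'   amplitude, center, width), `residual_rms`, `n_components`,
#'   `fitted` (function of wavelength).
#' @export
fit_spectrum <- function(wavelengths, intensities, n_components = 2) {
  stopifnot(n_components %in% 1:2)
  if (length(wavelengths) < 3 * n_components + 1) {
    stop("need at least ", 3 * n_components + 1, " points")
  }
  if (max(intensities) <= 0 || stats::sd(intensities) == 0) {
    stop("non-convergence: flat or non-positive spectrum (residual RMS ",
         format(stats::sd(intensities)), ")")
  }
  w <- wavelengths; y <- intensities
  rng <- range(w)
  span <- diff(rng)
  pk <- w[which.max(y)]
  if (n_components == 1) {
    start <- list(A1 = max(y), m1 = pk, s1 = span / 6)
    lower <- c(0, rng[1], span / 200)
    upper <- c(Inf, rng[2], span)
    form <- y ~ A1 * exp(-(w - m1)^2 / (2 * s1^2))
  } else {
    # second start centre: highest point far from the first peak
    far <- abs(w - pk) > span / 4
    pk2 <- if (any(far)) w[far][which.max(y[far])] else pk + span / 3
    start <- list(A1 = max(y), m1 = min(pk, pk2), s1 = span / 8,
                  A2 = max(y) / 2, m2 = max(pk, pk2), s2 = span / 8)
    lower <- c(0, rng[1], span / 200, 0, rng[1], span / 200)
    upper <- c(Inf, rng[2], span, Inf, rng[2], span)
    form <- y ~ A1 * exp(-(w - m1)^2 / (2 * s1^2)) +
      A2 * exp(-(w - m2)^2 / (2 * s2^2))
  }
  dat <- data.frame(w = w, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("non-convergence in spectral fit: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  k <- n_components
  comp <- data.frame(amplitude = p[seq(1, 3 * k, 3)],
                     center = p[seq(2, 3 * k, 3)],
                     width = abs(p[seq(3, 3 * k, 3)]))
  comp <- comp[order(comp$center), ]
  rownames(comp) <- NULL
  res <- stats::resid(fit)
  structure(list(components = comp,
                 residual_rms = sqrt(mean(res^2)),
                 n_components = k,
                 fitted = function(wl) {
                   out <- 0
                   for (i in seq_len(k)) {
                     out <- out + comp$amplitude[i] *
                       exp(-(wl - comp$center[i])^2 / (2 * comp$width[i]^2))
                   }
                   out
                 }),
            class = "spectrum_fit")
}

# 4PL (variable-slope) model on the log10 concentration axis
fourpl <- function(logc, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logc) * hill))
}

#' Fit a variable-slope dose-response curve (4-parameter logistic)
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 c) h))`
#' by bounded nonlinear least squares with 5 deterministic multi-starts
#' (logEC50 seeded at the half-max crossing and at response-range
#' quartiles). Zero concentrations are excluded from the fit itself.
#' When the response does not plateau within the measured range the fit
#' is flagged EC50 under-determined (the estimate is a lower bound).
#'
#' @param conc concentrations (molar); zeros allowed but not fitted.
#' @param response responses (e.g. percent change in BRET).
#' @return a `dose_response_fit`: list with `bottom`, `top`, `logec50`,
#'   `hill`, `ec50`, `se` (named vector of standard errors),
#'   `residual_rms`, `underdetermined` flag, `fitted` (function of conc).
#' @export
fit_dose_response <- function(conc, response) {
  keep <- conc > 0
  x <- log10(conc[keep]); y <- response[keep]
  if (length(unique(conc[keep])) < 5) {
    stop("need at least 5 distinct nonzero concentrations")
  }
  ylo <- min(y); yhi <- max(y)
  increasing <- stats::cor(x, y) >= 0
  half <- (ylo + yhi) / 2
  # half-max crossing on the measured grid
  ord <- order(x)
  cross <- x[ord][which.min(abs(y[ord] - half))]
  starts <- lapply(c(cross, stats::quantile(x, c(0.25, 0.5, 0.75)),
                     max(x)), function(le)
    list(bottom = ylo, top = yhi, logec50 = unname(le),
         hill = if (increasing) 1 else -1))
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fourpl(x, bottom, top, logec50, hill),
                        data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("non-convergence in dose-response fit")
  fit <- best$fit
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  # plateau check: fitted top must be approached within the data range
  ytop_at_max <- fourpl(max(x), p["bottom"], p["top"], p["logec50"],
                        p["hill"])
  plateau_frac <- abs(ytop_at_max - p["bottom"]) /
    max(abs(p["top"] - p["bottom"]), 1e-12)
  under <- unname(p["logec50"] >= max(x) | plateau_frac < 0.95)
  if (under) {
    message("EC50 under-determined; lower bound reported (response does ",
            "not plateau within the measured concentrations)")
  }
  structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                 logec50 = unname(p["logec50"]), hill = unname(p["hill"]),
                 ec50 = unname(10^p["logec50"]), se = se,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 underdetermined = under,
                 fitted = function(conc)
                   unname(fourpl(log10(conc), p["bottom"], p["top"],
                                 p["logec50"], p["hill"]))),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: EC50 = %.3g M (logEC50 %.3f), hill %.2f, [%.1f, %.1f]%s\n",
    x$ec50, x$logec50, x$hill, x$bottom, x$top,
    if (x$underdetermined) " [EC50 under-determined]" else ""))
  invisible(x)
}

boltzmann <- function(temp, bottom, top, tm, slope) {
  # clamp the exponent so near-step transitions keep finite gradients
  z <- pmin(pmax((tm - temp) / slope, -50), 50)
  bottom + (top - bottom) / (1 + exp(z))
}

#' Fit a Boltzmann sigmoidal thermal melt
#'
#' Fits `y = bottom + (top - bottom) / (1 + exp((Tm - T)/slope))`. Under
#' this sign convention a melt that decreases with temperature has a
#' negative slope; Tm is the temperature at which the curve is halfway
#' between bottom and top (verified on the fitted curve).
#'
#' @param temperature temperatures (degrees C), at least 6 spanning the
#'   transition.
#' @param bret_ratio measured (relative) BRET ratios.
#' @return a `melt_fit`: list with `bottom`, `top`, `tm`, `slope`, `se`,
#'   `covariance`, `residual_rms`, `fitted` (function of temperature).
#' @export
fit_melt <- function(temperature, bret_ratio) {
  if (length(temperature) < 6) stop("need at least 6 temperatures")
  x <- temperature; y <- bret_ratio
  if (stats::sd(y) == 0) stop("degenerate melt data: constant response")
  decreasing <- stats::cor(x, y) < 0
  half <- (min(y) + max(y)) / 2
  tm0 <- x[which.min(abs(y - half))]
  span <- diff(range(x))
  starts <- lapply(c(span / 50, span / 20, span / 8, span / 4), function(s)
    list(bottom = min(y), top = max(y), tm = tm0,
         slope = if (decreasing) -s else s))
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ boltzmann(x, bottom, top, tm, slope),
                        data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("non-convergence in melt fit")
  fit <- best$fit
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                 tm = unname(p["tm"]), slope = unname(p["slope"]),
                 se = se, covariance = covm,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 fitted = function(temp)
                   unname(boltzmann(temp, p["bottom"], p["top"],
                                    p["tm"], p["slope"]))),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm = %.2f C, slope = %.2f, range [%.3g, %.3g]\n",
              x$tm, x$slope, x$bottom, x$top))
  invisible(x)
}

#' Two-sample t-test convenience wrapper for fitted parameters
#' @param a,b numeric vectors of per-experiment parameter estimates.
#' @return the [stats::t.test()] result (two-tailed, unpaired, equal
#'   variance, matching the usual reporting convention).
#' @export
compare_parameters <- function(a, b) {
  stats::t.test(a, b, var.equal = TRUE)
}
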