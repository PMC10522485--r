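# NMR observables: chemical shift perturbation, DM-induced intensity
# attenuation classes, CPMG effective relaxation rates and two-site
# fast-exchange dispersion fitting.

#' Combined 1H/15N chemical shift perturbation
#'
#' `sqrt(dH^2 + (0.15 dN)^2)` in ppm; the 0.15 factor down-weights the wider
#' 15N shift range.
#'
#' @param delta_h 1H shift difference, ppm.
#' @param delta_n 15N shift difference, ppm.
#' @return combined perturbation, ppm. Vectorized.
#' @examples
#' csp(0, 1)  # 0.15
#' @export
csp <- function(delta_h, delta_n) {
  sqrt(delta_h^2 + (0.15 * delta_n)^2)
}

#' Classify DM-induced peak intensity attenuation
#'
#' Per-residue ratio r = I/I0. Classes: `"strong"` if r < 0.5;
#' `"significant"` if 0.5 <= r < (mean - sd) of all finite ratios;
#' otherwise `"unaffected"`. Residues with I0 = 0 are flagged
#' `"unassessable"` and excluded from the mean/sd statistics.
#'
#' @param table data.frame with columns `intensity` (I, with DM) and
#'   `intensity0` (I0, without DM); other columns (chain, residue) pass
#'   through.
#' @return the input with added columns `ratio`, `class`; summary mean and
#'   sd of the finite ratios attached as attributes `"mean"` / `"sd"`.
#' @export
classify_intensity_ratios <- function(table) {
  if (any(table$intensity < 0) || any(table$intensity0 < 0)) {
    invalid_parameter("intensities must be nonnegative")
  }
  assessable <- table$intensity0 > 0
  if (sum(assessable) < 3L) {
    insufficient_data("need at least 3 residues with I0 > 0")
  }
  ratio <- ifelse(assessable, table$intensity / table$intensity0, NA_real_)
  m <- mean(ratio[assessable])
  s <- stats::sd(ratio[assessable])
  cls <- rep("unassessable", nrow(table))
  r <- ratio[assessable]
  cls[assessable] <- ifelse(r < 0.5, "strong",
                     ifelse(r < m - s, "significant", "unaffected"))
  table$ratio <- ratio
  table$class <- cls
  attr(table, "mean") <- m
  attr(table, "sd") <- s
  table
}

#' Effective transverse relaxation rate from CPMG peak intensities
#'
#' `R2eff = (1 / T_CPMG) * ln(I0 / I_CPMG)`.
#'
#' @param i_cpmg peak intensity at a given CPMG frequency; must be positive.
#' @param i0 reference-plane intensity; must be positive.
#' @param t_cpmg constant-time relaxation delay, s.
#' @return rate in 1/s (negative, with a warning, if `i_cpmg > i0`).
#' @examples
#' r2eff(exp(-1), 1, 0.04)  # 25 s^-1
#' @export
r2eff <- function(i_cpmg, i0, t_cpmg) {
  stopifnot_positive(i_cpmg, "i_cpmg")
  stopifnot_positive(i0, "i0")
  stopifnot_positive(t_cpmg, "t_cpmg")
  out <- log(i0 / i_cpmg) / t_cpmg
  if (any(out < 0)) warning("I > I0: negative R2eff")
  out
}

#' Fit a CPMG relaxation-dispersion curve
#'
#' Fits both a flat model (no exchange, constant R2_0) and the two-site
#' fast-exchange Luz-Meiboom model
#' `R2eff(nu) = R2_0 + (phi/kex)(1 - (4 nu/kex) tanh(kex/(4 nu)))`,
#' and selects between them by small-sample-corrected AIC (AICc). Zero
#' frequencies are treated as reference planes and dropped; duplicated
#' frequencies (repeat error checks) are averaged. A methyl group is called
#' exchanging when the fitted dispersion amplitude
#' `R2eff(nu_min) - R2_0` exceeds 2 1/s.
#'
#' @param curve a `dispersion_curve` (list with `freqs`, `r2eff`).
#' @param threshold dispersion amplitude (1/s) above which the group is
#'   called exchanging (default 2).
#' @return list with `model` ("flat" or "two_state"), `r2_0`, `phi`, `kex`
#'   (NA for flat), `dispersion_amplitude`, `exchanging`, `aicc` (named,
#'   both models).
#' @export
fit_dispersion <- function(curve, threshold = 2) {
  nu <- curve$freqs
  r2 <- curve$r2eff
  keep <- nu > 0
  nu <- nu[keep]; r2 <- r2[keep]
  if (anyDuplicated(nu)) {
    r2 <- as.numeric(tapply(r2, nu, mean))
    nu <- sort(unique(nu))
  } else {
    o <- order(nu); nu <- nu[o]; r2 <- r2[o]
  }
  n <- length(nu)
  if (n < 6L) insufficient_data("need >= 6 distinct CPMG frequencies")

  aicc <- function(rss, k) {
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  # Flat model: mean.
  r2_flat <- mean(r2)
  rss_flat <- sum((r2 - r2_flat)^2)
  # Two-state model.
  amp0 <- max(r2[1L] - min(r2), 0.1)
  kex0 <- 4 * stats::median(nu)
  fit <- tryCatch(
    stats::nls(r2 ~ luz_meiboom(nu, r2_0, phi, kex),
               start = list(r2_0 = min(r2), phi = amp0 * kex0, kex = kex0),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE),
               algorithm = "port", lower = c(0, 0, 1e-3)),
    error = function(e) e
  )
  two_ok <- !inherits(fit, "error")
  if (!two_ok && rss_flat == 0) {
    # perfectly flat synthetic curve
    return(list(model = "flat", r2_0 = r2_flat, phi = NA_real_,
                kex = NA_real_, dispersion_amplitude = 0, exchanging = FALSE,
                aicc = c(flat = -Inf, two_state = Inf)))
  }
  if (!two_ok) {
    # fall back to flat if only the flat model is available
    return(list(model = "flat", r2_0 = r2_flat, phi = NA_real_,
                kex = NA_real_, dispersion_amplitude = 0, exchanging = FALSE,
                aicc = c(flat = aicc(max(rss_flat, 1e-300), 2),
                         two_state = Inf)))
  }
  rss_two <- sum(stats::resid(fit)^2)
  a_flat <- aicc(max(rss_flat, 1e-300), 2)   # mean + variance
  a_two <- aicc(max(rss_two, 1e-300), 4)     # 3 params + variance
  cf <- stats::coef(fit)
  if (a_two < a_flat) {
    amp <- luz_meiboom(min(nu), cf[["r2_0"]], cf[["phi"]], cf[["kex"]]) -
      cf[["r2_0"]]
    list(model = "two_state", r2_0 = cf[["r2_0"]], phi = cf[["phi"]],
         kex = cf[["kex"]], dispersion_amplitude = amp,
         exchanging = amp > threshold,
         aicc = c(flat = a_flat, two_state = a_two))
  } else {
    list(model = "flat", r2_0 = r2_flat, phi = NA_real_, kex = NA_real_,
         dispersion_amplitude = 0, exchanging = FALSE,
         aicc = c(flat = a_flat, two_state = a_two))
  }
}
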