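# Fluorescence-polarization exchange kinetics: intrinsic and DM-catalyzed
# CLIP off-rates, apparent on-rates (initial velocities), DM susceptibility
# and high/low grouping of allotypes.

#' Fit a single-exponential dissociation trace
#'
#' Least-squares fit of `baseline + amplitude * exp(-k * t)` to a
#' fluorescence-polarization dissociation trace. A floating baseline is used
#' because competition with excess unlabeled peptide makes rebinding
#' negligible but leaves a residual polarization offset.
#'
#' @param trace a `kinetic_trace` with `mode == "dissociation"` (or any list
#'   with numeric `times`/`signal`).
#' @return A `rate_estimate`: list with `rate` (per minute), `se`,
#'   `residual_variance`, `converged`, `flat` (TRUE when the trace carried no
#'   signal span and 0 was returned with a warning).
#' @export
fit_dissociation <- function(trace) {
  if (!is.null(trace$mode) && trace$mode != "dissociation") {
    invalid_parameter("`trace` must be a dissociation trace")
  }
  t <- trace$times
  y <- trace$signal
  if (length(t) < 5L) insufficient_data("need at least 5 points")
  span <- diff(range(y))
  if (span == 0 || span < 1e-12 * max(abs(y), 1)) {
    warning("flat trace: returning rate 0")
    return(structure(list(rate = 0, se = NA_real_, residual_variance = 0,
                          converged = TRUE, flat = TRUE),
                     class = "rate_estimate"))
  }
  # Log-linear start: regress log(y - b0) on t with b0 slightly below min.
  b0 <- min(y) - 0.05 * span
  pos <- y - b0 > 0
  k0 <- tryCatch({
    cf <- stats::coef(stats::lm(log(y[pos] - b0) ~ t[pos]))
    max(-cf[[2]], 1e-6)
  }, error = function(e) 1 / max(t[length(t)], 1))
  fit <- tryCatch(
    stats::nls(y ~ b + a * exp(-k * t),
               start = list(b = b0, a = span, k = k0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port", lower = c(-Inf, 0, 0)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    fit_failure(paste("dissociation fit failed:", conditionMessage(fit)),
                diagnostics = list(start = c(b = b0, a = span, k = k0)))
  }
  sm <- summary(fit)
  structure(
    list(rate = stats::coef(fit)[["k"]],
         se = sm$coefficients["k", "Std. Error"],
         residual_variance = sm$sigma^2,
         converged = fit$convInfo$isConv %||% TRUE,
         flat = FALSE),
    class = "rate_estimate"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial velocity of an association trace
#'
#' Ordinary least-squares slope over the early window of an association
#' trace. The window is all points before the signal first reaches
#' `early_fraction` of the total rise to the final plateau (plateau taken as
#' the mean of the last 10% of points), with a minimum of 4 points.
#'
#' @param trace a `kinetic_trace` with `mode == "association"`.
#' @param early_fraction fraction of the rise defining the linear window.
#' @return A `rate_estimate` with `rate` = v0 (signal units per minute).
#' @export
fit_initial_velocity <- function(trace, early_fraction = 0.2) {
  if (!is.null(trace$mode) && trace$mode != "association") {
    invalid_parameter("`trace` must be an association trace")
  }
  t <- trace$times
  y <- trace$signal
  n <- length(t)
  if (n < 4L) insufficient_data("need at least 4 points")
  tail_n <- max(1L, floor(0.1 * n))
  plateau <- mean(y[(n - tail_n + 1L):n])
  y0 <- y[1L]
  cut <- y0 + early_fraction * (plateau - y0)
  idx <- if (plateau >= y0) which(y >= cut) else which(y <= cut)
  last <- if (length(idx)) max(4L, idx[1L]) else n
  last <- min(last, n)
  if (last < 4L) insufficient_data("fewer than 4 early points")
  w <- seq_len(last)
  fit <- stats::lm(y[w] ~ t[w])
  slope <- stats::coef(fit)[[2]]
  if (slope < 0) warning("decreasing trace: negative initial velocity")
  sm <- summary(fit)
  structure(
    list(rate = slope, se = sm$coefficients[2, 2],
         residual_variance = sm$sigma^2, converged = TRUE,
         n_points = last),
    class = "rate_estimate"
  )
}

#' DM susceptibility of an allotype
#'
#' `(k_off_dm - k_off_in) / dm_conc`: the per-micromolar, per-minute
#' enhancement of peptide dissociation by HLA-DM.
#'
#' @param k_off_dm DM-catalyzed off-rate, per minute.
#' @param k_off_in intrinsic off-rate, per minute.
#' @param dm_conc DM concentration, uM; must be positive.
#' @return DM susceptibility in 1/(uM min).
#' @examples
#' dm_susceptibility(0.05, 0.014, 0.15)  # 0.24
#' @export
dm_susceptibility <- function(k_off_dm, k_off_in, dm_conc) {
  stopifnot_positive(dm_conc, "dm_conc")
  (k_off_dm - k_off_in) / dm_conc
}

#' Group allotypes by DM susceptibility
#'
#' The classifying threshold is the arithmetic mean of the susceptibilities;
#' values strictly above the mean are `"high"`, all others (including ties)
#' `"low"`.
#'
#' @param records data.frame with columns `allotype` and `dm_susceptibility`
#'   (or a numeric vector of susceptibilities, optionally named).
#' @return data.frame with columns `allotype`, `dm_susceptibility`, `group`;
#'   the threshold is attached as attribute `"threshold"`.
#' @export
classify_allotypes <- function(records) {
  if (is.numeric(records)) {
    records <- data.frame(
      allotype = names(records) %||% sprintf("a%02d", seq_along(records)),
      dm_susceptibility = as.numeric(records)
    )
  }
  if (nrow(records) < 2L) insufficient_data("need at least 2 records")
  if (any(!is.finite(records$dm_susceptibility))) {
    invalid_parameter("susceptibilities must be finite")
  }
  thr <- mean(records$dm_susceptibility)
  records$group <- ifelse(records$dm_susceptibility > thr, "high", "low")
  attr(records, "threshold") <- thr
  records
}

#' Summarize replicate rate estimates
#'
#' Replicates are fitted independently; this reports mean, standard
#' deviation and n, the convention used for triplicate exchange assays.
#'
#' @param rates numeric vector of per-replicate rate estimates.
#' @return list with `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(rates) {
  if (length(rates) < 1L) insufficient_data("no replicates")
  list(mean = mean(rates),
       sd = if (length(rates) > 1L) stats::sd(rates) else NA_real_,
       n = length(rates))
}
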