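# Thermal-shift analysis: melting temperature from dye-fluorescence
# unfolding curves.

#' Fit a melting curve and estimate Tm
#'
#' Least-squares fit of a four-parameter Boltzmann sigmoid
#' `lower + (upper - lower) / (1 + exp((tm - T)/slope))` to a thermal-shift
#' fluorescence curve. With `truncate_after_max = TRUE`, points after the
#' global fluorescence maximum are discarded before fitting; this removes
#' the dye-dissociation tail seen at high temperature.
#'
#' @param curve a `melt_curve` (list with `temperatures`, `fluorescence`).
#' @param truncate_after_max drop points after the fluorescence maximum.
#' @return A `tm_estimate`: list with `tm` (degrees C), `slope`, `lower`,
#'   `upper`, `se` (standard error of tm), `residual_variance`.
#' @export
fit_melt <- function(curve, truncate_after_max = FALSE) {
  temp <- curve$temperatures
  y <- curve$fluorescence
  if (length(temp) < 8L || diff(range(temp)) < 20) {
    insufficient_data("melt curve must have >= 8 points spanning >= 20 degrees C")
  }
  if (diff(range(y)) == 0) invalid_parameter("fluorescence is constant")
  if (truncate_after_max) {
    imax <- which.max(y)
    if (imax >= 8L) {
      temp <- temp[seq_len(imax)]
      y <- y[seq_len(imax)]
    }
  }
  lo0 <- min(y); up0 <- max(y)
  tm0 <- temp[which.min(abs(y - (lo0 + up0) / 2))]
  fit <- tryCatch(
    stats::nls(y ~ lower + (upper - lower) / (1 + exp((tm - temp) / slope)),
               start = list(lower = lo0, upper = up0, tm = tm0, slope = 2),
               control = stats::nls.control(maxiter = 200),
               algorithm = "port",
               lower = c(-Inf, -Inf, min(temp), 1e-3)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    fit_failure(paste("melt fit failed:", conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  if (cf[["upper"]] <= cf[["lower"]]) {
    fit_failure("no unfolding transition: fitted amplitude is nonpositive")
  }
  if (cf[["tm"]] < min(temp) || cf[["tm"]] > max(temp)) {
    fit_failure("fitted Tm outside the measured temperature range")
  }
  sm <- summary(fit)
  structure(
    list(tm = cf[["tm"]], slope = cf[["slope"]],
         lower = cf[["lower"]], upper = cf[["upper"]],
         se = sm$coefficients["tm", "Std. Error"],
         residual_variance = sm$sigma^2),
    class = "tm_estimate"
  )
}
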