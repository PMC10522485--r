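# Group-level association statistics: pooled two-sample t-test, ordinary
# least squares with R^2, and per-group odds-ratio correlations.

#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance, accepting either raw values or
#' summary statistics (mean, s.e.m., n). With summaries, the group standard
#' deviation is recovered as `sd = sem * sqrt(n)`. Degrees of freedom are
#' `n1 + n2 - 2` (the pooled form, identifiable from printed df when
#' reproducing published tests).
#'
#' @param g1,g2 either numeric vectors of raw values, or lists with `n`,
#'   `mean`, `sem` (or `sd`).
#' @return list with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @examples
#' pooled_t_test(list(n = 7, mean = 5.94, sem = 0.92),
#'               list(n = 5, mean = 2.36, sem = 0.40))
#' @export
pooled_t_test <- function(g1, g2) {
  as_summary <- function(g) {
    if (is.numeric(g)) {
      if (length(g) < 2L) insufficient_data("each group needs n >= 2")
      list(n = length(g), mean = mean(g), sd = stats::sd(g))
    } else {
      n <- g$n
      if (is.null(n) || n < 2) insufficient_data("each group needs n >= 2")
      sd <- g$sd %||% (g$sem * sqrt(n))
      list(n = n, mean = g$mean, sd = sd)
    }
  }
  s1 <- as_summary(g1)
  s2 <- as_summary(g2)
  df <- s1$n + s2$n - 2
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
  tstat <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean_diff = s1$mean - s2$mean)
}

#' Ordinary least-squares line with R-squared
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 3L) insufficient_data("need >= 3 points")
  if (stats::var(x) == 0) {
    abort_mhc2x("x is constant: degenerate fit", "mhc2x_degenerate_fit")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
       r_squared = r2)
}

#' Per-group correlation of disease odds ratios with a dynamic predictor
#'
#' Splits an allotype table by disease-association flag and fits the odds
#' ratio against the chosen predictor within each group.
#'
#' @param table data.frame with columns `odds_ratio`, `associated`
#'   (logical), and the predictor column (`dm_susceptibility` or
#'   `ms1_population`).
#' @param predictor which predictor column to use.
#' @return list with elements `associated` and `not_associated`, each a
#'   [linear_fit()] result (or NULL, with a warning, when that group has
#'   fewer than 3 allotypes).
#' @export
grouped_or_correlation <- function(table,
                                   predictor = c("dm_susceptibility",
                                                 "ms1_population")) {
  predictor <- match.arg(predictor)
  if (any(table$odds_ratio <= 0)) invalid_parameter("odds ratios must be positive")
  fit_group <- function(sub, label) {
    if (nrow(sub) < 3L) {
      warning(sprintf("group '%s' has fewer than 3 allotypes: skipped", label))
      return(NULL)
    }
    linear_fit(sub[[predictor]], sub$odds_ratio)
  }
  list(
    associated = fit_group(table[table$associated, , drop = FALSE],
                           "associated"),
    not_associated = fit_group(table[!table$associated, , drop = FALSE],
                               "not_associated")
  )
}
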