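# Equilibrium binding energetics: ligand-depletion Kd fitting, interaction
# free energies, and double-mutant-cycle coupling energies.

#' Fit a dissociation constant from a titration isotherm
#'
#' Least-squares fit of the exact ligand-depletion model
#' `bound = ((R + L + Kd) - sqrt((R + L + Kd)^2 - 4 R L)) / 2`,
#' `fraction = bound / L`. The quadratic form is mandatory here because the
#' probe concentration (typically 100 nM) is comparable to the fitted Kd, so
#' the simple hyperbola `R/(R + Kd)` would be biased.
#'
#' @param isotherm a `binding_isotherm` (list with `receptor_concs`,
#'   `fraction_bound`, `probe_conc`).
#' @return list with `kd` (nM), `se`, `residual_variance`,
#'   `boundary_warning` (TRUE when the data are saturated or Kd ran into
#'   its lower bound, i.e. Kd is not identified).
#' @export
fit_kd <- function(isotherm) {
  R <- isotherm$receptor_concs
  f <- isotherm$fraction_bound
  L <- isotherm$probe_conc
  if (length(R) < 6L) insufficient_data("need at least 6 titration points")
  if (anyDuplicated(R)) invalid_parameter("receptor concentrations must be distinct")
  boundary <- FALSE
  if (min(f) > 0.95) {
    warning("isotherm saturated: Kd poorly identified")
    boundary <- TRUE
  }
  kd_lo <- 1e-6 * max(R)
  # Start from the receptor concentration nearest half-saturation.
  kd0 <- R[which.min(abs(f - 0.5))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(R)
  fit <- tryCatch(
    stats::nls(f ~ ligand_depletion_bound(R, L, kd) / L,
               start = list(kd = kd0),
               control = stats::nls.control(maxiter = 200),
               algorithm = "port", lower = kd_lo),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    fit_failure(paste("Kd fit failed:", conditionMessage(fit)))
  }
  kd <- stats::coef(fit)[["kd"]]
  if (kd <= kd_lo * (1 + 1e-6)) {
    warning("Kd at lower bound")
    boundary <- TRUE
  }
  sm <- summary(fit)
  list(kd = kd, se = sm$coefficients["kd", "Std. Error"],
       residual_variance = sm$sigma^2, boundary_warning = boundary)
}

#' Interaction free energy from a Kd ratio
#'
#' `delta_g(kd_num, kd_den, T) = R T ln(kd_num / kd_den)` in kJ/mol, with
#' R = 8.314 J/(mol K). Positive when the numerator complex binds more
#' weakly.
#'
#' @param kd_num,kd_den dissociation constants (same units).
#' @param temperature temperature in K (default 298.15).
#' @return free energy difference, kJ/mol.
#' @examples
#' delta_g(1000, 100)  # RT ln 10 = 5.708 kJ/mol at 298.15 K
#' @export
delta_g <- function(kd_num, kd_den, temperature = 298.15) {
  stopifnot_positive(kd_num, "kd_num")
  stopifnot_positive(kd_den, "kd_den")
  stopifnot_positive(temperature, "temperature")
  .RGAS * temperature * log(kd_num / kd_den)
}

#' Coupling free energy of a double mutant cycle
#'
#' For a cycle of wild type, two single mutants and the double mutant, the
#' coupling energy is the non-additivity
#' `ddG = dG12 - (dG1 + dG2) = R T ln(Kd12 Kdwt / (Kd1 Kd2))`.
#' A nonzero value indicates energetic coupling between the two mutated
#' sites. Standard error is propagated first-order from the Kd standard
#' errors: `se(ddG) = R T sqrt(sum (se_i / Kd_i)^2)`.
#'
#' @param cycle list/data.frame with `kd_wt`, `kd_mt1`, `kd_mt2`, `kd_mt12`
#'   (nM) and optional `se_wt`, `se_mt1`, `se_mt2`, `se_mt12`.
#' @param temperature temperature in K.
#' @return list with `ddg` (kJ/mol), `se`, and the three component
#'   free energies `dg1`, `dg2`, `dg12`.
#' @export
coupling_energy <- function(cycle, temperature = 298.15) {
  kds <- c(cycle$kd_wt, cycle$kd_mt1, cycle$kd_mt2, cycle$kd_mt12)
  stopifnot_positive(kds, "cycle Kds")
  rt <- .RGAS * temperature
  dg1 <- rt * log(cycle$kd_mt1 / cycle$kd_wt)
  dg2 <- rt * log(cycle$kd_mt2 / cycle$kd_wt)
  dg12 <- rt * log(cycle$kd_mt12 / cycle$kd_wt)
  ddg <- dg12 - (dg1 + dg2)
  ses <- c(cycle$se_wt %||% 0, cycle$se_mt1 %||% 0,
           cycle$se_mt2 %||% 0, cycle$se_mt12 %||% 0)
  se <- rt * sqrt(sum((ses / kds)^2))
  list(ddg = ddg, se = se, dg1 = dg1, dg2 = dg2, dg12 = dg12,
       temperature = temperature)
}
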