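# mhc2x

Quantitative analysis of HLA-DM-catalyzed peptide exchange on MHC class II
allotypes.

## The problem

MHC class II (HLA-DR) molecules present peptides to T helper cells. Before
loading antigenic peptides, the groove is occupied by the placeholder
peptide CLIP, and the catalyst HLA-DM (DM) accelerates its exchange. The
DRB1 β-chain is highly polymorphic, and allotypes differ widely in thermal
stability, intrinsic CLIP off-rate, and how strongly DM accelerates
exchange. Linking those biochemical differences to the conformational
dynamics of the peptide–MHC-II complex — and ultimately to disease
association of individual allotypes — requires a pipeline that spans
kinetic and thermodynamic curve fitting, NMR observables, sequence
polymorphism scoring, Markov state modelling of conformational ensembles,
structure comparison, and group-level statistics. `mhc2x` implements that
pipeline for R, together with a synthetic-data module that generates every
input with known ground truth so each stage is testable end to end.

## Core quantities

- **Off-rates**: dissociation traces are fitted as
  `S(t) = baseline + A·exp(−k_off·t)`; apparent on-rates as the OLS slope
  of the early association window (initial velocity v₀).
- **DM susceptibility**: `(k_off,DM − k_off,in)/[DM]` in µM⁻¹ min⁻¹;
  allotypes strictly above the panel mean form the high-susceptibility
  group.
- **Thermal stability**: Tm from a four-parameter Boltzmann sigmoid fitted
  to thermal-shift fluorescence curves (optional truncation of the
  post-maximum dye-dissociation tail).
- **Binding energetics**: Kd from the exact ligand-depletion (quadratic)
  isotherm; `ΔG = RT·ln(Kd_ii/Kd_i)`; double-mutant-cycle coupling energy
  `ΔΔG = ΔG₁₂ − (ΔG₁ + ΔG₂)` with first-order error propagation.
- **NMR**: chemical shift perturbation `√(Δδ_H² + (0.15·Δδ_N)²)`; I/I₀
  intensity-ratio classes (strong < 0.5; significant < mean − s.d.);
  `R₂^eff = (1/T_CPMG)·ln(I₀/I)`; Luz–Meiboom two-site fast-exchange
  dispersion fits with AICc model selection and a 2 s⁻¹ dispersion
  criterion.
- **Polymorphism**: per-column normalized entropy
  `C = (−Σ ρ_α log₂ ρ_α)/log₂(min(N, K))`.
- **Conformational states**: TICA → k-means microstates → reversible
  maximum-likelihood MSM → PCCA+ metastable decomposition (50% crisp
  cutoff); populations, free energies `G = −RT·ln(p/p_ref)`, inverse-MFPT
  transition rates, trajectory-bootstrap 1σ confidence intervals.
- **Structures**: Cα Kabsch superposition with sequence-based residue
  pairing and iterative outlier rejection.
- **Statistics**: pooled-variance two-sample t-test, OLS with R², and
  per-group odds-ratio correlations.

## Worked example

```r
library(mhc2x)

# a DM-catalyzed dissociation trace with known ground truth
tr <- gen_kinetic_trace("dissociation", times = seq(0, 300, 5), k_off = 0.05,
                        amplitude = 100, baseline = 20, noise_sd = 1, seed = 2,
                        allotype = "SYN*04:01", dm_conc = 0.15)
est <- fit_dissociation(tr)
sprintf("k_off,DM = %.4f +/- %.4f per min", est$rate, est$se)
#> "k_off,DM = 0.0492 +/- 0.0008 per min"

dm_susceptibility(est$rate, k_off_in = 0.014, dm_conc = 0.15)
#> 0.235   # per uM per min: DM accelerates CLIP release ~3.5-fold here

# group comparison of DM-susceptible-state free energies
tt <- pooled_t_test(list(n = 7, mean = 5.94, sem = 0.92),
                    list(n = 5, mean = 2.36, sem = 0.40))
sprintf("t = %.2f, df = %d, P = %.3f", tt$t, tt$df, tt$p)
#> "t = 3.11, df = 10, P = 0.011"
```

The fitted `k_off,DM` recovers the simulated 0.05 min⁻¹ within its standard
error; the t-test shows the high-susceptibility group's DM-susceptible
conformation is significantly more stable (lower free energy) than the low
group's.

A full synthetic 12-allotype demo (simulate → kinetics → thermoshift →
MSM → stats) runs with:

```r
res <- run_pipeline(demo_config(seed = 1))
res$table   # 12 rows: k_off_in, k_off_dm, susceptibility, group, tm,
            # ms1_population, ms1_g
```

or from the shell via the installed CLI script:

```sh
Rscript exec/mhc2x pipeline --seed 1 --out demo_out
```

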