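---
title: "Models and methods behind mhc2x"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mhc2x}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2x)
```

`mhc2x` quantifies how HLA-DM catalysis of peptide exchange varies across
MHC class II (HLA-DR) allotypes, and how that variation relates to the
conformational dynamics of the peptide–MHC-II complex. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the methodology was genuinely open.

## Exchange kinetics

Dissociation of a fluorescent placeholder peptide (CLIP) is modelled as a
single exponential with a floating baseline,
$S(t) = b + A e^{-k_{\mathrm{off}} t}$. A single-exponential is justified
because the assay is run with a large excess of unlabeled competitor
peptide, which makes rebinding of the labeled probe negligible; the
baseline absorbs residual polarization of the free probe. Rates are per
minute; the standard error comes from the nonlinear-fit covariance. Flat
traces return rate 0 with a warning rather than an error, since fully
stable complexes are a legitimate assay outcome.

Apparent on-rates are summarized as initial velocities: the OLS slope over
the early window, by default all points before the signal reaches 20% of
its rise to the final plateau (minimum 4 points). The window rule is a
package choice — the assay literature rarely states one. For a saturating
exponential sampled densely, OLS over the 20% window carries a
deterministic curvature bias of about 7%; users who need unbiased $v_0$ on
smooth traces should shrink `early_fraction` (2% brings the bias below
2%). We keep 20% as the default because real traces are noisy and the
wider window stabilizes the slope estimate.

DM susceptibility is
$(k_{\mathrm{off,DM}} - k_{\mathrm{off,in}})/[\mathrm{DM}]$ in
µM⁻¹ min⁻¹ — the per-micromolar enhancement of dissociation by the
catalyst, measured here at 150 nM DM (0.15 µM). Allotypes are grouped by
the arithmetic mean of susceptibilities: strictly above → high, ties →
low. The tie rule is deterministic and conservative.

## Thermal stability

Thermal-shift curves are fitted with a four-parameter Boltzmann sigmoid
$F(T) = \ell + (u - \ell)/(1 + e^{(T_m - T)/s})$. "Sigmoidal function" is
underspecified in most protocols; the Boltzmann form is the common choice
and its midpoint is exactly $T_m$. Curves often show a post-maximum decay
from dye dissociation; `truncate_after_max` removes everything after the
fluorescence maximum before fitting, which our tests show changes $T_m$ by
less than 0.1 °C on clean curves. Fits are rejected (not silently
returned) when no rising transition exists or the fitted $T_m$ leaves the
measured range. Raw curves are fitted, not derivatives: the derivative
route amplifies noise and the raw sigmoid round-trips the generator
exactly.

## Binding energetics

Titrations use a fixed probe concentration (100 nM) comparable to typical
dissociation constants, so the free-receptor approximation fails. The
exact ligand-depletion solution of the binding quadratic is therefore
mandatory:
$\mathrm{bound} = \big(R + L + K_d - \sqrt{(R + L + K_d)^2 - 4RL}\big)/2$.
In the regime $L \ll K_d$ this reduces to the hyperbola $R/(R + K_d)$
(verified to 1% in tests). Saturated isotherms yield a boundary warning —
$K_d$ is then unidentified, not merely imprecise.

Free-energy differences are $\Delta G = RT \ln(K_{d,ii}/K_{d,i})$ with
$R = 8.314\,\mathrm{J\,mol^{-1}K^{-1}}$. The equilibrium-assay temperature
is not fixed by the protocol; 298.15 K is the default and every result
carries the temperature used. Double-mutant-cycle coupling is
$\Delta\Delta G = RT\ln(K_{d,12} K_{d,wt} / (K_{d,1} K_{d,2}))$, zero
exactly when mutational effects are multiplicative in $K_d$; the standard
error is first-order (delta-method) in the four $K_d$ errors, which is
adequate because fractional $K_d$ errors in these assays are small.

## NMR observables

Chemical shift perturbation uses the standard ¹⁵N weighting of 0.15.
Intensity-ratio classification follows a two-threshold rule: ratios below
0.5 are strongly affected; ratios between 0.5 and (mean − s.d.) are
significantly affected. The mean and s.d. are computed over all finite
ratios, including unaffected residues — the rule is a data-driven
threshold, not a test on a preselected subset. Residues with $I_0 = 0$
cannot be assessed and are excluded from the statistics.

CPMG intensities convert to rates via
$R_2^{\mathrm{eff}} = T_{\mathrm{CPMG}}^{-1}\ln(I_0/I)$ (40 ms constant
time by default). Dispersion curves are fitted with the Luz–Meiboom
two-site fast-exchange model
$R_2^{\mathrm{eff}}(\nu) = R_2^0 + \frac{\phi}{k_{ex}}\Big(1 -
\frac{4\nu}{k_{ex}}\tanh\frac{k_{ex}}{4\nu}\Big)$
against a flat no-exchange model, selected by AICc; slow-exchange
(Carver–Richards) fitting is out of scope, so $k_{ex}$ estimates are only
meaningful in the fast-exchange regime. 0 Hz entries are reference planes;
duplicated frequencies are repeat error checks and are averaged after
conversion. A methyl group is called exchanging when the fitted dispersion
amplitude $R_2^{\mathrm{eff}}(\nu_{\min}) - R_2^0$ exceeds 2 s⁻¹ — the
amplitude is evaluated at the lowest measured frequency, not the
$\nu \to 0$ limit $\phi/k_{ex}$.

## Sequence polymorphism

Per-column score
$C = \frac{-\sum_\alpha \rho_\alpha \log_2 \rho_\alpha}{\log_2 \min(N, K)}$
with $K = 20$ residue types and $N$ the residues observed at the column.
Gaps are excluded from $N$ and not counted as a 21st type — a choice, made
once: entropy should reflect substitution diversity, not alignment
geometry. The $\min(N, K)$ normalization keeps shallow columns in [0, 1].
Columns with $N < 2$ are undefined (denominator zero at $N = 1$) and
reported as missing. Positions are reported in the ungapped coordinates of
the first sequence so scores can be mapped onto structure residue
numbering.

## Markov state models

Feature trajectories (e.g. pairwise Cα distances within 15 Å of an anchor
residue) are projected by TICA: the generalized eigenproblem
$C_\tau v = \lambda C_0 v$ with symmetrized lagged covariance and a ridge
of $10^{-9}\,\mathrm{tr}(C_0)/d$ on $C_0$ for numerical rank safety.
Eigenvalues approximate autocorrelations at the lag; the leading
components isolate the slow subspace (verified on hidden two-state
processes: first-TIC alignment with the slow axis above 0.99).

Microstates come from k-means with deterministic k-means++ seeding.
Transition counts use sliding-window counting at the MSM lag; estimation
is restricted to the largest strongly connected state set, and the
reversible maximum-likelihood transition matrix is obtained by the
standard detailed-balance fixed-point iteration
$x_{ij} \leftarrow (c_{ij} + c_{ji})/(c_i/x_i + c_j/x_j)$, iterated to a
$10^{-10}$ relative tolerance. Estimated matrices satisfy
row-stochasticity to $10^{-10}$ and detailed balance with their own
stationary vector to $10^{-8}$ — these are tested invariants, not
assumptions.

PCCA+ memberships are built from the top $m$ right eigenvectors
(computed via the $\pi$-symmetrized form for numerical stability), with
inner-simplex vertex initialization followed by feasibility projection
(negative memberships clipped, rows renormalized). The full
constrained-optimization refinement of PCCA+ is not implemented: for the
well-separated metastable systems this pipeline targets, the inner-simplex
solution is already within numerical noise of crisp (block-matrix tests
show memberships above 0.99), and the projection guarantees valid
memberships in every case. Microstates are crisply assigned only when the
maximal membership exceeds 50%; the unassigned stationary mass is reported
separately rather than redistributed.

Metastable populations sum stationary probabilities over crisp members;
free energies are $G = -RT\ln(p/p_{\mathrm{ref}})$ with the most populated
metastable state as reference and a default temperature of 300 K
(configurable; all outputs carry the temperature). Coarse rates are
inverse mean first-passage times, with MFPTs from the linear system
$(I - T_{CC})h = \tau\mathbf{1}$ and $\pi$-weighted averaging over the
source state — chosen over a coarse-grained generator because MFPTs are
robust on crisp partitions and exact for two-state chains
(rate $= T_{01}$, verified analytically).

Uncertainty is by trajectory bootstrap: trajectories resampled with
replacement, the MSM and PCCA+ re-estimated per replicate on the fixed
microstate definitions, and replicate metastable states matched to the
full-data model by maximal $\pi$-weighted overlap (greedy one-to-one
matching). The 1σ interval is the replicate standard deviation. Coverage
was checked by simulation: over repeated synthetic experiments, true free
energies fall inside mean ± 2σ in at least 90% of cases.

## Structure comparison

PDB ATOM records are parsed for Cα atoms (altloc blank/'A', first model).
Chains are paired greedily by alignment score and residues by global
sequence alignment (match +1, mismatch −1, gap −2). Superposition is the
Kabsch SVD solution with the determinant sign corrected so a proper
rotation is always returned. Outlier rejection (default 5 cycles, cutoff
2× current RMSD) mimics the behaviour of structure-viewer alignment
commands; `max_cycles = 0` gives the plain all-pair Kabsch fit, for which
RMSD is symmetric in the two structures. The RMSD of a noise-σ perturbed
copy approaches $\sigma\sqrt{3}$, a useful calibration for what "below
1 Å" means: coordinate noise well under 0.6 Å per axis.

## Group statistics

The two-group comparison uses the pooled-variance Student t-test; the
pooled form is identified by its degrees of freedom $n_1 + n_2 - 2$.
Summary-statistics input (n, mean, s.e.m.) is supported and exactly
equivalent to raw values. Odds ratios for disease association are external
inputs (from genetic studies), never computed from genotype counts here;
they are regressed per association group against DM susceptibility or the
DM-susceptible-state population.

## The synthetic world

The generators emulate: exponential dissociation and saturating
association FP traces (Gaussian i.i.d. noise — the simplest model
consistent with plate-reader replicate scatter); Boltzmann melt curves;
ligand-depletion isotherms (titrations 4 µM down in 2-fold dilutions
against a 100 nM probe); Luz–Meiboom dispersion profiles over the
experimental frequency list (0–950 Hz, repeats included); alignments with
controlled column profiles; and hidden metastable jump processes emitted
into feature space with added fast-noise dimensions. Default parameter
ranges follow the assay conditions above (150 nM DM, 40 ms constant time,
Tm between 59.5 and 87.3 °C, minor-state populations of a few percent).
Every generator draws from a private seeded RNG stream and is
bit-reproducible.

What the synthetic world does *not* emulate: correlated or
heteroscedastic noise, photobleaching drifts, multi-exponential
dissociation, slow-exchange CPMG lineshapes, alignment gaps/indel
structure, non-Markovian memory in the feature dynamics, and any
structural realism for specific allotypes. A green end-to-end test
therefore establishes correctness of the estimators under their stated
models, not robustness to every experimental artifact.

## Numerical choices and degenerate inputs

Nonlinear fits use `nls` (port algorithm, bounded below where physics
demands positivity) with data-driven starting values; non-convergence is
an error carrying diagnostics, never a silent fallback. Flat dissociation
traces and equal-plateau melt curves are handled explicitly. PCCA+ refuses
degenerate spectra at the cut (requesting more metastable states than the
spectral gap supports). MFPT targets that are unreachable give rate 0 with
a warning. All error conditions are classed conditions
(`mhc2x_invalid_parameter`, `mhc2x_fit_failure`,
`mhc2x_insufficient_data`, ...) so callers can branch on them.

## Known limitations

- Fast-exchange-only CPMG fitting; no Carver–Richards model.
- PCCA+ without the optimization refinement step (see above).
- The demo pipeline's MSM stage runs on synthetic ensembles; real
  conformational ensembles require externally generated trajectories,
  which the MSM functions accept directly.
- No mmCIF structure input; PDB ATOM records only.
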