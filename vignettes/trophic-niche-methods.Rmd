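---
title: "Methods: trophic-niche analysis of small eukaryotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trophic-niche analysis of small eukaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixoniche)
```

This vignette documents the models behind `mixoniche`, the assumptions
they make, the defaults and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical conventions used
throughout. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Copy-number correction

18S rRNA gene counts overweight taxa with many gene copies per cell. The
correction model is a per-group ordinary-least-squares line of copies per
cell on cellular biovolume $V$ (µm³),

$$\text{copies/cell} = a_g + b_g V,$$

fitted separately for dinoflagellates, diatoms and all other eukaryotes
(the three groups that differ most in copy-number inflation). The
correction factor is the line evaluated at a reference biovolume,
$\mathrm{C.F.}_g = a_g + b_g V_\mathrm{ref}$, and gene counts are divided
by it: $\text{cells} = \text{genes}/\mathrm{C.F.}_g$.

**Choices and rationale.**

* *Linear axes* are the default because the calibration relationship is
  specified as a linear correlation; a log–log variant is available
  (`log_log = TRUE`) for users whose calibration spans wider biovolume
  ranges, where multiplicative error structure is more plausible.
* *Free intercept.* Nothing forces the line through the origin; a cell of
  vanishing biovolume with zero rRNA copies is a modelling fiction, and a
  free intercept lets the data decide. If the fitted line goes
  non-positive at $V_\mathrm{ref}$ the fit errors and points the user to
  the log–log option, which is positive by construction.
* *$V_\mathrm{ref} = 65$ µm³* matches the boundary of the 65–523 µm³
  calibration range appropriate for 0.8–5 µm filtered communities; it is
  configurable.
* Correction is applied at *group granularity* (three groups), because
  per-lineage copy numbers are rarely known; a per-lineage override table
  is supported where they are.
* The shipped default map is
  `r paste(names(cf_preset()), cf_preset(), sep = " = ", collapse = ", ")`
  copies per cell; a second literature-derived preset
  (`cf_preset("martin2022")`) supports sensitivity analysis. Because the
  correction is a per-group division, the *within*-group composition is
  invariant to it — only between-group shares change.

## 2. Trophic annotation

Lineages are annotated by exact-name lookup in a curated table at species
rank, falling back to genus, then family; the resolving rank is recorded.
Matching is case-sensitive after whitespace normalisation, and
reference-database placeholder names ("Chrysophyceae_Clade_G_sp.") match
verbatim at species rank. Conflicting entries (one taxon, one rank, two
modes) error when the table is built, so assignment itself is
deterministic and independent of table row order.

The exclusion policy removes, before any trophic statistics: Ciliophora,
Radiolaria and Foraminifera (their reads derive mostly from large cells
outside the small-mixotroph size fraction) and the unannotatable pool
(unknown-eukaryote placeholders, Fungi, Amoebozoa, and the parasitic
Syndiniales). Non-Syndiniales dinoflagellates are retained; an explicit
lineage blocklist handles finer-grained parasite removal. Lineages that
survive exclusion but find no annotation are kept with mode `unknown`:
they count toward the community total but never toward M/A/H.

## 3. Trophic indices

For sample $s$ and mode $g \in \{M, A, H\}$,

$$\mathrm{TI}_g(s) = \frac{\sum_{\ell:\ \mathrm{mode}(\ell)=g} x_{s\ell}}
                          {\sum_{\ell \in \mathcal{D}} x_{s\ell}},$$

where the denominator set $\mathcal{D}$ is, by default, *all retained
lineages* including unknowns, so the three indices sum to at most 1. The
default was chosen because global index triplets computed this way need
not sum to one — which matches how such tables are usually reported —
while the `annotated_only` denominator (indices summing to exactly 1) is
provided for sensitivity. Indices are invariant to any uniform rescaling
of a sample's abundances, so they are comparable between gene and cell
scales even though their values differ by the copy-number weights.

Surface-versus-depth contrasts pair samples by station and test the
within-station difference with a paired $t$-test (df = pairs − 1),
chosen because the paired design removes between-station variance; a
paired Wilcoxon signed-rank test is reported alongside as a
distribution-free companion. The statistic is positive when the surface
mean exceeds the depth mean. Identical vectors are a degenerate case
(zero-variance differences) and are reported as statistic 0, $p = 1$
rather than an error. Regional summaries report the median across
stations (the headline convention) with the mean alongside.

## 4. Environmental preprocessing and niche statistics

**Preprocessing.** Missing entries of each variable are replaced by that
variable's mean (computed before any transform, so imputation never
moves the mean), then log10-transformed. Variables containing zeros use
a shifted log, $\log_{10}(x + \varepsilon)$ with $\varepsilon$ = half
the smallest positive observed value — small enough to preserve order of
magnitude, large enough to keep zeros finite — and the shift is recorded
per variable. Imputation is done per analysis dataset (surface-only
versus surface-plus-depth are imputed separately). Whether the variables
are additionally z-scored is exposed as a flag; PCA defaults to
correlation-based axes (`scale. = TRUE`) because the 29 registry
variables carry wildly heterogeneous units.

**PCA** uses the standard singular-value decomposition of the centred
(optionally scaled) matrix with one added convention: each component is
flipped so its largest-magnitude loading is positive. This makes loading
tables deterministic across platforms and runs.

**Smoothers.** Index-versus-gradient trends use a penalised cubic
regression spline (basis dimension 10, smoothness by generalised
cross-validation — GCV was chosen over REML as the classical default for
this type of exploratory smoothing). The trend shape is classified from
the sign pattern of the fitted first derivative on a 200-point grid,
with a dead-band of 5% of the fitted range per unit gradient so that
numerically tiny wiggles do not break monotonicity; patterns other than
monotone/unimodal/flat are labelled `complex` rather than forced into a
category.

**Regressions.** Single-variable regressions are OLS with an optional
log10 predictor transform (mirroring how nutrient and light gradients
are usually displayed). The stepwise screen is bidirectional from the
intercept-only model minimising AIC (BIC by flag). AIC deliberately
tolerates some false inclusions on pure noise (around 15% of candidate
variables); users wanting a conservative screen should use the BIC flag,
whose null false-selection count is near zero — the unit tests assert
both behaviours. Benjamini–Hochberg q-values are emitted for the
marginal single-variable battery, because a 29-variable screen at
α = 0.05 would otherwise produce ~1.5 false positives per response.

**Redundancy analysis.** The species matrix is Hellinger-transformed
(square root of row-relative abundance; gives each sample a
unit-L2-norm composition, making Euclidean ordination appropriate for
compositional count data). Species are then reduced by Escoufier
equivalent-vectors selection: greedily add the species maximising the RV
coefficient between the selected sub-matrix and the full matrix, stop at
RV ≥ 0.9. Environmental variables pass two screens — a marginal
permutation test (999 permutations of the single-variable constrained
variance, α = 0.05, seeded so p-values are bit-reproducible) and
iterative removal of the largest variance inflation factor until all
VIF ≤ 10. These concrete screens are standard practice; the analysis
they implement names no specific test. The RDA core is multivariate OLS
of the centred species matrix on the centred surviving variables
followed by an SVD of the fitted matrix; sample scores are $UD$, species
scores $V$, and environment arrows are correlations of the constraints
with the sample scores. The constrained-variance fraction
$\|\hat{Y}\|^2/\|Y_c\|^2$ is invariant to affine rescaling of the
constraints. If no variable survives, an unconstrained ordination is
returned with a warning instead of an error.

**ANOVA.** Culture rates are tested with single-factor ANOVAs per factor
and multi-factor main-effects ANOVAs per requested combination, with the
conventional df bookkeeping (numerator df = levels − 1 per factor,
denominator df = residual df).

## 5. Culture kinetics

For a time series of grazer concentration $G_t$ and prey concentration
$P_t$ (cells mL⁻¹):

* **Growth**: $\mu_{\max}$ is the maximal OLS slope of $\ln G$ versus
  time over all contiguous windows of ≥ 3 points (windows containing
  non-positive counts are skipped). Reported in h⁻¹ and d⁻¹.
* **Stationary onset**: the first index from which every local ln-slope
  stays below a threshold (default 0.005 h⁻¹, roughly a tenth of typical
  maximal growth rates). Rate means cover only pre-stationary intervals.
* **Ingestion**: $I = (P_t - P_{t+1}) / (\Delta t \cdot \bar G)$ with
  $\bar G$ the arithmetic mean of the interval's endpoints
  (prey grazer⁻¹ h⁻¹).
* **Clearance**: $C = I / \bar P$ (mL grazer⁻¹ h⁻¹; also reported in
  nL), and biovolume-specific clearance $C \cdot 10^{12} / V$ body
  volumes h⁻¹ for grazer biovolume $V$ in µm³ (1 mL = 10¹² µm³).
  Clearance is the headline grazing metric because at prey
  concentrations above ~10⁶ cells mL⁻¹ ingestion saturates while
  clearance approaches its maximum.

Negative per-interval ingestion (prey growth exceeding grazing) is kept
and flagged, and means are reported both with and without those
intervals; clipping to zero is available but off by default, since
silently discarding negative intervals biases the mean upward.
Correction against a grazer-free control (scaling the expected
no-grazing prey by the control's relative change over the matching
interval) is implemented but off by default: both behaviours are
defensible and the choice is left explicit to the user.

## 6. What the generators emulate — and what they do not

**Community generator** (`simulate_community`). Stations fall into four
latitudinal bands with surface medians of light (25.4 / 24.3 / 14.7 /
18.8 mol photons m⁻² d⁻¹), nitrate+nitrite (0.89 / 0.03 / 0.13 / 17.3
µmol L⁻¹), heterotrophic bacteria (4.9 / 3.9 / 5.3 / 4.5 × 10⁵ cells
mL⁻¹), temperature and salinity, with station counts proportional to
36 / 17 / 37 / 14 and log-normal within-band spread. The true mixotroph
index follows a logistic link on log light and log nutrients
standardised against the surface samples,
$\mathrm{logit}\,\mathrm{TI}_M = a_0 + \beta_\mathrm{PAR} z(\log \mathrm{PAR}) + \beta_N z(\log N) + \epsilon$,
with defaults $\beta_\mathrm{PAR} = +0.5$, $\beta_N = -1.0$ and logit
noise sd 0.2; the autotroph/heterotroph remainder is split at a fixed
share and 3% of the community is carried by unannotated lineages.
Depth-layer samples (61 of 104 stations by default) receive mildly
shifted light/nutrient values plus a small extra logit shift (−0.2), so
the surface-versus-depth contrast has the expected sign without
double-counting the environmental effects. Cell abundances are spread
over lineages with log-normal weights, inflated into gene abundances by
the group correction factors, and multinomially resampled to a
sequencing depth of 10⁵ reads (compositional count noise); with
`resample = FALSE` and `cf_noise_cv = 0` the gene table is exactly the
cell table times the factors, which is what makes machine-precision
end-to-end recovery testable. The remaining registry variables are
plausible-scale noise, partly band-driven; they emulate dimensionality,
not oceanography.

Not emulated: spatial autocorrelation, seasonality, phylogenetically
structured taxon sampling, chimeras/contamination, or any mechanistic
link from bacteria to the indices. A passing recovery test therefore
shows the *pipeline's* correctness under the stated statistical
structure, not that real communities follow that structure.

**Culture generator** (`simulate_culture`). Integrates
$dP/dt = r_P P - c(P) P G$, $dG/dt = \mu G$ on a 0.1 h grid (fourth- or
fifth-order Runge–Kutta via `deSolve`), samples every 12–24 h, and
applies log-normal measurement noise of configurable CV. Grazer growth
is decoupled from ingestion ($\mu$ constant) to keep the ground truth
analytically simple; a saturating functional response (clearance capped
above a prey threshold) is available but off by default for
identifiability. The prey's intrinsic net rate defaults to 0, so the
grazer-free control is flat and the true clearance is identifiable
without control correction. Defaults: prey 2 × 10⁶ cells mL⁻¹ (the
prey-saturated regime of these assays), clearance 2 × 10⁻⁶ mL grazer⁻¹
h⁻¹, $\mu = 0.04$ h⁻¹, grazer inoculum 2 × 10³ cells mL⁻¹ — chosen so a
96 h experiment ends near 9 × 10⁴ grazers mL⁻¹, inside the 10⁴–10⁵
range typical of prey-supplemented cultures. The inoculum matters
beyond realism: the noise on an interval's clearance estimate scales
inversely with the grazer concentration, so the low-$G$ early intervals
dominate the error of the interval-averaged clearance; at this inoculum
the estimator's documented precision envelope (noise-free recovery
within ~6%, and replicate-mean recovery within 25% in the large
majority of noisy runs) holds, which the acceptance checks verify by
simulation.

## 7. Numerical conventions and degenerate inputs

* All generators take an integer seed and reproduce output
  bit-identically (R's default Mersenne-Twister); permutation p-values
  in the RDA are likewise seeded.
* Zero-sum samples: Hellinger emits zero rows with a warning; trophic
  indices flag the sample and return `NA`.
* Gene-mode tables are validated as integer-valued counts when read from
  disk; the noise-free simulator output is exempt (its exact gene values
  are cells × a fractional factor) via `check_integer = FALSE`.
* Exact fits (two calibration points, perfect regressions) are
  legitimate inputs; the perfect-fit warnings R's `summary.lm` would
  emit are suppressed where they are expected.
* Degenerate paired tests (zero-variance differences) return statistic 0
  and $p = 1$; degenerate copy-model fits (fewer than two distinct
  biovolumes) error.
* Problem sizes in the tests and acceptance script — 104 stations / 100
  replicate simulations for the power checks, 500 calibration
  replicates for coverage, 200 noisy culture runs — were chosen as the
  smallest sizes at which the binomial/Monte-Carlo error of the checked
  proportions is comfortably below the asserted margins.

## 8. Known limitations

* Trophic annotation reflects *potential*, not in-situ activity; the
  package inherits that interpretive limit from the annotation approach.
* The copy-number model is a three-group linear approximation; real
  copy-number variation is lineage-level and partly environmental.
* The stepwise screen with AIC is exploratory; its selections should be
  read together with the q-values of the marginal battery.
* The RDA screening defaults (permutation test, VIF ≤ 10) are standard
  but not canonical; both thresholds are exposed.
* The culture estimator's accuracy degrades when prey is strongly
  depleted within a sampling interval (the arithmetic interval means
  overestimate the effective concentrations); shorter sampling intervals
  or the control-correction flag mitigate this.
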