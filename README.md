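# mixoniche

Trophic-niche analysis of small marine eukaryotes from 18S rRNA
metabarcoding surveys, plus growth/grazing kinetics for cultured
mixotroph isolates.

## The problem

Pico- and nano-sized eukaryotes dominate open-ocean microbial food webs.
Many of them are *constitutive mixotrophs* — small flagellates that keep
their own chloroplasts but also ingest bacterial prey — and so compete
with strict autotrophs for nutrients and light, and with strict
heterotrophs for prey. Metabarcoding surveys make it possible to ask, at
ocean scale, where each trophic strategy wins. Two methodological hurdles
stand in the way:

1. **Gene counts are not cell counts.** 18S rRNA gene copy number per
   cell spans orders of magnitude across taxa (dinoflagellates carry
   thousands of copies; many small flagellates a handful), so raw read
   counts systematically overweight copy-rich groups.
2. **Trophic mode is not observable from the amplicon.** Each lineage
   must be annotated as mixotroph (M), autotroph (A) or heterotroph (H)
   from curated literature knowledge, with taxonomic-rank fallback.

`mixoniche` packages the full workflow:

* **Copy-number correction.** For each group *g* (dinoflagellates,
  diatoms, other eukaryotes) an ordinary-least-squares model
  `copies/cell = a_g + b_g · V` is fitted to calibration data of copies
  per cell versus cell biovolume `V` (µm³). The correction factor is the
  line at a reference biovolume, `C.F._g = a_g + b_g · V_ref`
  (`V_ref = 65` µm³ by default), and cell abundances are
  `cells = genes / C.F._g`. A default map
  `{dinoflagellate: 59.3, diatom: 10.5, other: 4.7}` is shipped, with an
  alternative literature preset for sensitivity analysis.
* **Trophic indices.** Per sample, `TI_g = Σ abundance(mode g) / T`,
  where the community total `T` by default includes unannotated lineages
  (so `TI_M + TI_A + TI_H ≤ 1`), with an annotated-only denominator as an
  option. Paired surface-versus-chlorophyll-maximum comparisons use a
  paired *t*-test (df = pairs − 1) with a Wilcoxon companion.
* **Niche statistics.** Environmental tables (29-variable registry) are
  mean-imputed and log10-transformed, then analysed with PCA
  (deterministic sign convention), penalised-spline smoothers of TI over
  PC axes (shape classification from the fitted derivative),
  single-variable and AIC-stepwise regressions, and redundancy analysis
  of Hellinger-transformed species matrices with Escoufier RV-based
  species selection, permutation significance screening and VIF
  collinearity screening.
* **Culture kinetics.** From grazer–prey batch-culture time series:
  maximal exponential growth rate (max window slope of ln cells vs
  time), per-interval ingestion
  `I = (P_t − P_{t+1}) / (Δt · mean(G_t, G_{t+1}))` (prey grazer⁻¹ h⁻¹),
  clearance `C = I / mean(P_t, P_{t+1})` (mL grazer⁻¹ h⁻¹),
  biovolume-specific clearance `C · 10¹² / V`, averaged over
  pre-stationary intervals, plus treatment ANOVAs.
* **Synthetic data.** Seeded generators emulate the survey (latitudinal
  bands with realistic light/nutrient/bacteria medians and a logistic
  light/nutrient control on the mixotroph index) and the cultures
  (grazer–prey depletion dynamics integrated on a 0.1 h grid), with
  ground truth returned for every quantity the pipeline estimates.

## Worked example

```r
library(mixoniche)

sim  <- simulate_community(community_sim_config(), seed = 42)  # 104 stations, 61 with depth samples
asn  <- assign_modes(sim$taxonomy, sim$db)                     # species -> genus -> family lookup
cells <- gene_to_cell(sim$abundance, sim$taxonomy)             # divide by group C.F.
ti   <- compute_ti(cells, asn)
ti
#> Trophic indices for 165 samples (cell abundances, denominator = all_retained)
#>   medians: TI_M 0.250 | TI_A 0.221 | TI_H 0.497

compare_layers(ti, sim$env, "TI_M")
#> Paired SUR vs CML comparison of TI_M (61 station pairs)
#>   medians: SUR 0.314 vs CML 0.167
#>   paired t = 11.119, df = 60, p = 3.31e-16 (Wilcoxon p = 1.2e-11)

regress_ti(ti$TI_M, sim$env$no3_no2, log_x = TRUE, predictor = "nitrate+nitrite")
#> TI ~ log10 nitrate+nitrite: slope -0.1543 (95% CI -0.1738 to -0.1348), p = 3.48e-34, R^2 = 0.599, n = 165
```

The mixotroph index is higher in the light-rich, nutrient-poor surface
layer and falls with increasing nitrate+nitrite — the niche signal the
generator encodes and the statistics recover.

Culture side:

```r
cu <- simulate_culture(culture_sim_config(), seed = 42)
grazing_rates(cu$series[[1]])
#> Grazing rate estimates ('r1', 8 pre-stationary interval(s))
#>   mu_max: 0.04 h^-1 (0.96 d^-1)
#>   mean ingestion: 2.038 prey grazer^-1 h^-1
#>   mean clearance: 1.877e-06 mL (1.877 nL) grazer^-1 h^-1
#>   biovolume-specific clearance: 1.877e+04 body volumes h^-1
```

The simulator's true clearance is 2e-6 mL grazer⁻¹ h⁻¹; the
interval-based estimator lands within its documented ~6% discretisation
error.

## Layout

* `R/` — implementation (I/O, copy correction, annotation, indices,
  niche statistics, RDA, kinetics, simulators)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/trophic-niche-methods.Rmd` — models, assumptions, parameter
  choices, limitations
* `inst/extdata/` — the 29-variable environment registry and a small
  demonstration trophic-annotation table
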