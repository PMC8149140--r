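# introtroph

Quantitative population biology and trophic ecology for multi-population
fish studies — built around the comparison of purebred and introgressed
(hybrid-swarm) *Barbus* populations, and usable for any study with the same
design: several river populations, per-fish length/weight/age records, gut
contents by the relative-fullness method, bulk stable isotopes, and two-pass
electrofishing catches.

It is aimed at fish ecologists who want the full published workflow as
tested, reusable functions rather than a one-off script pile.

## What it computes

**Growth.** Von Bertalanffy length-at-age, `TL = L∞(1 − e^{−K(t − t0)})`,
fitted by least squares to mean length-at-age under all 8 parameter-sharing
structures (each of L∞, K, t0 shared across populations or not) and ranked
by small-sample corrected AICc. Length–weight relations
`log10 W = log10 a + b log10 TL` with isometry t-tests (`b = 3`), ANCOVA
across populations, residual body condition, and a length/age MANOVA
(Pillai's trace).

**Diet.** Vacuity index, mean gut fullness, Amundsen–Costello feeding
strategy (`Fi% = 100 Ni/N` vs `Pi% = 100 ΣSi/ΣSti`), per-fish Shannon `H`,
arcsine-√ transformed Bray–Curtis distances, nMDS with 40 % core-niche
standard ellipses, one-factor PERMANOVA, SIMPER, and exact sample-based
prey accumulation curves.

**Isotopes.** C:N lipid screening (flag at 3.5), pooled one-baseline
macroinvertebrate references, deterministic trophic position
`TP = 2 + (δ15N_fish − δ15N_BMI)/4.2` and corrected carbon
`C_corr = ((δ13C_fish − Δ13C) − δ13C_BMI)/CR`, a Bayesian one-baseline TP
model (Gibbs-within-Metropolis, TDF prior `N(4.2, 0.2²)` ‰), and isotopic
niches as standard ellipse areas `SEA = π√det(S)` with exact conjugate
Bayesian draws (`SEA_B`), posterior exceedance comparisons and ellipse
overlap.

**Communities.** Two-pass removal abundance `N̂ = C1²/(C1 − C2)`
(Moran–Zippin) with SE, densities per m², richness, Shannon diversity and
Bray–Curtis dissimilarity between sites.

**Synthetic data.** `default_study_configs()` encodes a four-population
study (two purebred, two introgressed; shared `K = 0.24`, L∞ of
34.4–45.7 cm, published diet/isotope contrasts); `simulate_study()` draws
deterministic, seeded datasets so the whole pipeline is testable without
field data.

## Worked example

```r
library(introtroph)
bundle <- run_all(run_config(seed = 1, tdf_c = 2.0))
cat(report_summary(bundle), sep = "\n")
```

Abridged output of this exact call:

```
## Growth model selection (dAIC)
- Linf*/K/t0*  (k=9, SSE=3.470, dAIC=0.00)
- Linf/K*/t0*  (k=9, SSE=4.000, dAIC=2.70)
...
- Linf*/K*/t0*  (k=12, SSE=2.760, dAIC=46.95)

## Diet
- TLp: N=22, vacuity=0%, fullness=83 +/- 18%, H=1.83 +/- 0.11, nMDS ellipse=0.00
- TLi: N=19, vacuity=26%, fullness=30 +/- 30%, H=1.22 +/- 0.21, nMDS ellipse=0.07
- PERMANOVA: F3,69 = 25.33, R2 = 0.52, p = 0.001

## Isotopes
- PVp: d15N=9.0 +/- 0.7, TP=3.4 (3.2-3.6), SEA_B=0.07 (0.04-0.14)
- TLi: d15N=11.9 +/- 1.5, TP=2.3 (2.1-2.6), SEA_B=0.37 (0.22-0.70)
```

Reading it: the shared-K structure (`Linf*/K/t0*` — population-specific L∞
and t0, common K) wins model selection, i.e. the introgressed populations
reach larger asymptotic sizes while growing at the same rate; the
introgressed TLi population has the emptiest guts (vacuity 26 %, fullness
30 %), the least diverse but widest diet (lowest H, largest ordination
ellipse — fish and plant material), the lowest trophic position (2.3 vs
2.8–3.4) and an isotopic niche ~5× larger than any other population
(SEA_B 0.37 ‰²).

Each stage is also callable on its own (`analyze_growth()`,
`analyze_diet()`, `analyze_isotope()`, `analyze_community()`), as are all
the underlying statistics (`fit_vb()`, `vb_model_selection()`,
`permanova()`, `simper()`, `tp_bayes()`, `sea_bayes()`,
`zippin_two_pass()`, ...). Input CSVs are read with `read_table()`; see
`?read_table` for the four schemas.

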