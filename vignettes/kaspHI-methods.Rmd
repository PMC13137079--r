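---
title: "From KASP fluorescence to a hybrid index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From KASP fluorescence to a hybrid index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspHI)
```

## The problem

Hybrid zones are usually mapped by genotyping many captured individuals, which
is invasive and expensive. Nuclear environmental DNA (eDNA) offers an
alternative: water from a site contains a pooled mixture of the resident
animals' DNA, so the *population-level* allele proportion at a
species-diagnostic SNP can in principle be read from a single filtered water
sample. Kompetitive Allele-Specific PCR (KASP) makes this sequencing-free:
two competing allele-specific primers drive FRET cassettes labelled with FAM
and HEX, so the end-point fluorescence of a reaction in the (FAM, HEX) plane
encodes the relative abundance of the two alleles in the template.

kaspHI implements the full analysis path from a raw per-PCR fluorescence
table to a **hybrid index (HI)** — the proportion of B-lineage
(*Triturus macedonicus*-diagnostic) alleles, 0 for a pure A-lineage
(*T. ivanbureschi*) population, 1 for pure B, 0.5 for an F1-like
composition — together with the validation statistics used to demonstrate
concordance between eDNA-derived and genotype-derived ancestry in a mesocosm
experiment, and a simulator that reproduces that experiment's design.

## The calibration model

The central quantity is the **angle** of a signal from the origin of the
(FAM, HEX) plane, `atan2(HEX, FAM)` in degrees: 0° along the FAM axis (pure
B-allele signal), 90° along HEX (pure A). Angles are invariant to the overall
amplification strength (the radius), which varies strongly between reactions;
this is why the method works on raw intensities without normalisation.

Real assays deviate from the ideal geometry: homozygote clusters sit short of
0°/90° because of residual fluorescence in the opposite channel, and unequal
primer competition displaces the heterozygote cluster away from 45° by a
SNP-specific amount. kaspHI therefore calibrates each SNP from swab samples
of animals with known genotypes:

1. **Centroids.** For each genotype class A/AB/B the centroid is the
   component-wise median (median FAM, median HEX) of the class's averaged
   signals. Marginal medians — not the geometric median — are used: they are
   the natural robust summary per fluorescence channel, and the choice is
   explicit in `compute_centroids()`.
2. **Genotype verification.** Every swab call is assigned to its nearest
   centroid (Euclidean distance). A call nearest to a foreign centroid is a
   *mismatched genotype*; exact distance ties are treated as mismatches,
   because an ambiguous call cannot validate anything. Mismatches are
   excluded together with the eDNA calls of every container housing that
   animal at that SNP; an animal mismatched at *all* evaluated SNPs (a likely
   mislabel) is removed entirely along with its containers' eDNA samples.
3. **Outlier screening.** Within each (SNP, genotype) cluster, distances to
   the assigned centroid are screened with the robust rule
   `d >= median(d) + 3 * MAD(d)`, `MAD = 1.4826 * median(|d - median|)`.
   Outliers are removed from centroid estimation only — their HI estimates
   remain in the downstream tables.
4. **Angles.** Centroids are recomputed from the retained points and
   converted to the anchors `alpha_A > alpha_AB > alpha_B`. A SNP violating
   this strict ordering is unusable and calibration fails loudly for it.

The HI map is **piecewise linear in angle** with the three anchors pinned to
HI = 0, 0.5 and 1:

```
HI(alpha) = 0.5 (alpha_A - alpha) / (alpha_A - alpha_AB)          alpha >= alpha_AB
HI(alpha) = 0.5 + 0.5 (alpha_AB - alpha) / (alpha_AB - alpha_B)   alpha <  alpha_AB
```

Outside `[alpha_B, alpha_A]` the adjacent segment is extrapolated, never
truncated: a sample slightly "beyond" a homozygote anchor gets a slightly
negative (or >1) HI. Truncation would bias the population mean toward the
interior; preserving linearity keeps averages honest. The map is continuous
and strictly decreasing over the whole real line, and `hi_to_angle()` is its
exact inverse (the simulator uses it to place eDNA signals).

Per-sample HI values are averaged across the available SNPs of a sample to
give the population-level estimate (`population_hi()`), mirroring how allele
frequencies aggregate over unlinked markers.

## Quality control and its knobs

All thresholds live in `qc_config()`:

* **Low-fluorescence triangle** — vertices (0,0), (2,0), (0,2) in raw
  intensity units. Reactions inside it are background noise or failed
  amplifications and are dropped before averaging. The boundary counts as
  inside: the region is a noise floor, and an inclusive boundary is the
  conservative choice.
* **Read-cycle selection** — end-point fluorescence is read after several
  cycle counts (e.g. 39/42/45/48/51); over-cycling promotes primer-dimer
  signal in template-free wells. `select_read_cycle()` keeps the largest
  candidate cycle at which no NTC or lab-negative well escapes the triangle.
  The triangle is used as the dimer proxy deliberately: it is the only
  quantitative noise region the framework defines. Selection is per table
  (plate-level), matching how NTCs are laid out on plates; if every cycle
  shows control signal the smallest cycle is used with a warning.
* **Replicate averaging** — the arithmetic mean (not median) of up to four
  retained replicates per sample x SNP, the stated averaging of the
  framework; groups that lose all replicates are reported as dropped.
* **Field controls** — animal-free containers sampled like real samples.
  Any out-of-triangle PCR flags the control as possible contamination; this
  is a warning, not a stop, since downstream concordance is the real
  arbiter.
* **MAD constants** — multiplier 3 and consistency constant 1.4826, both
  configurable and echoed into reports. A degenerate cluster with MAD = 0
  would void itself under the literal ">=" rule (every point ties the
  median), so there only points strictly above the median are excluded.
* **SNP retention band** — a SNP is kept when the entire 95% percentile
  bootstrap CI (B = 2000) of its median swab deviation lies within ±0.05 HI
  units, i.e. a 5% allowable systematic deviation on the HI scale.

## Statistical choices

Deviations `hi_obs - hi_exp` are non-normal in this design, so the battery
is non-parametric throughout:

* **Spearman rank correlation** per sampling regime
  (`stats::cor.test`; exact p-values for small tie-free samples, asymptotic
  otherwise).
* **Permutation ANCOVA** `hi_obs ~ hi_exp * regime` with term-wise
  Freedman-Lane permutation of reduced-model residuals, default 5000
  permutations, `p = (1 + #{F* >= F}) / (n_perm + 1)`. Only qualitative
  significance calls are comparable across implementations of permutation
  ANCOVA; exact p-value equality is not expected.
* **Kruskal-Wallis** across genotypic profiles within each regime, then
  per-profile **one-sample Wilcoxon signed-rank** tests against zero with
  Holm correction within the regime. All-zero profiles are degenerate for
  the signed-rank statistic and reported with p = 1. `stats::wilcox.test`
  defaults govern exact-vs-asymptotic switching.
* **Pairwise Fligner-Killeen** tests of variance homogeneity across profile
  pairs, Holm-adjusted over the set of pairs.
* **Bland-Altman** agreement: mean bias and 95% limits of agreement
  (mean ± 1.96 SD, n−1 denominator, the Bland & Altman 1986 convention) for
  (a) per-regime population deviations and (b) between-regime differences
  paired by population.
* **Biomass correction**: the expected HI can be recomputed weighting each
  member's genotype contribution by body mass
  (`sum(m_i hi_i) / sum(m_i)`); paired Wilcoxon tests per mixed-genotype
  profile compare absolute deviations under the two expectations.

The profile-level tests default to per sample-SNP deviations (each
sample x SNP combination one observation), which is the granularity of the
framework's accuracy figures; population-level aggregates feed the
Bland-Altman analyses. Shapiro-Wilk normality screening is left to the user
as a diagnostic; the package does not auto-select tests.

## The simulator

`simulate_experiment()` generates the full validation layout: 9 SNPs, 36
animals (9 + 9 homozygotes, 18 F1s), 18 two-animal populations in five
genotypic profiles (3/3/6/3/3 replicates), each sampled under a
low-concentration (30 L) and a high-concentration (6 L) regime, plus
no-template, lab-negative, field-negative and positive controls — 3114 PCRs
in the default layout.

Generative model, per reading:

* true per-SNP anchors drawn from Normal(82.0°, 1.13), Normal(46.6°, 6.05),
  Normal(12.9°, 1.46) — the empirical spread of homozygote and heterozygote
  centroid angles in the validated assay panel — resampled to respect the
  strict ordering;
* a swab reading sits at its (possibly corrupted) genotype angle plus
  Normal angular noise (default SD 2°), at a log-normal radius; allelic
  dropout (an F1 rendering at a random homozygote angle, default rate
  0.035) and false heterozygosity (a homozygote at the AB angle, default
  0.0127) act at the sample x SNP level because they are template
  properties shared by replicates;
* an eDNA sample draws Dirichlet shedding weights over its members
  (concentration 5 by default — moderately unequal individual
  contributions), forms the latent allele proportion `p = sum(w_i hi_i)`,
  and renders each SNP at `hi_to_angle(p)` plus regime-scaled noise
  (default SD 5°, low-concentration regime scaled 1.25x);
* any PCR fails into the low-fluorescence triangle with probability 0.045.

Observable angles are clamped to [0°, 90°] because fluorescence intensities
are non-negative. A side effect worth knowing: near the homozygous anchors
the clamp truncates the noise distribution asymmetrically, producing a
slight regression toward mid-range HI at extreme profiles — strongest in the
noisier regime. High-powered runs of the interaction term in the permutation
ANCOVA can detect this simulator artifact as a tiny slope difference between
regimes; it is a property of the generator, not of the estimation pipeline.

What the simulator does **not** emulate: radius-dependent angular precision
(weak reactions are noisier in real assays), plate and batch effects,
cross-contamination between wells, temporal eDNA accumulation or decay, and
cycle-dependent dimer growth (simulated tables carry a single, pre-selected
read cycle; the cycle-selection rule is exercised on constructed per-cycle
fixtures instead). Passing tests on simulated data therefore demonstrate the
pipeline's correctness and statistical calibration under this error model,
not field performance.

## Numerical conventions and degenerate inputs

* Triangle membership is an inclusive half-plane test with a relative
  tolerance of 1e-12 on the orientation determinants.
* Nearest-centroid ties (within 1e-12) are mismatches by design.
* `angle_of()` rejects the origin; calibration requires all three genotype
  classes per SNP and at least two points per cluster for outlier
  screening (a singleton cluster warns and is left alone).
* Empty profile groups, constant inputs to rank tests, and single-pair
  biomass comparisons are reported as untestable rather than silently
  dropped; the constant-expectation Spearman case reports an undefined rho.
* All Monte-Carlo machinery (bootstrap, permutations, simulator) is
  seed-driven and bit-reproducible under a fixed seed.

## Problem sizes used in the package's own studies

The bundled studies were sized to give stable Monte-Carlo estimates at
desk scale: parameter recovery uses 120 simulated populations x 2 regimes
(240 population samples; default-noise RMSE ≈ 0.05, |bias| < 0.01);
statistical-size calibration uses 1000 null replicates with 199
permutations per ANCOVA (the permutation p-value is exactly uniform on its
attainable grid, so nominal size holds for any permutation count); the
variance-pattern study uses 100 populations per profile (200 population
samples per profile). The acceptance script reruns the full study layout
plus the recovery study from a single seed.

## Limitations

* The pipeline estimates *population-scale ancestry*, not individual hybrid
  classes; an HI of 0.5 cannot distinguish an F1 population from a balanced
  mixture of pure parental species without multi-locus discordance
  reasoning.
* Calibration requires swab (or equivalent individual-level) references for
  all three genotype classes at every SNP.
* The ±0.05 SNP-retention band, the triangle vertices and the MAD constants
  are assay-calibrated defaults; other chemistries or plate readers may
  need different noise floors.
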