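---
title: "Methods: nitrogen-efficiency phenotyping and microbiome association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen-efficiency phenotyping and microbiome association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neffbiome)
```

## The problem

Lactating dairy cows convert only a modest share of the nitrogen they eat
into milk protein; the rest leaves in urine and feces, at both economic and
environmental cost. Nitrogen efficiency,

$$\mathrm{Neff} = \frac{\text{milk N (g/d)}}{\text{N intake (g/d)}} \times 100,$$

varies substantially between cows on the same diet, and the gastrointestinal
microbiome — both the rumen, where most dietary protein is degraded and
microbial protein is synthesised, and the hindgut, sampled through feces —
is a plausible driver of that variation. `neffbiome` implements the full
analysis chain for a divergent-phenotype study of this question: build a
per-cow nitrogen balance from on-farm measurements, split the herd into
low / mid / high Neff phenotypes, and ask whether rumen and fecal 16S rRNA
communities, or plasma amino acids, travel with the phenotype.

## The nitrogen balance

Each cow contributes one record of raw measurements; `partition_n()` turns
it into a complete N budget using five standard identities:

* **N intake** `(offered x diet CP − refused x refusal CP) / 6.25 x 1000`
  (g/d). Feed protein converts at N x 6.25. The first term uses feed
  *offered*: intake is defined as offered minus refused, so using measured
  intake there would subtract refusal N twice. The x1000 converts kg of N
  to grams and applies to the whole expression — this is forced by
  dimensional consistency with budgets reported in g/d.
* **Milk N** `milk yield x (true protein / 6.38) x 1000` (g/d); milk true
  protein converts at N x 6.38.
* **Urine volume** `29 x BW / creatinine` (L/d), using creatinine as an
  output marker with a daily excretion of 29 mg per kg of body weight;
  urinary N is volume times the (acid-stabilised) urine N concentration.
  Acidification chemistry is upstream of this package: the concentration in
  the record is taken as already adjusted.
* **Apparent digestibility**
  `100 − 100 x (marker_diet/marker_feces) x (nutrient_feces/nutrient_diet)`
  (%), with indigestible ADF as the internal marker; fecal N is the
  indigestible share of N intake, computed *per cow* from that cow's own
  marker ratio. (The alternative — one pooled digestibility for the herd —
  is a defensible design; per-cow propagation keeps the additive identities
  exact at the cow level, which is what the tests verify.)
* **Manure N** = urinary + fecal N, and **retained N** = intake − (milk +
  manure), so the budget closes exactly by construction. Manure components
  are also expressed per kg of milk; a zero milk yield flags those entries
  as undefined (NA) rather than producing infinities.

### The phenotype rule

`classify_phenotype()` labels a cow **low** when its Neff falls strictly
below `mean − 0.5 SD` of the cohort and **high** strictly above
`mean + 0.5 SD`; everything else, including exact boundary values, is
**mid**. The SD is the sample SD (n − 1). The rule is location- and
scale-invariant, so labels do not depend on the unit of Neff. Downstream
contrasts (diversity comparisons, differential abundance, correlations) use
only the low and high cows, as a divergent design intends.

## Community analysis

### Rarefaction and alpha diversity

Tables are rarefied by a single seeded draw without replacement to a fixed
depth (default 5,834 reads); samples below depth are dropped with a
warning, never padded. Metrics per sample:

* observed features (richness);
* Shannon–Weiner index **in bits**. The base-2 logarithm matters: at the
  scale reported for these communities (Shannon ≈ 7.5, richness ≈ 640)
  only base 2 makes evenness = Shannon / log2(richness) land on the
  reported ≈ 0.80; a natural log would give ≈ 5.2 and an inconsistent
  evenness. Base 2 is also the QIIME 2 convention;
* Pielou evenness `H / log2(S)`, undefined (NA) for S < 2;
* Good's coverage `1 − F1/N`. It is computed on whatever table it is
  given; the pipeline applies it to the rarefied table, and coverage before
  rarefaction is available by passing the raw table instead.

Group comparisons of alpha metrics use the Kruskal–Wallis rank test with
tie correction; an all-tied metric returns H = 0, p = 1 instead of NaN.

### Weighted UniFrac, PCoA, PERMANOVA

`weighted_unifrac()` computes, for every pair of samples,
$\sum_b \ell_b \, |p_A(b) - p_B(b)|$ over all branches $b$, where
$p_X(b)$ is the fraction of sample X's reads on tips below $b$ — the
*unnormalised* variant, matching the q2-diversity default; a normalised
variant (divide by $\sum_b \ell_b (p_A(b)+p_B(b))$) sits behind a flag.
Denominators are per-sample totals after rarefaction. Unrooted trees are
midpoint-rooted first, since the branch-mass recursion needs a root. The
implementation accumulates tip mass rootwards in postorder; the tests pin
it to a deliberately naive branch-enumeration oracle (and to an independent
implementation) at 1e-9.

`pcoa()` is classical metric scaling: Gower-centre `-d^2/2`,
eigendecompose, scale eigenvectors by the square root of positive
eigenvalues. Eigenvalues within 1e-10 of zero are snapped to zero;
negative eigenvalues (non-Euclidean distances) are reported honestly and
carry no axis — no Lingoes/Cailliez correction, so axis shares are shares
of *positive* inertia.

`permanova()` is the one-factor pseudo-F on squared distances with freely
permuted labels (no strata) and `p = (#{F* >= F} + 1)/(n_perm + 1)`;
999 permutations by default (the count is a convention — the study design
does not fix it). Its pseudo-F matches `vegan::adonis2` to 1e-10 in the
tests, and its type-I error at nominal 0.05 is calibrated on 500 null
replicates.

### Differential abundance

`lefse_da()` follows the LEfSe recipe for a class-only design (two groups,
no subclass): CPM scaling (x 1e6, so the usual threshold of 2.0 keeps its
meaning), a per-feature Kruskal–Wallis screen at **raw** p < 0.05 (LEfSe
applies no multiplicity correction at this stage), then an effect-size
filter at log10 effect >= 2.0. The canonical LDA effect size blends
discriminant-axis coefficients with class-mean differences and is
under-documented, so this package uses a documented surrogate: the mean
over 30 seeded bootstrap rounds (resampling ceiling(2n/3) per group) of
`log10(max(|mean CPM difference|, 1))`. It is monotone in the true
difference and deterministic under a seed, but it is *not* bit-compatible
with the original implementation — conclusions should rest on recovery
behaviour, not score parity.

A consequence worth stating plainly: because the screen uses raw p-values,
about 5% of truly null features reach the effect stage regardless of their
dispersion, and on overdispersed count data their selected mean differences
are large enough that the 2.0 threshold removes few of them. On synthetic
data with realistic overdispersion the procedure has excellent sensitivity
(≈ 0.97 for features planted at 10,000 CPM) but a false-discovery
proportion near 0.5. That is a property of the LEfSe-style recipe itself,
reported here honestly; `correlate_features()` applies BH-FDR downstream
precisely because this stage does not.

Differential features are then hierarchically clustered
(`cluster_features()`, average linkage, Euclidean distance on per-feature
z-scored CPM profiles; zero-variance profiles become zero rows with a
message).

### Correlations and strength bands

`correlate_features()` relates analytes or differential features to Neff:
Pearson for plasma amino acids, Spearman (Pearson on average ranks) for
relative abundances. P-values use the t approximation on n − 2 df,
adequate at the n ≈ 11 scale of divergent designs; an exact permutation p
is available (`cor_test(n_perm = )`). Benjamini–Hochberg adjustment is
applied *within a family* — rumen features, fecal features and plasma
analytes are separate families, mirroring how such results are reported
separately — and significance is declared on q <= 0.05 while the raw p is
also returned (the underlying report is ambiguous about which it gated on;
declaring on q is the conservative reading). Strength bands follow the
2-decimal reporting convention: |r| in [0.51, 0.70] moderate, [0.71, 1.00]
strong; r is rounded to 2 decimals first, which also closes the printed
gap between 0.70 and 0.71.

## The synthetic-data generator

There is no public per-cow table for such a study, so the generator
emulates the *published group-level statistics* and the analysis'
structural assumptions, not any real cow:

* **Herd** (n = 23): DMI ~ N(26.7, 2.5) kg/d on a 16.5% CP diet with 10%
  refusals; BW ~ N(633.5, 49.8) kg; milk yield 37.7 kg/d at mean DMI with
  a 1.3 kg/kg DMI slope plus N(0, 5.5) residual; true protein
  N(3.05%, 0.12%); creatinine N(730, 60) mg/L (≈ 25 L urine/d); urine N
  N(8.7, 0.9) g/L; fecal marker and N fractions tuned to ≈ 65% apparent N
  digestibility. The induced Neff distribution has mean ≈ 25% and SD ≈ 4.5,
  and the ±0.5 SD rule yields low/high groups with means near 22% and 30%.
* **Communities**: one master tree (random bifurcating topology,
  exponential branch lengths) over a universe of 1,050 ASVs of which 800
  form the rumen community and 550 the fecal one (300 shared — the
  site-specific remainder is what separates sites in UniFrac space). Base
  compositions are ranked-lognormal (a logistic-normal prior), sdlog 1.75
  (rumen) and 1.45 (feces), chosen once so that evenness (≈ 0.80 / 0.84)
  and mean Good's coverage at depth 5,834 (≈ 0.99, above the 0.97 the
  design requires) match the published scale. Counts are
  Dirichlet-multinomial with concentration 200 around the base, at
  N(20,000, 2,000) reads per sample.
* **Planted signal**: `n_differential` features per site (default 20) are
  shifted by `effect_cpm`/1e6 (default 2,000 CPM) in the enriched group's
  base composition, alternating enrichment direction, then renormalised;
  the additive construction cannot push a proportion negative. The default
  effect is deliberately small (total planted mass 4%): community-level
  phenotype PERMANOVA must stay null while feature-level tests can find
  the planted features — exactly the published pattern. The recovery
  benchmark raises the effect to 10,000 CPM.
* **Plasma**: a 19-analyte panel at plausible bovine concentrations, with
  a Gaussian-copula Gln analyte at target r = +0.59 and a Trp analyte at
  −0.61 with Neff (the published correlations); everything else is
  independent noise.

One master seed drives everything; each generator draws from a substream
at a fixed offset, so adding or reordering calls cannot silently change
another component's stream, and the generator's phenotype labels are
produced by the same ±0.5 SD rule the classifier applies — the two cannot
drift apart.

### What the emulation does and does not show

Passing tests on this generator demonstrate that the *pipeline* recovers
what was planted under realistic overdispersion and sample sizes. They do
not validate denoising, taxonomy, or any real biology; and two published
quantities are knowingly not matched: per-sample observed richness
(≈ 250 at depth 5,834 versus ≈ 640 reported — single-sample compositions
under concentration 200 are much steeper than the base composition), and
the specific counts of differential ASVs, which depend on the real
sequencing data. Reproducing those would require the deposited raw reads
and the full denoising stack, which is outside this package's scope.

## Problem sizes and numerical choices

The shipped tests run the full default study (23 cows, 800/550 features,
20,000 reads) where a single run suffices, and reduced replicate counts
where a rate is being estimated: 500 null replicates for PERMANOVA size
(12 samples, 199 permutations each), 20 seeded replicates for
differential-feature and plasma recovery, 200 random ≤ 16-tip trees for
the UniFrac oracle. Ties in ranks use average ranks throughout; boundary
phenotype values go to mid; eigenvalue cleanup snaps |λ| < 1e-10 to zero;
the permutation p never reaches zero by construction. All file output is
plain text (TSV/CSV/JSON/newick) with a version + seed + config-hash
header, and re-running with the same configuration reproduces byte-identical
numeric payloads.

## Interfaces

This is an analysis package rather than a shell tool: the exported
functions, `run_pipeline()` (which chains every stage and can write the
full artifact set to a directory) and the repository's
`scripts/acceptance.R` are its command surface. Readers and writers cover
the interchange formats: `#FeatureID`-sentinel TSV feature tables
(features x samples on disk, samples x features in memory), newick trees,
herd and partition CSVs, labelled distance-matrix TSVs, and a JSON truth
ledger for synthetic studies.
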