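---
title: "Association mapping in structured inbred germplasm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping in structured inbred germplasm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structAM)
```

## The problem

Breeding germplasm panels of self-pollinated crops such as barley are small,
highly structured collections: growth habit (winter vs spring, i.e.
vernalization sensitivity) and inflorescence type (two-rowed vs six-rowed)
are themselves the main axes of population structure. Mapping the genes for
exactly those traits by marker–trait association is therefore the hardest
case for association mapping — any correction for structure also absorbs the
signal of interest. Two genetic architectures make it harder still:
vernalization sensitivity is controlled epistatically by three loci (only
one of the eight dominance combinations is sensitive), and the six-rowed
phenotype arises from several independent loss-of-function haplotypes at one
locus, so no single SNP tags it.

`structAM` implements the full analysis chain for this setting — marker QC,
structure and kinship correction, four nested single-marker models, an
FDR-gated all-pairs interaction scan, LD-decay extent estimation, and
"synthetic" allele-type markers that summarize a gene's functional state —
together with a founder-mosaic germplasm simulator that reproduces the
statistical structure of such panels with known ground truth, so every claim
the package makes can be tested by recovery.

## Single-marker models

For a trait $y$ (days to flowering, censored; or row type coded 0/1) and a
marker genotype $g \in \{0, 1\}$ (inbred lines carry one allele per locus),
the four nested models are

* **M**: $y = \mu + \beta g + e$
* **M+Q**: $y = \mu + \beta g + Q\gamma + e$
* **M+K**: $y = \mu + \beta g + u + e$, $u \sim N(0, \sigma^2_g K)$
* **M+Q+K**: $y = \mu + \beta g + Q\gamma + u + e$

where $Q$ holds structure covariates (principal-component scores of the
column-standardized genotype matrix, 2 axes by default — the number that
separates the major germplasm groups) and $K$ is the relative-kinship
matrix. M and M+Q are ordinary least squares with an F-test on the marker
term. The kinship models are linear mixed models fitted by **maximum
likelihood**, not REML: the downstream interaction analysis compares models
that differ in fixed effects, and only ML likelihoods are comparable there,
so the whole chain uses one likelihood convention.

`ml_mixed_fit()` rotates the model by the spectral decomposition
$K = U D U^\top$, after which the profile log-likelihood depends on the
single variance ratio $\delta = \sigma^2_g / \sigma^2_e$; $\delta$ is
optimized on the log scale over $[e^{-12}, e^{12}]$ with the boundary
$\delta = 0$ checked explicitly. Eigenvalues pushed slightly negative by
flooring the empirical kinship are clamped to zero. In the default scan
mode the variance components are estimated once under the no-marker null
and reused across markers (the standard population-parameters-previously-
determined approximation); each marker is then tested by a Wald/F statistic
on its GLS coefficient. An `exact = TRUE` mode refits every marker on its
complete cases with per-marker variance components and serves as the
reference implementation in the tests, where the fast scan is checked
against it. Missing genotype calls are mean-imputed per marker in the fast
scan; binary traits run through the same linear machinery on the 0/1 scale
(a deliberate simplification — logistic alternatives are out of scope).

Per-trait scans are Benjamini–Hochberg adjusted (`fdr_adjust()`), with
monomorphic markers excluded from the adjustment.

## Loiselle kinship

The relative kinship of accessions $i, j$ uses the Loiselle et al. (1995)
allele-frequency correlation estimator. With panel allele frequency $p_l$
at locus $l$, individual allele "frequencies" $x \in \{0,1\}$
(haploid-coded inbred lines), and $n_l$ typed individuals,

$$F_{ij} = \frac{\sum_l \left[ (x_{il}-p_l)(x_{jl}-p_l) +
  \frac{p_l(1-p_l)}{n_l - 1} \right]}{\sum_l p_l (1-p_l)},$$

i.e. frequency-centered cross-products with the small-sample bias term,
locus-weighted by the polymorphic-information denominator, both sums
running over the pair's co-observed loci only. Reference frequencies come
from the analysis panel itself. Negative coefficients mean "less related
than two random members of the panel"; `floor_negative()` sets them to
zero before the matrix enters a mixed model. A naive loop implementation
written independently of the package serves as the correctness oracle in
the tests (agreement to 1e-10 on toys with missing data).

## Linkage-disequilibrium extent

For every marker pair, $r^2$ is computed from the 2×2 haplotype count
table over pairwise-complete accessions (inbred lines expose haplotypes
directly) with a two-sided Fisher exact p-value. Pairs on different (or
unknown) chromosomes are "unlinked" and calibrate the significance
baseline: their $r^2$ values are Box-Cox transformed (maximum-likelihood
$\lambda$ on a grid of step 0.01; a fixed shift of $10^{-6}$ keeps zero
values positive, and the same shift is removed after back-transformation),
and the parametric 95th percentile (mean + 1.645 sd on the transformed
scale, back-transformed) becomes the threshold above which same-chromosome
LD is attributed to linkage. Fewer than 30 unlinked values trigger a
fallback to the empirical 95th percentile with a warning; degenerate
all-equal input is declared not estimable.

Same-chromosome pairs significant at p < 0.001 enter a degree-2 loess fit
of $r^2$ on cM distance (span 0.5 by default — the degree and confidence
level are fixed by the method, the span is a reported knob) with pointwise
90% bands. The **extent of LD** is the smallest distance at which the
fitted curve crosses the threshold from above, located by linear
interpolation on a 0.01 cM grid; the band crossings give the confidence
interval. The estimate is declared not estimable when fewer than 10
significant pairs exist, when all significant pairs sit at $r^2 = 1$ (a
threshold of 1 cannot be crossed — the small winter-germplasm situation),
or when the curve never exceeds the threshold. Per-chromosome estimates
and their unweighted mean are both reported, since a panel-wide "average
extent" necessarily averages over chromosomes. On sparse maps (marker
spacing comparable to the decay scale) the estimate is frequently not
estimable; the decay-recovery property is therefore validated against a
synthetic exponential-decay process with known scale, where the 90% CI
covers the true scale in ≥80% of seeds.

## Interaction scan

Markers with FDR-adjusted M+Q+K p-values strictly below 0.20 are gated
into an all-pairs scan ($n(n-1)/2$ pairs). Whether the published gate
applied to raw or adjusted p-values is ambiguous; the package defaults to
adjusted and logs both counts (`select_candidates(use = "raw")` switches).
For each pair the likelihood-ratio statistic is

$$\Lambda = (-2\ell\ell)_{\text{reduced}} - (-2\ell\ell)_{\text{full}},
\qquad \text{full: } y \sim Q + g_a + g_b + g_a g_b,\quad
\text{reduced: } y \sim Q,$$

both fitted by ML on the pair's complete-case accessions. Kinship is
deliberately absent from both models — the reduced model contains only the
population structure. $\Lambda$ is referred to $\chi^2_{df}$ with $df$
equal to the difference in *estimable* fixed-effect parameters: 3 for two
complete biallelic markers, fewer when a genotype cell is empty or a term
aliased (the fit counts ranks rather than columns). For a binary trait, a
full-model residual sum of squares of zero means the four genotype
combinations predict the trait without error: the pair is flagged
`perfect_flag` with p = 0 and an undefined $-\log_{10} p$.

Results are **competition-ranked**: perfect predictions first, then by
statistic descending; values tied within $10^{-9}$ share the lowest rank
and the next distinct value skips (1, 1, 3, 3, 5). Null calibration is
checked by simulation: with a structure-only trait the LRT mean matches
its df to within Monte-Carlo error (the small upward bias of ML likelihood
ratios at n = 100, about 5%, sits inside that band).

## Haplotypes and allele-type markers

`call_haplotypes()` groups equal-length aligned gene sequences into
equivalence classes (haplotypes, numbered by first occurrence after
sorting accession ids, so input order never matters). Gap characters are a
distinct state for equivalence — deletion alleles are haplotype-defining —
but are excluded when counting SNP sites. `build_allele_type_marker()`
collapses haplotypes or feature tables (gene presence/absence, deletion
type) to one dominant/recessive call per accession, driven entirely by a
rule table: the biological mapping is data, not code, and an observed
haplotype with no rule entry yields a missing call rather than a guess —
novel alleles need an explicit judgment, as with loss-of-function alleles
whose state cannot be derived from sequence similarity automatically.
`multilocus_haplotypes()` enumerates observed combinations across L such
loci against the $2^L$ possible.

## The germplasm simulator

`simulate_germplasm()` generates the study conditions, not a convenient
fixture:

* **Structure**: K admixed subpopulations (default 4, mirroring
  winter six-rowed / spring six-rowed / two spring two-rowed groups);
  per-accession admixture from Dirichlet($\alpha$), $\alpha = 0.1$ —
  mostly-assigned accessions with occasional strong admixture.
  Subpopulation allele frequencies diverge by a Balding–Nichols model
  ($F_{st} = 0.2$ by default).
* **LD**: each subpopulation owns a pool of 16 founder haplotypes;
  chromosomes are tiled with exponential-length segments (mean
  `ld_block_decay_cM`, default 5 cM) copied from founders drawn by the
  accession's admixture. Small pools plus segment copying produce block
  LD decaying on the segment-length scale within subpopulations, plus
  structure-driven long-range LD across them. Sixteen founders per pool
  keeps causal loci polymorphic within subpopulations (an 8-founder pool
  fixes a 0.85-frequency allele in a quarter of pools, which would remove
  the within-structure signal the method needs); multi-program breeding
  germplasm realistically draws on pools of this order.
* **Causal architecture** (`default_causal_spec()`): three vernalization
  loci whose dominance combination sets sensitivity — exactly one of the
  eight combinations (repressor present, both promoters recessive) is
  sensitive and assigned exactly the censor day (150); insensitive lines
  flower uniformly on [32, 69] days plus Gaussian noise (sd 3 days),
  truncated strictly below the censor — the uniform-plus-noise choice is
  a stand-in, the real flowering-time distribution of insensitive lines
  is not specified beyond its range. One inflorescence locus carries a
  dominant wild type and three distinct recessive haplotypes that all
  collapse to six-rowed. Founders carry causal allele types with
  subpopulation-specific frequencies, so both traits are strongly
  confounded with structure by construction.
* **Markers emitted**: evenly spaced background SNPs; per causal locus an
  allele-type marker `<name>_AT` and, only for loci with more than two
  haplotypes, per-haplotype tag SNPs. At a biallelic functional locus a
  haplotype indicator would duplicate the allele-type column, and gene
  SNPs riding on presence/absence polymorphism fail array QC in practice,
  so emitting them would misrepresent the data the method actually sees.
* **Nuisance**: uniform random missingness (default 2%; the real
  missingness mechanism is unknown, uniform is the neutral choice),
  simulated QC scores from a Beta mixture with a configurable fraction
  below 0.6, and a small fraction of markers with unknown map position —
  both exist to exercise the filters.
* **Reproducibility**: one seed fixes everything bit-identically; the
  phenotype stage runs under a stored derived seed so phenotypes can be
  regenerated exactly from the truth record (`regenerate_phenotypes()`).

What the simulator does **not** emulate: coalescent realism, mutation,
recombination hotspots, selection history, heterozygosity, genotyping
error correlated with allele frequency, and ascertainment bias of array
SNPs. Passing recovery tests therefore show that the statistical machinery
behaves as claimed under the assumed structure — not that real germplasm
satisfies those assumptions.

## Validation problem sizes and numerical choices

The test suite and the acceptance script validate at these scales, chosen
to exercise the methods well inside a desktop budget: oracle equivalence
on 8–10 accession toys (kinship to 1e-6, ML log-likelihood to 1e-4
against a dense grid); interaction-LRT null calibration over 1,000
simulations of 100 accessions; the structure-correction ordering (median
count of significant far-from-causal markers, M+Q+K ≤ M+Q ≤ M) over 20
seeds of 200 accessions × ~1,000 markers; causal-pair recovery and
LD-extent CI coverage over 20 seeds each. Further numerical conventions:
marker QC keeps unscored markers (a filter cannot act on a score that was
never assigned); the 10%-missing rule is computed on the analysis set in
use; MAF "below 0.05" is strict, the boundary is kept; tri-allelic sites
drop the minor state with lexicographic tie-breaking; Q columns that turn
out collinear are dropped by rank with a message before fitting.

## Known limitations

Censored flowering times are analyzed as-is (the censor value is a real
data point at 150); a binary sensitive/insensitive recode is a documented
alternative. The mixed-model marker test is Wald-type under reused
variance components, which is slightly anti-conservative for very strong
markers. The loess-band crossing gives pointwise, not simultaneous,
confidence statements about the extent. Logistic models for binary traits,
D′-type LD statistics, haplotype-phase inference, imputation and
three-way interactions are out of scope.
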