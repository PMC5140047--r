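---
title: "Tumor purity, clonal architecture and mutation signatures: models and methods"
author: "clonescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor purity, clonal architecture and mutation signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

# The problem

A bulk tumor specimen is a mixture: a fraction $\alpha$ of its cells are
tumor cells (the *purity*), the rest are admixed normal cells, and the tumor
cells themselves are a mosaic of clones. `clonescape` reconstructs three
layers of that architecture from routine assays — SNP-array B-allele
frequencies (BAF), exome read counts at somatic point mutations, and
Infinium-style CpG methylation profiles — and ships a synthetic-cohort
generator that realizes exactly the statistical model the estimators
assume, so every stage can be validated against planted ground truth.

# Purity and CNA cell fractions from BAF

## The mixture geometry

At a heterozygous SNP probe the BAF of pure diploid tissue sits at $1/2$. A
copy-number alteration (CNA) carried by a fraction $c$ of **all** cells
shifts the heterozygous BAF into two symmetric bands. Counting B-allele and
total copies over the cell mixture:

* hemizygous deletion (CN1): peaks at $\dfrac{1-c}{2-c}$ and
  $\dfrac{1}{2-c}$, so the separation $d=\mu_2-\mu_1 = \dfrac{c}{2-c}$
  inverts to $c = \dfrac{2d}{1+d}$;
* copy-neutral LOH: peaks at $\dfrac{1\pm c}{2}$, so $c = d$.

`cellFractionFromPeaks()` implements these inversions, and the suite checks
the round trip against the allele-counting derivation to $10^{-9}$ on a
grid over $c\in[0,1]$.

## Fitting the peaks

`fitBafPeaks()` fits each deletion/LOH segment's probe BAFs with a
two-component Gaussian mixture by expectation–maximization. The mixture is
constrained *symmetric about 0.5 with a shared variance* — components
$N(\mu, \sigma^2)$ and $N(1-\mu, \sigma^2)$. The constraint is not
cosmetic: the A/B labeling of array alleles is arbitrary, so the two bands
are exchangeable reflections, and the symmetric parameterization is what
makes the two-peak fit identifiable at small separations. Initialization
uses the 10th percentile of the folded BAFs $\min(v, 1-v)$; the observed
log-likelihood is asserted non-decreasing at every iteration.

Numerical choices: the component standard deviation is floored at
$10^{-4}$ so noise-free segments cannot collapse the likelihood;
convergence is declared when the log-likelihood increment falls below a
*relative* tolerance of $10^{-7}$ (segments whose true separation is below
the noise level creep along a flat likelihood ridge — they hit the
iteration cap, are returned with a warning, and are typically flagged
*degenerate*, meaning a separation under 0.02, roughly the resolution of
array noise); segments with fewer than 50 probes are left `unassigned`
rather than fitted.

## Purity as the rightmost clone

Each deletion/LOH contributes one cell fraction $\pi = c$. The density of
$\pi$ across a genome is multi-modal: each mode is a clone, and the
rightmost mode — the most prevalent cell population carrying CNAs — is the
primary clone, whose location is the purity estimate $\hat\alpha$
(`estimatePurity()`). The density is a Gaussian kernel estimate with
Silverman's rule-of-thumb bandwidth. A mode only counts as a clone if its
basin carries at least 5% of the total density mass; without this guard a
single noisy segment to the right of the main clone would inflate
$\hat\alpha$. CN2 segments carry no CNA, CN0 segments leave no
heterozygous tumor signal, and amplifications are excluded because their
amplitude response is too variable to invert reliably; none contribute
$\pi$ values.

A CNA is called *clonal* when $c \ge (1-\texttt{relTol})\,\hat\alpha$,
with `relTol = 0.1` by default. The tolerance is this package's choice: it
absorbs the compounded estimation noise of $\hat c$ (EM on a few hundred
probes) and $\hat\alpha$ (a density peak over a few dozen segments) while
still separating cell fractions below $0.9\,\alpha$. Whether $\pi$ should
be read as a fraction of all cells or of tumor cells was genuinely open;
this package fixes $\pi$ = fraction of **all** cells, which is what makes
the rightmost peak itself the purity.

`assignCopyState()` assigns the copy state from the tumor/normal
read-depth ratio plus BAF imbalance, with documented defaults (deletion
below 0.9, amplification above 1.1, homozygous deletion below 0.25,
imbalance at peak separation 0.1). For a clonal deletion at purity 0.7 the
expected ratio is $(2-c)/2 = 0.65$, comfortably below the 0.9 threshold.

# Clonality of somatic point mutations

## The expected mutant-allele fraction

A clonal mutation is carried by every tumor cell; a subclonal one by a
fraction. The test statistic is the mutant-allele fraction (MAF). Under
the *clonal null* the point mutation precedes any overlapping CNA, so the
CNA acts on a mutation-bearing chromosome. With purity $\alpha$ and a CNA
carried by a fraction $\beta$ of **tumor** cells ($\beta = c/\alpha$),
counting mutant and total alleles over the three cell classes (normal,
tumor without the CNA, tumor with it) gives the closed forms implemented
in `expectedMaf()`:

| locus state | configuration | expected MAF |
|---|---|---|
| CN2 | — | $\alpha/2$ |
| CN1 | wild type deleted | $\alpha/(2-\alpha\beta)$ |
| CN1 | mutant deleted | $\alpha(1-\beta)/(2-\alpha\beta)$ |
| LOH | mutant duplicated | $\alpha(1+\beta)/2$ |
| LOH | wild type duplicated | $\alpha(1-\beta)/2$ |

Every formula is verified against a brute-force cell-enumeration oracle to
$10^{-9}$ over a $20\times20$ grid of $(\alpha,\beta)$. Amplified and
homozygously deleted loci admit no usable clonal null (absolute copy
number and its subclonality are unresolved there), so mutations in AMP/CN0
regions are *excluded*, never force-classified.

## The test

`clonalityTest()` is the one-sided exact binomial lower tail
$P(X \le \text{alt} \mid \text{depth}, \text{MAF}_0)$: subclonality can
only depress the MAF below its clonal expectation, so only the lower tail
is evidence. The test is uniform-or-conservative under the null (binomial
discreteness makes it conservative; the suite checks the empirical
rejection rate at $p<0.05$ on $10^4$ simulated clonal mutations lands in
$[0.02, 0.06]$). The subclonal call threshold is $p < 0.05$ by default —
a documented package choice — and per-mutation calls are deliberately
*not* multiplicity-corrected, since the FSM statistics below use them
descriptively.

When the allele configuration (mutant on the retained vs the lost allele)
is unknown — the common case, since phasing is unavailable — both
configurations are tested and the **larger** p-value kept: a mutation is
only called subclonal if it is subclonal under every configuration. This
max-p rule is conservative by construction. $\beta$ is inherited from the
overlapping segment's estimated cell fraction; mutations in segments with
no usable fit are tested at $\beta=0$ and flagged `betaImputed`. A plain
binomial (not beta-binomial) is used, matching the stated read-sampling
model; overdispersion handling is left to future work.

The fraction of subclonal mutations (FSM) is
$n_{\text{sub}}/(n_{\text{clonal}}+n_{\text{sub}})$ over classified calls.
Per-gene FSM is tested against the pooled background with Fisher's exact
test (`fsmGeneTest()`), and two-group feature enrichment (e.g. APOBEC
membership in subclonal vs clonal mutations) with `enrichment2x2()`; both
are checked against an exhaustive hypergeometric enumeration on all small
tables.

# Mutation signatures

Substitutions are collapsed to the pyrimidine strand and classified into
nine types: {C→A, C→G, C→T} split by CpG dinucleotide context (reference C
followed by G after strand collapse — a dinucleotide criterion, not a CpG
*island* one) plus {T→A, T→C, T→G}. The split only for C-reference types
follows from the biology: deamination at methylated CpG cytosines is the
context-dependent process worth separating. APOBEC-signature mutations
are C→T and C→G in TCW motifs (TCA/TCT, W ∈ {A,T}) after the same
collapse. `summarizeSample()` reports the total mutation count (TNSM),
the nine fractions, the transversion fraction (FT; C→A, C→G, T→A, T→G),
the APOBEC fraction (FA), and the rate per megabase of target. All 96
(ref, alt, context) combinations are validated against a
reverse-complement enumeration oracle. Indels are outside the nine-type
scheme and excluded upstream.

Associations between per-sample signature statistics and covariates use
the two-sided Wilcoxon rank-sum test (exact when tie-free and small, the
normal approximation otherwise — `stats::wilcox.test`'s standard switch)
or Fisher's exact test for binary features.

# Methylation–signature association

For each CpG probe, `probeAssociation()` fits ordinary least squares of
the mutation trait (TNSM, FT, FA, or a type fraction) on the probe's beta
value plus covariates — smoking status, age, stage and sex in the
simulated cohorts, with categorical covariates as factor indicators and
age continuous. Which side of the regression the trait sits on was not a
settled convention; this package regresses *trait on methylation*, so a
positive effect means higher methylation accompanies a higher mutation
burden. The family-wise threshold is Bonferroni, $\alpha/n$, with $n$
taken from the probes actually tested, never hard-coded. Category
enrichment is the ratio of significant-probe rates,
$(k_{\text{cat}}/n_{\text{cat}})/(k_{\text{all}}/n_{\text{all}})$, kept at
full precision and rounded only for display; `fractionPositive()` reports
the sign composition among significant probes. FDR-style screening is
available via `benjaminiHochberg()` (the standard step-up procedure).

# What the generator simulates — and what it does not

`simulateTumorSample()` realizes exactly the admixture model above: probe
BAFs are drawn around the analytic peak positions with Gaussian noise
*truncated* to $[0,1]$ (inverse-CDF truncation, so no mass piles on the
boundaries), and SNV alt counts are binomial at the analytic expected MAF
with Poisson depth. Defaults are chosen to mimic a smoking-dominated lung
adenocarcinoma cohort:

* purity uniform on $[0.2, 0.9]$; 40 segments per sample weighted
  CN1-heavy (50% CN1, 24% AMP, 13% LOH) to match the observed
  deletion-dominated CNA mix, with 60% of CNAs subclonal;
* subclonal CNA fractions $\beta$ uniform on $[0.2, 0.8]$ — no published
  distribution exists, so a flat prior over a realistic range;
* 200 probes per segment, BAF noise sd 0.03 (array noise levels are not
  published for this platform; 0.03 is a realistic Infinium-class value
  and is configurable);
* 400 SNVs per sample at mean depth 100, 55% subclonal with cancer-cell
  fractions uniform on $[0.1, 0.8]$; clonal mutations in CNA regions get
  an allele configuration uniformly at random (both cases occur in
  reality and neither is observable);
* a type spectrum with transversion fraction 0.62 and TCW contexts
  upweighted so the APOBEC fraction averages about 10%; contexts are
  otherwise uniform, and half the mutations are emitted on the purine
  strand to exercise strand collapse.

A mutation on the lost allele of a fully clonal deletion has expected MAF
0 — no mutant template survives — so the generator drops it, as a variant
caller necessarily would.

The generator does **not** simulate raw reads, alignment or calling
artifacts, GC waves in array intensities, segmentation error (segments are
inputs by design — the bespoke analysis starts at peak fitting),
allele-specific amplification states beyond a generic AMP label, or
correlated noise between probes. Passing recovery tests on these cohorts
therefore demonstrates correctness of the estimators *under the stated
model*, not robustness to upstream artifacts in real data.

`simulateMethylationDataset()` plants exactly `nAssoc` probes whose
methylation tracks the covariate-independent component of the trait with
a standardized effect (partial correlation
$\text{effect}/\sqrt{1+\text{effect}^2}$; the default 0.5 gives
essentially complete power at 500 samples and Bonferroni-corrected
$10^{-5}$-scale thresholds, which is what a "strong, replicable
association" looks like at cohort scale). Planted effects are positive by
construction, so sign recovery is also testable.

# Problem sizes and determinism

The validation suite uses desk-scale sizes chosen to make Monte-Carlo
noise negligible relative to the tolerances tested: 50 samples for purity
recovery (mean absolute error bounded at 0.05, typically under 0.005),
$10^4$ mutations for test calibration, 5,000 probes × 500 samples for the
methylation power and uniformity checks, and exhaustive enumeration
(all 2×2 tables up to total 30; all 96 substitution contexts) where a
finite case space exists. Every simulation is seeded: a per-sample seed is
derived deterministically from the configuration seed and the sample
index, so cohorts are reproducible element-wise and byte-identical on
rerun, including through `runPipeline()`, which records its seed and
parameters in a JSON manifest.

# Known limitations

* Single-sample design: without multi-region data, clones are identified
  only as density modes of $\pi$; phylogeny and subclone assignment of
  individual mutations are out of scope.
* Amplifications are excluded from both purity estimation and mutation
  clonality; tumors whose architecture is amplification-driven will be
  under-characterized.
* The binomial read model ignores overdispersion; at very high depth the
  clonality test can become anti-conservative if counts are
  overdispersed.
* Whole-genome doubling is not modeled; in a doubled genome the CN1/LOH
  peak inversions are misspecified.
* The clonal/subclonal CNA boundary (`relTol`) and the subclonality
  p-value cutoff are tunable conventions, not estimated quantities;
  conclusions sensitive to them should be checked across a range.
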