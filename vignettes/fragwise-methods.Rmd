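---
title: "fragwise: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragwise: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Ecotoxicological work on non-model organisms — here, anuran larvae exposed
to the organophosphorus pesticides azinphos-methyl (AZM) and chlorpyrifos
(CPF) — often relies on a de novo assembled transcriptome without a
reference genome. Quantification then happens at the level of *fragments*:
assembled isoforms/contigs, several of which may map to one annotated gene.
`fragwise` implements a hypothesis-driven workflow over such data:

1. **Curation.** Confirm each fragment's annotation from alignment hits
   (best hit, percent match strictly above 50 to the expected gene), then
   discard fragments with a zero value in any sample or with very low and
   erratic levels.
2. **Normalization.** Between-sample TMM scale factors computed from
   scratch; expression reported in counts per million of the effective
   library.
3. **Reference-gene selection.** Candidate housekeeping (HK) transcripts
   are ranked by percent coefficient of variation over all samples
   (CV% = 100·SD/mean, SD with the n−1 denominator) and retained when
   CV% < 20.
4. **Standardization.** Each sample's expression is divided by the mean of
   its HK genes' control-referenced ratios, and relative expression per
   treatment is taken against the control mean.
5. **Dual differential expression.** (i) Exact nonparametric tests
   (Kruskal–Wallis, Mood's median, pairwise exact rank tests) treating a
   gene's accepted fragments × replicates as observations; (ii) a
   collapsed-gene negative-binomial (NB) exact test with a common
   dispersion, calling DEGs at fold change ≥ 2 (or ≤ ½) and p ≤ 0.05.
6. **Synthesis.** Cross-approach concordance, a heatmap-style category
   matrix with the down:up call ratio and fold-magnitude bins, DEG ranking
   by |log2FC| with rank bins, and geometric-mean HK normalization of qPCR
   Ct data.

## Statistical details and numerical choices

### Exact tests

The Kruskal–Wallis statistic uses midranks and the tie-correction factor
1 − Σ(t³−t)/(N³−N); when every observation is identical the statistic is 0
and p = 1 (the tie factor would otherwise vanish). The p-value is the
permutation-null tail probability P(H\* ≥ H):

* **Full enumeration** of all distinct assignments of the observations to
  the group sizes when the total N ≤ `exact_limit` (default 10). For
  two-group layouts the assignment count is `choose(N, n1)`, so enumeration
  stays cheap well past N = 10; we therefore enumerate any two-group case
  with `choose(N, n1)` ≤ 200 000 (the five-fragment pairwise layout, N = 20, is still exact; the enumerated null distribution is cached by rank multiset and layout, so it is computed once across all genes). This only ever *extends* the exact regime
  (an exact computation is never replaced by an approximation). With the
  study design of duplicated treatments and two-to-three accepted fragments
  per gene, the pairwise treated-vs-control tests (N up to 12) are exact.
* **Seeded Monte-Carlo** otherwise (default 100 000 permutations at the
  single-test level; the per-gene driver uses a smaller shared, seeded
  permutation set — one per distinct N — so adding genes never perturbs
  another gene's p-value).
* A flagged **chi-square approximation** is available explicitly but never
  chosen automatically.

Mood's median test dichotomizes at the grand median with ">" versus "≤"
(stated so the 2×k table is reproducible), and sums multivariate
hypergeometric probabilities of all tables with the observed margins that
are as or less likely than the observed table (N ≤ `exact_limit`), falling
back to chi-square with Yates continuity correction for 2×2 tables.

Two-tier calling: p ≤ 0.05 is significant, 0.05 < p ≤ 0.10 a *tendency*.
The tendency tier formalizes common figure-annotation practice in this
field (effects at p = 0.08–0.09 reported as trends); both thresholds are
arguments.

### The collapsed NB exact test

Fragments are summed per gene, and group sums are modeled as NB with means
proportional to effective library sizes (raw library size × TMM factor) and
a common dispersion φ. Conditional on the pooled total, the two-sided
p-value sums the probabilities of all splits as or less likely than the
observed one. Numerical choices:

* Totals ≤ 5 000 are fully enumerated; larger totals restrict the support
  to the window holding all but ~1e−14 of the conditional mass (the
  conditional pmf is log-concave, so the excluded tails are negligible for
  any calling threshold).
* Unequal effective library sizes are handled by deterministic linear
  rescaling of each group sum to the geometric-mean effective library,
  rounded to an integer — a simpler convention than quantile-adjusted
  pseudo-counts. Exact numerical agreement with edgeR's quantile-adjusted
  conditional likelihood is consequently not claimed anywhere; edgeR is
  used in the test suite only as an independent cross-check for the TMM
  factors.
* log2FC = log2((a₁ + c)/(a₂ + c)) with abundances a on the
  counts-per-geometric-mean-library, per-sample scale, and prior count
  c = 0.5 for stabilization.

The common dispersion is method-of-moments: per gene, within-group means m
and variances s² on library-size-normalized counts are pooled as
φ_g = max(0, Σ(s²−m)/Σm²) across the replicated groups, and φ is the median
of φ_g over genes with normalized mean above 5. Pooling across the five
groups *before* truncation at zero matters at duplicate-level replication:
per-group moment estimates from n = 2 are so noisy that a per-group median
would collapse toward zero. The estimator carries the usual small-sample
downward bias of median-of-moments (roughly 10–15 % at n = 2 per group); it
is a deliberate simplicity/robustness trade-off, not an attempt to
reproduce quantile-adjusted conditional maximum likelihood.

### TMM from scratch

The reference sample is the one whose 75th-percentile count fraction is
closest to the mean of those fractions. M and A values are computed over
rows positive in both libraries, doubly trimmed (30 % of the M tails, 5 %
of the A tails, the method's canonical values), and averaged with
inverse-asymptotic-variance weights; factors are rescaled to geometric
mean 1. The unit test checks equality with a literal-formula oracle at
1e−10 and with `edgeR::calcNormFactors` at 1e−8.

### Housekeeping selection and standardization

CV% < 20 is applied *strictly*; on the published candidate table both the
strict and non-strict conventions retain the same 9 of 12 transcripts
(the excluded candidates sit at 21.7, 22.6 and 81.3 %), and the threshold
is an argument. Standardization computes per-sample factors
F_s = mean_h (TMM_{h,s} / control-mean_h); by construction the factors
average exactly 1 over control samples. The underlying study description
("averaged for each treatment") is ambiguous between per-sample and
per-treatment averaging; both are implemented
(`mode = "per_sample"` default, `"per_treatment"` behind the flag) — the
per-sample default retains independent replicate variation, which the
fragment-as-replicate tests need.

### qPCR

Quantities are Q = E^(−Ct) with per-gene efficiency E ∈ (1, 2] supplied,
never estimated. The normalization factor is the geometric mean of the HK
quantities per sample; fold changes are ratios of geometric means across
replicates (arithmetic pooling behind a flag). With one HK gene and E = 2
this is exactly 2^−ΔΔCt, which the test suite asserts. Technical-replicate
Ct rows are averaged arithmetically on the Ct scale before analysis.

## The synthetic-data generator

The generator emulates the study design so every downstream stage is
testable without any data download: five treatments (control, AZM 6 h,
AZM 24 h, CPF 6 h, CPF 24 h) in duplicate — ten samples; one to five
fragments per gene (about 2–3 accepted per gene on average, matching the
curation funnel's outcome); NB-distributed counts; designated low-CV HK
genes; moderate effects, mostly below 2-fold, with down-regulations
outnumbering up-regulations 3:1; and a fraction of corrupted fragments.

Defaults and the reasoning behind them (the within-group variance of the
original data is unreported, so these are the package's own choices of
realistic values, fixed once):

* `nb_dispersion = 0.10`: biological coefficient of variation ≈ 32 %,
  typical for whole-organism pools of outbred larvae. It also separates
  the populations the HK filter must distinguish: a non-HK gene's
  gene-level CV is ≈ √(1/μ + φ) ≳ 32 %, comfortably above the 20 %
  selection threshold, while HK genes are tuned well below it.
* `hk_cv_target = 15` (%), `n_hk_genes = 12`, `hk_min_abundance = 600`:
  HK genes get an abundance floor (so counting noise cannot dominate) and
  a tightened dispersion of (0.6 × target/100)², putting their realized
  CV% safely under the target.
* `baseline_log_mean = 5`, `baseline_log_sd = 1.5` (natural log): median
  abundance ≈ 150 count-units with a realistic dynamic range of ~4 orders
  of magnitude; total expected library ≈ 10⁶, so count units roughly
  coincide with CPM.
* `effect_log2_range = c(0.3, 2)` with `frac_affected = 0.3` and
  `down_up_ratio = 3`: mostly sub-2-fold effects, down:up odds 3:1.
* `library_size_cv = 0.15`: libraries were normalized before sequencing,
  so only moderate depth variation remains.

Fragment shares within a gene follow a symmetric Dirichlet (concentration
5). NB variation is realized as a per-(gene, sample) Gamma multiplier with
squared CV φ shared by the gene's fragments, followed by Poisson sampling
per fragment. The NB(μ, φ) marginal then holds *both* per fragment and for
the gene-level sum (Poisson–Gamma identity), and fragments of one gene
share their biological replicate noise — as real fragments of one
transcript do. Had fragments been drawn independently, collapsing would
average away biological variation and non-HK genes would masquerade as
stable at the gene level.

Corruption has two modes, as the expression filter expects: a randomly
chosen sample forced to zero, or "low and erratic" — the fragment's mean is
rescaled below the expression floor (uniform 1–4 TMM units) and one
replicate in each treatment group is multiplied by Uniform(0.05, 0.3)
noise. Corrupting one replicate per group (rather than a single sample
overall) is what the phrase "replicates with very low and erratic values"
describes, and is required for the conjunctive low+erratic rule to be
detectable at all: a single corrupted sample among ten is usually
indistinguishable from honest low expression.

One top-level seed drives independent, labeled substreams (structure,
library sizes, counts, corruption, hits, qPCR), so adding one generator
never perturbs another, and identical configuration and seed give
byte-identical artifacts.

### What the generator does not emulate

Read-level artifacts (assembly errors, mapping ambiguity, multi-mapping
between paralogs), length biases, batch effects, treatment-specific effect
patterns (a gene's planted effect is shared by all four exposure groups),
and correlated effects within pathways. Passing tests on synthetic data
therefore demonstrate that the *procedures* are implemented correctly and
recover known truth under the stated model — not that the model captures
every property of the original larval data.

### Evaluating the down:up call ratio

The heatmap summary reports the down:up ratio over *all* called cells.
When the generator's 3:1 regulation odds are checked against realized
calls, the comparison is restricted to genes carrying a planted effect
(the ground truth identifies them): null genes contribute false calls in
both directions with equal probability, so including them drags any
realized ratio toward 1 regardless of the simulated regime — they carry no
information about the regulation odds. This mirrors the motivating study,
where the 3:1 observation was made over hypothesis-selected, largely
responsive genes rather than the whole transcriptome.

## Problem sizes used in the checks

The recovery checks run the full workflow on the default 2 000-gene,
5 × 2-sample design, and the strong-effect detection check on a
1 000-gene variant with exactly three fragments per gene and fixed 4-fold
effects (the regime in which the fragment-as-replicate tests are meant to
operate). Exact-test property checks use hundreds of random small layouts
(N ≤ 8) against full-enumeration oracles, and the NB exact test is checked
against an exhaustive-split oracle for totals up to 50. The published
reference-gene stability table (12 candidates over 10 samples) is shipped
as a plain-text fixture and its CV% column recomputed from the printed
means and SDs.

## Known limitations

* The NB exact test intentionally differs from edgeR's quantile-adjusted
  CML in its library-equalization step; concordance percentages between
  the nonparametric and NB routes are therefore properties of this
  package's conventions, and published concordance figures (66.7 % at the
  transcript level in the motivating study) are not reproduction targets.
* Fragments are treated as exchangeable replicates within a gene; no
  per-fragment weighting is offered.
* No multiple-testing correction is applied to the calling rules (raw
  exact p-values with fold-change bounds, as in the motivating workflow);
  a BH-adjusted column can be derived by the user from the emitted tables.
* Efficiencies for qPCR are inputs; no standard-curve fitting.
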