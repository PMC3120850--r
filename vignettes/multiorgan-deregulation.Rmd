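---
title: "Multi-organ transcriptome deregulation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ transcriptome deregulation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Growth-restricted fetuses (IUGR, here modelled by a maternal low-protein
diet in the rat) show transcriptional responses that differ radically
between organs, both in intensity and in direction. Given per-gene
expression ratios (treated over control) for several organs measured on a
common array, `modeg` answers a chain of questions: how many genes does
each organ deregulate beyond a fold threshold, and in which direction? Do
organs respond concordantly or in mirror image, relative to what
independence would predict? Do particular gene panels (epigenetic
effectors, imprinted genes, pathways) deviate from the genome-wide
behaviour? Is deregulation positionally clustered along chromosomes? And
do promoters of the most induced and most repressed genes differ in
predicted transcription-factor binding sites?

The pipeline deliberately starts *downstream* of array preprocessing: its
entry point is a table of log2 ratios per gene per organ. Probe-level
processing, normalization and per-gene moderated tests belong to the
upstream platform tooling and are out of scope.

```{r setup}
library(modeg)
```

## Classification at a fold threshold

Gene $g$ in organ $o$ with log2 ratio $r_{go}$ is labelled

$$\text{up if } r_{go} \ge \log_2 \theta, \qquad
  \text{down if } r_{go} \le -\log_2 \theta, \qquad
  \text{unchanged otherwise},$$

with $\theta = 2$ by default. The boundary is inclusive: a gene at exactly
two-fold counts as changed. An exclusive boundary would change results
only on a measure-zero set for continuous ratios, but the rule must be
stated once and kept; inclusive is what `classify()` does. The *modified
fraction* is $100\,(n_\text{up}+n_\text{down})/n$, and is monotone
non-increasing in $\theta$.

Directional bias among changed genes is tested two-sided against
$H_0\!: P(\text{up}) = P(\text{down})$, either by a 1-df Pearson
goodness-of-fit statistic on $(n_\text{up}, n_\text{down})$ (default) or
by the exact binomial test. The two disagree noticeably only at small
counts, which is why the method is a recorded parameter rather than a
hard-wired choice.

## Cross-organ concordance under independence

For organs $A$ and $B$ sharing a gene universe of size $N$, the observed
$3\times3$ joint table over $\{$up, down, unchanged$\}$ is compared with
the counts expected if the two classifications were independent:

$$E_{ij} = \frac{n_i^{(A)}\, n_j^{(B)}}{N}.$$

`expected_counts()` keeps the expected matrix exact (it sums to $N$ to
machine precision) and rounds only in printing, since downstream excess /
deficit calls would otherwise inherit rounding error. Swapping $A$ and $B$
transposes both matrices.

Organ similarity uses the Pearson correlation of log2-ratio profiles over
the shared genes, converted to the distance $d = 1 - r$, and average-
linkage agglomerative clustering. Neither the distance nor the linkage is
canonical for this problem; complete and single linkage are accepted
alternatives, and the choice is recorded on the result. Average linkage is
the default because it reproduces the expected two-block partition on
coupling-structured data without being driven by single extreme pairs.
Leaves are sorted by label before clustering so tied merges resolve
deterministically.

Tree faithfulness is summarized by the cophenetic correlation — the
Pearson correlation between the original $n(n-1)/2$ pair distances and the
distances implied by the dendrogram. For significance the package offers
two labelled options, because no exact reference distribution exists for
so few leaves: a $t$ approximation with $n_\text{pairs}-2$ degrees of
freedom (which treats pair distances as independent — they are not, so
read it as an order-of-magnitude guide), and a label-permutation test.
With five organs only $5! = 120$ distinct relabellings exist, so
permutation p-values cannot go much below $10^{-2}$; the $t$ option is the
one comparable to published values.

## Gene-panel deviation from the genome background

A panel's composition $(o_\text{up}, o_\text{down}, o_\text{unch})$ is
tested against expectations taken from the organ's genome-wide class
proportions with a plain Pearson goodness-of-fit statistic,

$$X^2 = \sum_c \frac{(o_c - e_c)^2}{e_c},$$

with no continuity correction and no minimum-expected-count rule: panels
of interest here have single-digit expected counts, and applying Yates or
exactification would no longer reproduce the reference values this layout
is meant to mirror. A warning is emitted whenever an expected cell drops
below 1, and a class whose expectation is exactly zero (and observed zero)
contributes neither to the statistic nor to the degrees of freedom; an
expected-zero cell with observed members is reported as an infinite
statistic rather than silently patched.

Two deliberate conventions:

* **Background includes the panel.** The genome proportions are taken
  from all genes, not from genome-minus-panel. Both conventions are
  implemented (`background = "complement"`), but whole-genome is the
  default because it is the convention that reproduces the reference
  table values this test mirrors.
* **Two-class mode** collapses to down vs rest, the contrast used for
  imprinted-gene panels where the question is a deficit or excess of
  repressed members.

Pathway over-representation uses the expected count
$e = m \cdot K / N$ for a pathway of $m$ genes when $K$ of $N$ genes are
modified, with an exact binomial upper tail by default (hypergeometric as
an option). The binomial is the default because pathway universes in
published tables rarely match the analysis universe exactly, and at
$m \ll N$ the two models agree to the order of magnitude, which is the
level at which such p-values can be compared at all.

## Chromosome scans

Per-chromosome bias applies the same goodness-of-fit test per chromosome
against the class proportions of all annotated genes, with df 2 (or down
vs rest with df 1 as an option, since published analyses do not always say
which was used). Multiple testing is reported in the uncapped
*Bonferroni-product* convention — raw p times the number of chromosomes
tested, so values above 1 occur — because that is the convention of the
reference table layout; a conventional capped column sits alongside and
drives the `significant` flag. The background is computed on annotated
genes only, so the per-chromosome counts sum exactly to the genome totals
entering the test; genes missing from the annotation are excluded with a
logged count.

Positional structure uses a sliding window of $k = 10$ consecutive genes
(step 1, never spanning a chromosome boundary), ordered by start
coordinate — gene order, not base pairs, which matches how such profiles
are drawn and makes the profile invariant to coordinate translation.
Regions are called as maximal runs of at least `min_windows = 3`
consecutive windows with $|\bar r| \ge$ a threshold and consistent sign.
The threshold is user-set with default 0.5 (a generic screen at half the
two-fold cut). When the expected cluster effect is known — as in the
synthetic studies, where injected clusters shift genes by 1.5 — a
threshold near half that effect gives boundary errors below one window
width; with a heavily deregulated background (a quarter of the placental
genome beyond two-fold) the 0.5 default will legitimately smear
boundaries by a few genes. Region calling is idempotent, and raising the
threshold only shrinks the called window support.

Internally all coordinates are 0-based half-open (BED convention);
1-based inclusive TSV input is converted on read behind an explicit
format flag, and the input dialect is recorded. Genes present in ratio
tables but absent from the annotation stay in all non-positional analyses
and are only excluded (counted) from chromosome scans.

## Promoter site-count comparison

The promoters of the $n = 20$ most induced and $n = 20$ most repressed
genes (ties at the cut broken lexicographically, so selection is
deterministic) are compared family-by-family on predicted binding-site
counts with a two-sample, two-sided Student t-test (pooled variance by
default, Welch optional) and Bonferroni correction over the families
tested. Every promoter of a selected gene is one observation — genes
commonly own several alternative promoters, and collapsing them would
discard exactly the within-gene variation the comparison rests on.

Counts can be supplied precomputed (the primary path, since the matrix
libraries behind published site counts are proprietary), or produced by
the package's own log-odds PWM scanner: counts plus a per-column
pseudocount of 0.8 are normalized to probabilities, scored against a
uniform 0.25 background, and a position on either strand counts as a site
when its score reaches a fraction (default 0.85) of the maximum
attainable score. `N` bases contribute their column's expected background
score, making them neutral rather than disqualifying. The scanner is
checked exactly against a naive per-position scorer; the reverse strand
is scanned by reverse-complementing the matrix, which makes strand
symmetry an algebraic identity rather than an approximation.

## qPCR validation

Relative quantification follows the standard
$2^{-\Delta\Delta C_t}$ scheme: per condition,
$\Delta C_t = \overline{C_t^\text{target} - C_t^\text{reference}}$ over
replicates (arithmetic mean, the original convention), and the fold
change is $2^{-(\Delta C_t^\text{treated} - \Delta C_t^\text{control})}$.
The estimate is invariant to any global shift applied to both target and
reference cycles. Platform concordance is computed on the log2 scale of
both platforms: Pearson $r$ plus the $R^2$, slope and intercept of the
least-squares fit of array on qPCR ratios.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `sim_study()` generate the full input bundle under one
seed. The defaults *are* the study conditions:

* 23,456 transcripts, five organs, two-fold threshold; deregulated
  fractions lung 0.34, liver 0.24, kidney 0.077, heart 0.033, placenta
  0.24. A 2,000-gene `small = TRUE` preset keeps the same structure at
  desk scale; simulation-heavy tests use it, and full scale is used where
  a single realization must be stable (fraction recovery).
* **Coupling.** Each gene carries a shared latent score and latent
  direction; each organ follows the latent with probability 0.6 (its
  coupling strength), with sign $-$ for placenta and kidney and $+$ for
  liver, lung and heart. Followers of the shared factor produce the
  mirror pattern: within-group correlations positive, between-group
  negative, and the first dendrogram split separates
  {placenta, kidney} from {liver, lung, heart}.
* **Directional splits.** Followers are direction-symmetric by
  construction, so the configured per-organ down-probability applies to
  the independently deregulated remainder; the realized down-fraction is
  $c/2 + (1-c)\,p_\text{down}$. Defaults (0.62, 0.42, 0.685, 0.685, 0.53)
  were chosen once so the realized splits land at the study-like values
  (≈0.55 lung, ≈0.47 liver, ≈0.57 kidney/heart, ≈0.51 placenta).
* **Effect sizes.** Deregulated genes get
  $\pm(\log_2 2 + \text{Exp(mean } 0.7))$ — every deregulated gene is
  genuinely beyond the threshold, and the exponential tail produces
  occasional ten-fold effects like real extreme inductions. Null genes
  draw from $N(0, 0.25)$, which puts the two-fold false-positive rate at
  $2\Phi(-4) \approx 6\times10^{-5}$ — a handful of genes at full scale,
  predictable from the tail formula. Deregulated genes carry no extra
  noise on top of the shift; blurring the shift across the threshold
  would make the configured fractions unrecoverable by design, which
  would defeat the generator's purpose as ground truth.
* **Chromosomes and clusters.** Genes are laid out evenly over 21
  chromosomes at 10-kb spacing; two 30-gene down-clusters (effect 1.5)
  are injected on chromosome 15 for placenta and kidney, mirroring the
  clustered-deregulation phenomenon. Forcing cluster genes into the
  deregulated set retires an equal number of randomly chosen deregulated
  genes of the same direction, so marginal counts stay at the configured
  fractions.
* **Panels, promoters, qPCR.** Gene panels are sampled with configurable
  odds multipliers on genes deregulated in a given organ/direction
  (e.g. the imprinted panel is up-enriched in kidney). Promoter site
  counts are Poisson: rate 3 background, with the effect family at rate
  2 for induced-gene and 6 for repressed-gene promoters; sequences with
  the effect family's sites embedded at the drawn counts are emitted for
  the scanner path. The qPCR panel spans the ratio range of one organ,
  with platform noise calibrated so the population cross-platform
  correlation is 0.97.

What the generator does **not** emulate: probe-level intensity noise,
normalization artefacts, inter-gene correlation beyond the single latent
factor, realistic chromosome lengths or gene-density variation
(centromeric gaps in particular), and panel biology beyond membership
odds. Passing tests therefore demonstrate that the statistics recover the
structure they are designed for — not that real arrays contain such clean
structure.

## Numerical and degenerate-input conventions

* Ratios of exactly zero or infinity (a zero intensity) drop the gene
  with a counted message instead of clipping — clipping would fabricate
  fold changes.
* No changed genes: the bias test is flagged undefined with $p = 1$.
* Constant distance vectors: cophenetic $r$ is `NA`, flagged, never
  silently 0.
* Zero variance in both promoter groups: $t = 0$, $p = 1$, flagged.
* The Bonferroni product for chromosomes is reported uncapped (mirroring
  the reference layout) *and* capped; the capped value drives
  significance.
* All randomness flows through a single seed; a bundle written twice
  under one seed is byte-identical.

## Problem sizes used in the shipped checks

Simulation-based checks run at the 2,000-gene preset with 100 repetitions
for the bipartition property, 20 for cluster recovery, and 1000
replicates for calibration properties (null rejection level, family-wise
error, p-value uniformity); single-realization recovery checks run at the
full 23,456-gene scale. These sizes put Monte-Carlo error comfortably
below the tolerances being asserted while keeping the whole suite quick
on one CPU.

## Known limitations

* The cophenetic $t$ approximation ignores dependence between pair
  distances; treat its p-value as indicative.
* Pearson goodness-of-fit p-values with expected cells below ~1 are
  rough; the package warns but does not refuse, since reproducing
  published table layouts requires exactly this regime.
* The PWM scanner assumes a uniform background and independent columns;
  it is a generic log-odds scanner, not a reimplementation of any
  proprietary matrix library, and counts obtained with different
  libraries are not directly comparable.
* Bonferroni across promoter families is conservative when families are
  correlated (as overlapping matrix families are in practice).
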