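---
title: "Flexible-threshold, conservation-aware binding-site over-representation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-threshold, conservation-aware binding-site over-representation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexsite)
library(dplyr)
```

## The problem

When a transcription factor drives a gene expression program — here the
motivating system is the axotomy-induced regeneration program of facial
motor neurons, where Jun/AP1 upregulates a large set of
regeneration-associated genes — its functional binding sites should be
over-represented in the promoters of its target genes relative to promoters
of unregulated genes. Detecting that excess is hard for two reasons. Short
degenerate motifs match random sequence constantly, so most matches at any
threshold are noise; and the score threshold separating bound from unbound
sites is not a biological constant — it shifts with cofactors and cellular
state, so a fixed cutoff tuned on one condition loses sensitivity on
another.

`flexsite` implements an analysis pipeline built around three ideas:

1. **Flexible thresholds.** Instead of one fixed cutoff, every score
   observed for a matrix in the test and control promoters is tried as a
   threshold, and the best admissible one is reported.
2. **Cross-species conserved scores.** Each candidate site is rescored in
   up to five aligned ortholog genomes; a rank-based reduction turns the
   six per-site scores into a single *conserved score* so the
   single-threshold machinery applies unchanged while enforcing
   conservation in at least `n` species.
3. **Selection-aware resampling FDR.** Because exhaustive threshold
   optimization is a strong selection effect, significance is controlled by
   re-running the *entire* optimization on label-shuffled promoter pools
   and counting location-groups of matrices that do as well or better.

## Scoring model

A position frequency matrix (PFM) with columns $i = 1..L$ is converted to
column-stochastic frequencies $f(b,i)$ after adding a pseudocount (0.01 per
cell — enough to avoid $\ln 0$, small enough to leave dominant columns
essentially untouched). Each position carries an information weight

$$c_i = \sum_b f(b,i)\,\ln\!\big(4 f(b,i)\big) \in [0, \ln 4],$$

zero exactly for an uninformative (uniform) column. A window $s$ scores
$\mathrm{raw}(s) = \sum_i c_i\, f(s_i, i)$, min–max normalized over the
attainable range so scores live in $[0,1]$ (percentages in figures). This
is the matrix-similarity convention of the classical promoter-scanning
tools: degenerate positions are down-weighted rather than excluded. A
matrix whose attainable range is empty (all columns uniform) is rejected.

Both strands are scored at every offset; where both pass the threshold only
the higher-scoring strand is kept, so palindromic or near-palindromic
elements (AP1, CRE) are not double-counted. Windows containing `N` are
skipped but remain in the promoter length — a conservative choice, since
they can only dilute frequencies. Coordinates are 0-based half-open,
measured from the 5' end of the stored sequence; promoters are stored
5'→3' with the TSS at the 3' end, so truncating to an analysis window
keeps the TSS-proximal bases.

## Conserved scores

For each mouse hit, the central position `offset + floor(L/2)` is mapped
through a per-species position map (an exact lookup — unaligned positions
are simply unaligned, never interpolated), the motif-length ungapped window
centred on the mapped position is extracted from the ortholog, and scored
best-of-both-strands. With the per-species scores $s_1 \ge s_2 \ge \dots$
(absent species dropped) the conserved score for requirement $n$ is

$$\mathrm{cs}_n = \begin{cases} s_{\text{mouse}} & n = 0\\
\min(s_{\text{mouse}},\, s_n) & n \ge 1 \text{ and } \ge n \text{ species available}\\
0 & \text{fewer than } n \text{ species available.}\end{cases}$$

Taking the minimum with the mouse score is the unique reduction for which
thresholding $\mathrm{cs}_n$ at $t$ is *exactly* the predicate "the mouse
site scores $\ge t$ and at least $n$ species windows score $\ge t$" — the
property that lets the threshold optimizer operate on one score per site.
Whether the rank is taken over the ortholog scores alone or with the mouse
score included is ambiguous in the descriptions this design follows; the
min-with-mouse form is the only one that satisfies both the $n=0$ limit
and the iff-property, so it is used. Sites in promoters that align in
fewer than `n` species get conserved score 0 and can never pass — the
conservative reading.

## The flexible-threshold statistic

For one matrix under one (window, $n$) setting, let $A$ and $B$ be the
site counts at threshold $t$ in the test and control sets with total
lengths `lenA`, `lenB` (bp). The pipeline computes, at *every* distinct
observed conserved score (thresholds are inclusive, so each candidate
realizes at least one hit):

* **OR ratio** $(A/\mathrm{lenA})\,/\,(B/\mathrm{lenB})$ — the per-length
  frequency ratio;
* **Additional Sites** $A - B\cdot \mathrm{lenA}/\mathrm{lenB}$ — the
  excess count over the control-rate expectation;
* a one-sided exact binomial p-value (below);
* an admissibility flag: the control frequency $1000\,B/\mathrm{lenB}$
  must lie in $[0.01, 0.2]$ sites/kb. The lower bound keeps the control
  rate estimable; the upper bound keeps the analysis in the specific-site
  regime rather than counting ubiquitous weak matches.

The optimum is the admissible point maximizing the configured objective —
the OR ratio, or Additional Sites subject to a minimum OR ratio of 2.5
(the AS score otherwise rewards indiscriminately low thresholds). Ties are
broken by smaller p-value, then larger threshold. `run_enrichment()`
evaluates the full grid of window lengths × conservation requirements per
matrix.

### Binomial significance: two parameterizations

Only four numbers enter the test: $A$, $B$, `lenA`, `lenB`. Two exact
constructions exist, and `binomial_p()` implements both:

* **conditional** — given $A+B$ total sites, each falls in the test arm
  with probability $\mathrm{lenA}/(\mathrm{lenA}+\mathrm{lenB})$;
  $p = P(X \ge A)$, $X \sim \mathrm{Bin}(A+B, \cdot)$. The classical exact
  two-sample comparison; it charges the control count with its own
  sampling noise.
* **rate** — the control set defines a reference rate $B/\mathrm{lenB}$,
  and the test count is referred to
  $X \sim \mathrm{Bin}(\mathrm{lenA}, B/\mathrm{lenB})$; $p = P(X \ge A)$.
  This is the construction used by the threshold-optimizing site-frequency
  methods this pipeline descends from: the control corpus is treated as
  the background model being scanned against.

The pipeline reports the rate model. The practical difference matters: at
the site frequencies where this analysis operates (tens of sites per
hundreds of kb), the conditional test is substantially weaker — a power
analysis during design showed that even an error-free detector cannot
reach high detection rates on realistic planted-truth corpora under the
conditional construction, while the rate construction resolves the same
contrasts comfortably. Users can select either via the `model` argument.

## Grouping and the resampling FDR

Motif collections are redundant: many matrices for related factors match
the same genomic locations. Two matrices are *related* when at least 50%
of either one's hit centers (center = offset + ⌊L/2⌋) lie within 4 bp of
some hit center of the other on the same promoter; location groups are the
connected components of this relation (the relation itself is not
transitive; closing it transitively yields the disjoint groups that get
reported). Each group is summarized by its representative (highest
objective value) and can be annotated with the highest-expressed member TF
scoring within 75% of the group's top objective value — annotation is by
objective score, with expression used only to pick among qualifying
members, the reading adopted where the two were ambiguous.

The group-wise FDR is estimated by resampling: if the analysis compared
$a$ test against $b$ control promoters, each of `n_runs` (default 100)
null runs draws $a$ promoters from the pooled $a+b$ as a pseudo-test set,
re-executes the *full* flexible-threshold optimization and grouping on
that split — never a cached shortcut that would dodge the
optimization-induced selection effect — and counts null groups whose
optimum is equal to or better than the observed group's (ties count
against us, the conservative direction). The FDR estimate is the
arithmetic mean of these counts; results with FDR < 0.05 survive
`report_filter()`. One caching step *is* used because it provably cannot
change any count: per-promoter hit scores depend only on the sequence, not
on arm membership, so the pooled promoters are scanned once and only the
arm assignment, threshold optimization and grouping are redone per run.
For the same reason the permissive scanning threshold is calibrated once
(on the observed control arm) and reused across runs.

## Flanking-region analysis

To find factors co-operating with an anchor factor (CRE sites near AP1
sites; CRE near SRF), the 100 bp on either side of each anchor site are
extracted, clipped to promoter bounds, overlapping flank intervals merged,
and every anchor-motif match window masked out, so no anchor sequence
leaks into the fragments. The same scan/optimize machinery then compares
these fragments against fixed-length (200 bp) fragments sampled from the
control promoters — promoter chosen with probability proportional to its
number of eligible starts, start uniform, seed-reproducible. The control
fragment count defaults to `max(1000, 5 × n_fragments)`; the source
procedure does not state its count, and this choice keeps the control
length estimate stable without dominating runtime. Fragment hits carry
original promoter coordinates, so conservation scoring and grouping work
unchanged.

## Regulatory-class classification

Genes are classified per timepoint from two contrasts at global cuts
(fold change 1.5, FDR 0.01; the fold boundary is inclusive on the log2
scale for reproducible ties, the FDR cut strict):

| WT after axotomy | KO relative to WT | class |
|---|---|---|
| up | lower | JunUP |
| down | higher | JunDOWN |
| up or no change | higher | AltUP |
| down or no change | lower | AltDOWN |
| otherwise | | none |

JunUP genes are *completely* Jun-dependent at a timepoint when the KO
axotomy contrast shows no upregulation under the same cuts, *partially*
otherwise; a gene is complete over the time course when it is JunUP at
some timepoint and never KO-upregulated at any. Control genes for the
promoter analysis are those with no significant genotype effect at any
timepoint, genotype fold change below 1.3 throughout, and maximum
expression above 7 (log2 array-intensity units, about the mean baseline) —
the expression floor excludes silent promoters likely to sit in
heterochromatin. "Maximum expression" is evaluated over all samples, the
literal reading.

## What the synthetic data emulates — and what it does not

The generators produce (i) i.i.d. or order-1 Markov background sequence,
(ii) planted sites sampled column-wise from a PFM at per-kb Poisson rates,
placed without overlap on a random strand, (iii) ortholog bundles in which
each planted site survives intact per species with a retention
probability while background diverges by per-base substitution, with
identity position maps minus optional random deletions, and (iv) a
two-genotype × {uninjured, d1, d4, d14} expression design with group
means placed so each planted class satisfies its pattern, contrasts from
Welch t-tests with Benjamini–Hochberg correction per contrast.

Key defaults and why:

* **Motif sharpness** — the built-in AP1/CRE/SRF/GC matrices use
  per-position dominance 0.95 (~1.7 bits), matching the near-deterministic
  core positions of curated matrices for these factors. Blurrier motifs
  make planted sites statistically indistinguishable from background at
  any threshold, which tests the corpus, not the method.
* **Divergence 0.4** — roughly the mean neutral promoter divergence of
  mouse against rat, guinea pig, rabbit, human and marmoset. Much lower
  values make the pseudo-species nearly identical to mouse, so background
  matches pass the conservation filter by chance and the filter loses its
  point.
* **Retention 0.9** per species per site; **rates** in the planted-truth
  studies are 0.15 vs 0.05 sites/kb over 200 × 1 kb promoters per arm —
  a 3× contrast at realistic site densities.
* **Expression design** — 4 replicates per group, residual sd 0.25 log2
  units, baseline ~8; every informative contrast in a planted class has
  effect ≥ the `effect` parameter (default 2; recovery tests use 3, at
  which a power calculation puts per-gene misclassification below
  10⁻⁵, i.e. margin-clearing for exact-recovery checks).

Real promoters are not i.i.d. sequence: they have CpG islands, repeats,
composition gradients toward the TSS, correlated site clustering, and
indel-rich alignments. Passing the planted-truth tests therefore shows the
machinery is correct and calibrated under its own statistical model — not
that effect sizes seen on real promoter corpora will match.

## Numerical and procedural choices

* Normalized scores are clamped to $[0,1]$ against floating-point
  round-off; threshold comparisons are inclusive (`>=`).
* Strand ties at one offset keep the `+` strand.
* Candidate thresholds are the exact observed score values, so count
  tallies use exact equality on bit-identical doubles (scores are computed
  once and reused).
* The grid runner orders results by motif then objective value descending;
  all TSV output is written deterministically, and every CLI run writes a
  manifest (inputs, md5 hashes, seed, parameters) so identical
  configurations give byte-identical outputs.
* Problem sizes in the validation suite (200 promoters × 1 kb per arm for
  power; 30 × 1 kb arms across 200 corpora for null calibration; 50-seed /
  25-seed replicate counts) were chosen as the smallest designs at which
  the binomial power calculations above stabilize, and are fixed in the
  tests.

## Known limitations

* The conserved-score window is substitution-aware but indel-blind beyond
  the gap-removed mapping: an indel inside the ortholog window shifts
  sequence into or out of it rather than being aligned around.
* The rate-model binomial treats the control rate as known; at very small
  `lenB` this is anticonservative, which is one reason the admissibility
  band and the resampling FDR — not the raw p-value — gate what is
  reported.
* The FDR estimate is an expected count of equal-or-better null groups,
  not a probability; values above 1 are possible and simply mean "worse
  than typical chance".
* Grouping compares hit locations only at each matrix's own optimum, so
  two matrices for the same factor optimized to very different thresholds
  can land in different groups.

## A worked run

```{r worked, eval = FALSE}
fx <- worked_fixture()
fit <- resample_fdr(fx$test, fx$control, fx$pfms, fx$bundles,
                    window = 500, n_required = 1, objective = "or",
                    n_runs = 50, seed = 1)
tidy(fit$results)
fit$groups
autoplot(fit$results)
```
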