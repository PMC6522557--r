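---
title: "Methods: linking gene fusions to cancer cell fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gene fusions to cancer cell fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscreen)
```

## The problem

Fusion transcripts called from tumour RNA-seq are abundant, but most are
passengers: artifacts of error-prone callers or by-products of genomic
instability. This package implements a computational triage that asks, for
each fusion observed in a cancer cell line, whether there is functional
evidence that the cell depends on it — from recurrence beyond chance,
from deregulated partner-gene expression, from differential drug
sensitivity, and most directly from pooled CRISPR-Cas9 loss-of-fitness
screens. Every stage is exercised end to end on synthetic data with
planted ground truth, so the statistical machinery can be validated
without access to controlled-access genomic data.

## Consensus fusion catalog

Callers disagree; single-caller calls are unreliable. A *fusion
transcript* is retained when it is supported by at least two algorithms
and at least four reads aligning directly across the breakpoint, and its
ordered gene pair is absent from a blacklist of fusions seen in
non-neoplastic tissue. Calls from different callers are considered the
same transcript when sample and ordered gene pair agree and both
breakpoints lie within a tolerance, 5 bp by default. The tolerance is
configurable because there is no universally accepted definition of
"same transcript" across callers; 5 bp absorbs the off-by-a-few
coordinate conventions of common callers without merging genuinely
distinct isoforms. Representative breakpoints come from the
best-supported call; the junction-read criterion uses the maximum over
supporting callers (a transcript convincingly seen by one caller and
weakly confirmed by another is kept). Coordinates are 1-based and
inclusive: `breakpoint5` is the last base retained from the 5&prime;
gene, `breakpoint3` the first base retained from the 3&prime; gene.
Cell lines sequenced by two sources are resolved by a source-precedence
list before any counting.

Any number of transcripts joining the same ordered gene pair in one cell
line is a single *fusion event*; an event is labelled in frame if any
constituent transcript is. A *unique fusion* is a distinct ordered pair
cohort-wide, *recurrent* if present in two or more lines. Reported
percentages are rounded to the nearest integer with halves away from
zero.

## Recurrence beyond chance

Whether a gene is fused in a cancer type more often than expected is
judged against a null that preserves both how often each gene is fused
and how fusion-laden each sample is. The binary gene × sample occurrence
matrix is randomized by checkerboard switches: two 1-cells in distinct
rows and columns whose complementary corners are 0 are swapped,
preserving all margins exactly. Each chain step *proposes* one switch
drawn uniformly from pairs of 1-cells and leaves the state unchanged
when the proposal is invalid. Counting proposals rather than accepted
swaps matters: the proposal kernel is then symmetric and constant across
states, making the chain's stationary distribution exactly uniform over
margin-compatible matrices, whereas stopping after a fixed number of
*successful* swaps biases sampling toward matrices that admit more
switches (verifiably so: on the 3×3 margin-(2,1,1)/(2,1,1) space the
switch-degrees are 4,3,3,3,3). The default chain length is 10× the
number of 1-entries, a mixing heuristic. A known degenerate corner:
matrices with exactly two 1-cells in general position have a two-state,
strictly alternating chain; such inputs are far below the scale of any
real occurrence matrix.

Per (gene, cancer type), the p-value is the plus-one-smoothed fraction
of permutations in which at least the observed number of samples of that
type carry the gene fused: `p = (1 + b) / (1 + R)`. Plus-one smoothing
avoids the impossible `p = 0` with finite permutations. Only pairs with
at least one observed fused sample are tested — absent genes would
contribute guaranteed `p = 1` rows and inflate the Benjamini–Hochberg
correction, which is applied over all tested pairs.

## Fusion status and partner-gene expression

For genes recurrently fused at an end (three or more carrier lines, per
end), expression (log2 RPKM) is modelled by ordinary least squares as

G = &beta;<sub>cov</sub> X<sub>cov</sub> + &beta;<sub>fusion</sub> X<sub>fusion</sub> + &psi;

with cancer type (in pan-cancer runs), microsatellite-instability status
and the gene's copy-number category as covariates. The CNA covariate is
a three-level factor (loss / neutral / amplified) rather than a numeric
dose, avoiding a linearity assumption; MSI is binary with unknown status
as its own level. The fusion-term p-value is the type-II F-test (via
`car::Anova`), which for a single term without interactions equals the
nested-model F-test — the test suite asserts that equivalence to 1e-10
against an independently coded oracle. BH adjustment is applied within a
stratum; a pan-cancer analysis is one stratum. Covariates enter the
design before the fusion term, so that a fusion indicator that is a
linear combination of covariates is the aliased term and is reported as
not testable rather than silently absorbing a covariate's effect.

Rare fusions cannot be modelled this way, so 3&prime;-partner outlier
overexpression is flagged separately: the carrier's expression is ranked
against all *other* lines (strict inequality, carrier excluded from its
own reference set); a rank at or above 0.95 flags the event unless the
carrier is amplified for the gene, since amplification offers a mundane
explanation for high expression.

## Drug-sensitivity associations

Log-scale IC50 values are modelled per drug by OLS with tissue and MSI
covariates (tissue is dropped automatically for drugs screened in one
tissue). Stage 1 screens established cancer functional events (CFEs —
driver mutations, copy-number segments, methylation states); a CFE
passing FDR &lt; 25%, p &lt; 0.001 and both Glass Deltas &gt; 1 for a
drug becomes a stage-2 covariate for that drug. Stage 2 tests recurrent
fusion events (two or more positive lines) with those confounders
included; hits require FDR &lt; 25% and both Glass Deltas &gt; 1, with
negative effect sizes meaning sensitization. The two stages are
BH-corrected separately, each over its own family of tests.

Glass Deltas are |mean difference| divided by each group's own sample
standard deviation, computed on raw (unadjusted) IC50s — matching the
definition of the statistic rather than mixing it with model residuals.
A group of size one, or with zero spread, leaves its delta undefined,
which fails the effect-size gate without aborting the run. A saturated
fit with zero residual variance yields no F-test; the association is
reported with effect size and deltas but no p-value.

## The fusion essentiality score (FES)

Pooled CRISPR screens usually average guide-level fold changes to gene
level. That throws away exactly the signal needed here: a fusion splits
each partner gene into a retained and a lost part, and only guides
cutting in the retained part ("mapping" guides) probe the fusion
product. The mapping rule follows gene orientation: for the 5&prime;
gene on the plus strand, a guide maps when its cut site is at or before
the breakpoint (at or after on the minus strand); the 3&prime; gene is
the mirror image. A cut exactly at the breakpoint counts as mapping on
either side — a symmetric, documented tie rule. Guide position is a
single cut-site coordinate from the library annotation; the protospacer
extent is not modelled.

Fold changes are first corrected (upstream of this package) and scaled
per cell line so the median over non-essential-gene guides is 0 and the
median over essential-gene guides is −1; a cell line where the essential
median is not below the non-essential median fails a basic screen
quality contract and raises an error. Each guide is then Z-normalized
across the cell lines of one screening dataset (sample sd; degenerate
rows become zeros). Per partner gene with at least one mapping guide,
the mean mapping Z minus the mean non-mapping Z is taken — zero standing
in for the non-mapping mean when a gene has no non-mapping guide — and
the per-gene differences are averaged into the FES. Strongly negative
FES in the carrier line means the fusion-containing region is
preferentially required for fitness.

Significance comes from randomizing the scaled fold changes *within*
each cell line, recomputing Z and the FES each time: this preserves each
line's fold-change distribution while breaking the guide-to-position
assignment. The p-value is depletion-sided,
`p = (1 + #{null FES ≤ observed}) / (1 + n_perm)`. One stated
description of this test counts randomized scores *higher* than
observed; read literally, that would assign the strongest depletions
p ≈ 1, so the depletion-sided reading is implemented. BH FDR is computed
per screening dataset (libraries differ; datasets are never pooled), and
significant hits must additionally show a pooled raw mapping minus
non-mapping scaled fold-change difference of at most −0.45 — the pooling
mirrors the FES construction, with absent non-mapping means treated as
zero. Event-level significance is "any transcript, any dataset" for the
cell line. Transcripts with no mapping guide on either gene are
untestable and reported as such.

## Pre-ranked set enrichment

To ask whether a class of transcripts (known oncogenic fusions, in-frame
transcripts, planted functional fusions in the synthetic study)
concentrates at one end of a ranking, a weighted running-sum statistic
is used: sorted by decreasing score (ties broken by item id for
reproducibility), the walk rises by the normalized |score|^w at set
members (default w = 1; w = 0 gives the classic unweighted form) and
falls by 1/(N − m) elsewhere; the enrichment score is the walk value of
largest magnitude, earliest such step winning within a 1e-9 tolerance so
exactly symmetric extremes resolve deterministically. The p-value draws
random same-size sets; it is one-sided and sign-matched, since the
direction of enrichment is part of the hypothesis. A consequence worth
stating: under the null the rejection rate at level &alpha; is close to
2&alpha; (each sign contributes a one-sided test); the test suite
asserts that property rather than uniformity. No normalization across
set sizes or leading-edge reporting is attempted.

## Synthetic study and what it does (not) show

`sim_config()` fixes the reference conditions: 60 cell lines in 4 cancer
types, 120 genes on 4 chromosomes, 20 planted fusion pairs — six
recurrent within a single cancer type (4 carriers each), six recurrent
across types (3 carriers), eight singletons — with three callers, a 10%
per-caller dropout, single-caller and low-read noise calls, and 5
blacklist pairs that are called convincingly but must be removed. Five
pairs are CRISPR-functional (mapping guides depleted by −1 scaled unit
in carriers, guide noise sd 0.25, 5 guides per gene); six drive partner
expression (+3 log2 units at the 3&prime; end, oncogene-like, or −2 at
the 5&prime; end, TSG-like; residual sd 1); one sensitizes its carriers
to a drug by −3 log IC50; one is confounded — its carriers coincide with
a CFE that carries the real −3 effect on another drug, so the fusion
association must vanish once the stage-1 covariate enters. Fold changes
are emitted on the already-scaled convention (0/−1 anchors), with
`scale_to_essentials()` exercised separately. All noise is Gaussian.

These are deliberately clean conditions: effects are additive, noise is
homoscedastic, breakpoints are exact, guides are evenly spaced, and
every planted effect is recorded in a truth manifest that tests resolve
against the generated files. Passing therefore demonstrates the
statistical machinery — calibration of the permutation nulls, oracle
equivalence of the ANOVA p-values, recovery of planted effects at the
stated sizes — not robustness to the pathologies of real screens
(heterogeneous guide efficiency, copy-number artifacts in CRISPR counts,
dose–response fitting error, subclonal fusions). Those corrections are
upstream inputs by design.

## Numerical and operational choices

* Permutation sizes: tests and the acceptance script run the recurrence,
  FES and enrichment nulls at 1000 permutations and the calibration /
  recovery suites at 50 replicates; these sizes give Monte-Carlo
  standard errors well inside the asserted bands while keeping the suite
  quick. All permutation defaults in the API are 10,000 (1000 for
  enrichment), the scale intended for real analyses.
* Every stochastic stage takes an explicit seed; `run_pipeline()`
  derives stage seeds from one global seed by fixed offsets, so a single
  integer reproduces the whole run byte-for-byte and any stage can be
  re-run alone. The run manifest records seeds, parameters and output
  digests, and contains no timestamps precisely so that reruns are
  byte-identical.
* Degenerate inputs are handled by explicit rules stated above (zero-sd
  Z rows, groups of size one, saturated fits, all-ones occurrence
  matrices, transcripts without mapping guides) rather than errors
  mid-run; genuine contract violations (inverted essential anchors,
  missing annotations, rank-deficient expression designs) raise errors
  naming the offending columns or samples.
* The R-level API is the interface: `run_pipeline()` orchestrates the
  stages, and each stage is an exported function over plain data frames
  and matrices read from tab-separated files (`read_fusion_calls()`,
  `read_gmt()`).

## A worked miniature

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
out <- run_pipeline(file.path(tempdir(), "demo"), cfg,
                    n_perm_recurrence = 1000, n_perm_fes = 1000)
out$summary                 # catalog counts and recurrence percentage
head(out$recurrence)        # per-(gene, cancer type) permutation test
head(out$expression)        # fusion-expression betas and type-II p
subset(out$drug_stage2, significant)
print(out$fes)              # FES table with permutation p and -0.45 filter
out$enrichment              # planted functional fusions vs FES ranking
```

## Known limitations

Per-gene (not per-pair) recurrence only; no analytical recurrence test;
no isoform-level expression; no dose–response refitting; gene-level
essentiality callers (BAGEL/MAGeCK-style) are out of scope, as are
reading-frame prediction and copy-number correction of CRISPR counts —
all are consumed as inputs where relevant. The FES inherits the
limitations of its screens: it needs mapping guides (roughly half of
real transcripts have only mapping guides, where the non-mapping mean is
zero by definition), detects gain-of-function dependence rather than
tumour-suppressor loss, and can be biased by guide efficiency and
amplification artifacts.
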