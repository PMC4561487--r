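---
title: "The sequence and shape environment of TF binding motifs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequence and shape environment of TF binding motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifenv)
```

## The problem

A transcription factor's core binding motif, summarized as a position
frequency matrix (PFM), is a weak predictor of where the protein actually
binds: genomes and in vitro selection pools contain vastly more
motif-matching sequences than bound ones. This package implements an
analysis of what distinguishes *bound* from *unbound* motif-containing
sequences when the motif itself is held fixed: the **motif environment** —
the flanking sequence around the aligned core — compared between the two
pools position by position, in nucleotide content, in predicted DNA shape
(propeller twist), and in its overall similarity to the motif itself
(the homotypic environment). Two prediction schemes quantify how much the
environment alone discriminates bound from unbound: L2-regularized linear
regression over environment features, and a two-state block hidden Markov
model scored by log-likelihood ratio.

Both experimental designs of the original analyses are reproduced in
structure: an in vitro mode (short selection probes, bound = selected
round, unbound = unselected pool) and an in vivo mode (genome-wide motif
hits inside open chromatin, bound = inside ChIP-seq peaks, unbound =
outside all peaks). The real selection and ChIP-seq datasets are not
shipped; a synthetic-data generator produces every input with planted,
recoverable effects, so each claim the package makes is testable against
ground truth.

## Motif scanning with exact p-values

Sequences are scored against the PFM in log~2~-odds against a background
nucleotide distribution. To honor p-value cutoffs the way FIMO-style
scanners do, the null distribution of scores is computed exactly by a
dynamic program: per-position scores are discretized to a grid
(granularity 1/1000 bit) and convolved across motif positions under the
background, yielding the exact tail probability of every achievable score.
All p-value decisions — scanning cutoffs, cluster-count bins, tie
detection during alignment — are made on that same integer grid, so a
score's p-value is exact rather than a float-rounded lookup. This matters:
for short motifs the achievable score distribution is coarse (a 6-mer has
at most 4096 distinct k-mers), and rounding a float score independently of
the table can misprice an entire tie group of k-mers.

Two consequences of that coarseness are worth knowing. First, the smallest
achievable p-value for a 6-mer under a uniform background is about
2.4e-4, so an alignment cutoff of 1e-4 (the default, configurable) retains
almost nothing for 6-bp motifs; the study configurations shipped in
`scenarios.R` use 1e-3 for their 6-bp synthetic motifs. Second, some
p-value windows (for example 0.05–0.1) may contain no achievable score at
all for a given PFM, in which case that cluster-count bin is legitimately
empty.

Reverse-strand windows are scored as the log-odds of the window's reverse
complement under the same PFM, and their p-values use the forward score
table. That lookup is exact whenever the background is
complement-symmetric, which both defaults are (uniform in vitro;
genome-wide mononucleotide frequencies in vivo, which are
complement-symmetric by construction when both strands are counted).

## Alignment of bound and unbound pools

`align_best_hit()` keeps, per sequence, the unique highest-scoring window
at or below the p-value cutoff; sequences with no qualifying window, with
a tied top score (compared on the discretized grid), or whose requested
flank window runs off the probe are discarded and tallied by reason.
Reverse-strand best hits are reverse-complemented into the common frame.
Pools smaller than `min_pool_size` (default 1000, the study's inclusion
filter) raise an error. Pool sizes are then equalized by deterministic
random subsampling (`match_sizes()`).

The aligned frame places the core at a fixed block; positional statistics
exclude the core and 2 bp on each side (`core_exclusion`, configurable).
The nominal in vitro window is ±10 bp, but 20-bp probes with a centered
6-bp core cannot supply it; the generator's default geometry yields the
widest window every plant supports (±6 bp, hence 8 analysis positions).
The in vivo window is ±300 bp.

## Positional comparison and preference calls

For each flank position, the bound and unbound pools are compared with a
one-sided rank test in both directions. The package defaults to the
unpaired Wilcoxon rank-sum test: the two pools are independent samples,
and nothing pairs sequence *i* of one pool with sequence *i* of the other.
The index-paired signed-rank variant is available (`test = "signed_rank"`)
for fidelity to analyses that treated the size-matched pools as paired;
on size-matched pools the two give very similar profiles. Exact
distributions are used for n ≤ 25 tie-free data; binary indicator columns
always tie, so they take the normal approximation with continuity and tie
correction.

Each one-sided family of p-values is corrected for multiple testing across
positions, separately per profile. The default is Storey q-values with
pi0 estimated at lambda = 0.5; because profiles can be as short as a few
positions, the raw estimate `mean(p > 0.5)/0.5` is smoothed by add-one,
`pi0 = min(1, (1 + #{p > 0.5}) / (0.5 m))`, which keeps a fully
left-shifted small profile from collapsing q to zero. Benjamini–Hochberg
is available as `method = "BH"`.

The signed significance score is `delta = -log10(q_greater)` where the
bound mean is higher and `log10(q_less)` (negative) where the unbound mean
is higher. A TF is called high-GC (or high-AT) when at least five
positions are significant at q ≤ 0.05 in the corresponding direction; with
both directions above threshold the larger count wins.

## DNA shape

Propeller twist is predicted per position by a sliding pentamer lookup
table; position *i* takes the value of the pentamer centered on it, the
first and last two positions are undefined and excluded from statistics
rather than imputed (as are positions whose pentamer covers an N). The
table is a pluggable TSV input (512 reverse-complement-reduced or full
1024 rows; propeller twist is a base-pair parameter, so
value(revcomp(p)) = value(p) is enforced). Tests and synthetic analyses
use `synthetic_shape_table()`: an affine function of pentamer GC count
(−14° at AT-rich up to about −5° at GC-rich, matching the observed
direction that GC-rich sequence has less pronounced propeller twist) plus
RC-symmetrized pentamer noise. It is explicitly synthetic; analyses of
real data should supply the published pentamer model.

## Homotypic clusters and the homotypic environment

Off-core windows (those sharing no position with the core block) are
scored on both strands. Cluster counts bin hits at p ≤ 0.001, 0.001–0.05
and 0.05–0.1; counted hits may overlap each other (raw window counts).
The homotypic environment score of a sequence is the unthresholded mean
over off-core windows of the better strand's log-odds; the better-strand
choice reflects that a binding site is a site on either strand
(forward-only mode is available). Two controls probe whether positional
differences are carried by discrete weak sites: masking every position
covered by a significant off-core hit, and dropping every sequence that
contains one; both leave a planted pure-GC shift intact in the tests.

## Co-occupancy

For a TF pair (A, B), motif-site pairs overlapping by ≥1 bp are discarded
from A's numerator and denominator (related PFMs often call the same
underlying site), and the co-occupancy fraction is the share of A's
remaining sites whose closest edge-to-edge gap to a B site is ≤ 300 bp
(midpoint mode available). GC-preference similarity between two TFs is the
ratio of their mean signed significance summaries, oriented so the
larger-magnitude summary is the denominator: the ratio lives in [−1, 1],
1 meaning identical direction and strength, negative meaning opposite
preferences; when both summaries are exactly zero the ratio is defined as
1 with a degeneracy flag.

## Prediction: regularized regression

Four per-sequence environment features are extracted from the flanks only:
mean GC fraction, mean propeller twist, homotypic environment score, and
the homotypic cluster sum (sum of off-core window scores at p ≤ 0.001).
The core motif score is carried along solely for motif-strength matching —
quantile-binned subsampling that equalizes the core-score distributions so
the environment models cannot exploit motif strength — and is never a model
feature.

The model is exactly what its name says: multiple *linear* regression on
0/1 labels with an L2 penalty (closed-form solve, intercept unpenalized,
features standardized on each training portion), scored by AUROC on the
raw linear predictions. Outer 10-fold cross-validation is stratified;
lambda is chosen per outer fold by an embedded 10-fold CV maximizing inner
AUROC over a 13-point grid log-spaced from 1e-3 to 1e3 (spanning the
under- to over-regularized regimes). The empirical significance cutoff is
the maximum AUROC over full nested-CV refits on label permutations.
Everything is deterministic given (seed, folds, grid). Cross-domain
transfer fits on one domain (lambda by CV on that domain only,
standardization learned there) and scores the untouched other domain.

## Prediction: block HMM

The generative model emits, at every boundary, one background base with
probability 0.99 or a complete motif block with probability 0.01 — the
stated 0.99 transition dominance read as a state-independent emission
choice, which keeps a single well-defined likelihood; the block is forward
with probability equal to the strand bias *s*, precalculated as the
forward fraction of motif hits at p ≤ 0.001 in the bound pool. The forward
recursion

F(i) = 0.99·β(x~i~)·F(i−1) + 0.01·[i ≥ L]·(s·P~fwd~ + (1−s)·P~rev~)·F(i−L)

is computed in log space, vectorized over a pool. Each sequence's score is
the log-likelihood ratio against a fixed genomic background estimated from
the TF's unbound pool. Three background-state emission modes are compared:
the genomic background itself, the PFM's column-average base frequencies,
and that average with the A/G and T/C masses swapped (exchanging the AT
and GC totals while preserving purine/pyrimidine pairing — the package's
reading of "inversed" frequencies). No end state is modeled; likelihoods
are only ever compared between equal-length sequences (pools are
length-matched), so normalization over lengths cannot affect AUROC.
Whole sequences are scored, core included.

## The synthetic generator: what it emulates, and what it does not

`generate_pools()` emulates fixed-length selection probes: every sequence
(bound and unbound — both pools contain the motif, as in the study design)
carries exactly one core plant sampled base-by-base from the PFM at a
recorded offset and orientation; defaults are 20-bp probes (the dominant
probe length) with a 6-bp core at center ± 1. Planted effects, all
recorded in a truth table: a flank GC shift between pools; a homotypic
fraction of bound flank positions drawn from the PFM's column-average
distribution; and Poisson-rate weak off-core plants, rejection-sampled
from a temperature-softened PFM until they pass the planting p-value
(0.001), so "recovered at the planting threshold" is well defined.
`generate_genome()` emulates the in vivo branch: a background genome,
non-overlapping open intervals at a target coverage, peaks inside some of
them, and motif plants at interval centers with environment effects only
inside peaks.

The frozen study conditions live in `scenarios.R`: the power scenario
plants a 4-percentage-point GC shift (the reported in vivo average) at
n = 5000 per pool; the cluster scenario plants three weak sites per bound
sequence (the reported average) in 80-bp probes; the homotypic scenario
uses a 0.4 homotypic fraction — 0.5 and above saturates AUROC at 1.0,
which destroys strict-order comparisons between HMM modes; the regression
scenario plants the GC and homotypic effects independently with *no*
discrete weak plants, so the cluster feature carries only signal embedded
in the environment, mirroring the reported feature hierarchy in which
clusters are the weakest feature and the combined GC/shape/environment
model is the best.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: selection-round amplification biases, probe
synthesis artifacts, chromatin-accessibility confounding beyond the
open/closed split, dinucleotide or higher-order background structure,
inter-position dependence within motifs, and real shape physics beyond a
GC-affine caricature. Recovery of planted effects demonstrates the
machinery is correct and calibrated, not that real TFs behave this way.

## Numerical choices and degenerate inputs

* Score grid granularity 1e-3 bits; ties compared on the grid.
* PFM pseudocount 0.01 per cell with renormalization, configurable.
* All-tied rank-test columns return p = 1 on both sides (no evidence).
* Zero eligible off-core windows: sequence skipped with a report, or an
  error when the whole frame is too short.
* Empty HMM sequence has log-likelihood 0; N in an HMM sequence is an
  error (mask upstream).
* Constant feature columns get coefficient 0 with a warning.
* Strand bias with no hits defaults to 0.5.
* Flanks truncated by chromosome ends exclude the record (keeping
  per-position n constant) rather than padding.
* Motif hits overlapping a peak boundary are classified by hit midpoint.

## Problem sizes

The shipped analyses and the acceptance script run, per invocation: the
scanning oracle on 102 random 80-bp sequences at motif lengths 4–6; the
HMM tiling oracle at L = 2, n ≤ 8; 100 null replicates at 400 sequences
per pool; 20 power replicates at 5000 per pool; 20 homotypic replicates at
300 per pool; one regression study at 2000 per pool; cluster recovery at
1000 bound sequences; and a double end-to-end run at 400 per pool for
bit-identity. These sizes give the positional tests per-position z-scores
well above the calling threshold at the planted effect sizes while keeping
a full rerun in the minutes range on one core.

## Known limitations

* Only zero-order backgrounds; no gapped or variable-length motifs; no
  motif discovery beyond the IUPAC-seed refinement.
* Only propeller twist among shape features.
* The Storey estimator's add-one smoothing makes very short profiles
  conservative.
* Whether the original positional test paired sequences, and whether its
  q-value correction pooled the two one-sided families, is not derivable
  from the description; both choices here (unpaired; separate families)
  are documented defaults, not claims about the original.
* The co-occupancy denominator counts motif instances, not
  motif-containing peaks; with one motif instance per peak the two
  coincide.
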