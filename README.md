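# motifenv

Analysis of the sequence and DNA-shape environment surrounding
transcription-factor (TF) core binding motifs.

A TF's position frequency matrix (PFM) massively over-predicts binding:
most motif-matching sequences, in vitro and in the genome, are never
bound. This package asks what distinguishes bound from unbound sequences
*that carry the same motif*, and answers it with a reproducible pipeline:

1. **Motif-anchored alignment.** Bound and unbound pools are scanned with
   the PFM (log2-odds scores with *exact* p-values from a dynamic program
   over a discretized score grid), each sequence is aligned on its unique
   best hit (ties and misses discarded and tallied), and pool sizes are
   matched.
2. **Positional environment statistics.** For every flank position
   (excluding the core and 2 bp each side), the pools are compared by
   one-sided Wilcoxon tests with FDR q-values; the signed score
   delta = ±log10(q) summarizes each position, and a TF is called
   high-GC / high-AT when ≥ 5 positions are significant (q ≤ 0.05) in one
   direction. The same machinery profiles predicted propeller twist from a
   sliding-pentamer shape table.
3. **Homotypic clusters and environment.** Off-core motif hits are counted
   in three p-value bins; the homotypic-environment score is the
   unthresholded mean off-core window log-odds (better strand). Masking
   and sequence-dropping controls separate discrete weak sites from the
   overall environment.
4. **Co-occupancy.** Fraction of one TF's motif sites within 300 bp of
   another's (overlapping sites discarded), related to the similarity of
   their GC-preference profiles.
5. **Prediction.** (a) L2-regularized *linear* regression on environment
   features (GC, propeller twist, homotypic environment, homotypic
   clusters) with nested 10-fold cross-validation for the penalty, AUROC
   scoring, motif-strength matching and shuffled-label significance
   cutoffs; (b) a two-state block HMM (background emissions vs whole motif
   blocks, 0.99/0.01 mixture, precalculated strand bias) scored by
   log-likelihood ratio under three background emission modes.

Real selection/ChIP-seq data are not bundled; a first-class synthetic
generator (`generate_pools()`, `generate_genome()`) plants recoverable
effects — flank GC shifts, homotypic flank composition, weak off-core
sites, peaks in open chromatin — and records the truth, so every analysis
is benchmarked against known ground truth. See the methods vignette
(`vignettes/motif-environment.Rmd`) for models, assumptions and parameter
choices.

## Worked example

Plant the study's average effect size — a 4-percentage-point flank GC
shift in the bound pool — at n = 5000 sequences per pool, run the
alignment pipeline and call the environment preference:

```r
library(motifenv)

gen   <- generate_pools(scenario_power(seed = 1))   # +4 pp GC, n = 5000/pool
pools <- align_scenario(gen, p_cutoff = 1e-3, min_pool_size = 1000, seed = 1)
gc    <- delta_profile(pools$bound, pools$unbound, "GC")
round(gc[, c("position", "mean_bound", "mean_unbound", "delta")], 3)
#  position mean_bound mean_unbound delta
#        -6      0.541        0.504 3.209
#        -5      0.533        0.492 3.434
#        -4      0.541        0.525 1.577
#        -3      0.538        0.499 3.345
#         3      0.539        0.493 3.663
#         4      0.542        0.498 3.663
#         5      0.543        0.520 2.047
#         6      0.535        0.492 3.663
call_preference(gc, tf = "synthetic")
#         tf    call n_significant_positions mean_delta_gc
#  synthetic high-GC                       8      3.618208
```

All 8 flank positions are significantly GC-enriched in the bound pool
(positive delta = bound-higher at −log10 q), and the recovered pool-mean
GC difference (3.6 pp) tracks the planted 4 pp (alignment subsampling
attenuates it slightly). The HMM comparison on homotypically-flanked
pools shows the background-mode ordering:

```r
run_hmm_modes(generate_pools(scenario_homotypic(seed = 1)))
#      genomic  pfm_average pfm_inversed
#        0.656        0.929        0.141
```

Using the motif's own average composition as the HMM background
discriminates bound from unbound far better than the genomic background,
and swapping the AT/GC masses is far worse than either — the homotypic
environment carries the signal.

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study on synthetic data
and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates all inputs (pools, toy genome, shape table) |
| `02_align_profiles.R` | alignment + positional GC/shape profiles + preference calls |
| `03_homotypy.R` | cluster counts, environment scores, masking controls |
| `04_invivo_cooccupancy.R` | genome split into bound/unbound, co-occupancy vs family |
| `05_predict.R` | regression models, transfer, HMM background modes |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

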