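#!/usr/bin/env Rscript
# Homotypic-cluster counts and homotypic-environment scores for the
# paperlike pools, with the masking/dropping controls showing that the GC
# signal is not carried by discrete weak sites alone.

suppressMessages(library(motifenv))

data_dir <- "results/data/paperlike"
out <- "results/homotypy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gen <- read_pools(data_dir)
x <- gen$cfg$motif
bg <- background()
tp <- truth_aligned_pools(gen)
pv <- exact_pvalues(x, bg)

message("== cluster counts by p-value bin, bound vs unbound")
hb <- count_clusters(tp$bound, x, bg, pool_u = tp$unbound, pv = pv)
cmp <- attr(hb, "comparison")
print(cmp)
write.table(cmp, file.path(out, "cluster_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hb, file.path(out, "bound_homotypy_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("== homotypic environment score comparison")
eb <- env_similarity(tp$bound, x, bg, pv = pv)
eu <- env_similarity(tp$unbound, x, bg, pv = pv)
p_env <- compare_position(unname(eb), unname(eu))
message(sprintf("  mean env score bound %.3f vs unbound %.3f bits, p(bound>unbound) = %.3g",
                mean(eb), mean(eu), p_env[["p_greater"]]))

message("== control: mask significant off-core matches, recompute GC delta")
gc0 <- delta_profile(tp$bound, tp$unbound, "GC")
mb <- mask_motif_matches(tp$bound, x, bg, p_cutoff = 0.001, pv = pv)
mu <- mask_motif_matches(tp$unbound, x, bg, p_cutoff = 0.001, pv = pv)
gc_masked <- delta_profile(mb, mu, "GC")
message(sprintf("  mean dGC: %.3f pp unmasked, %.3f pp masked",
                100 * mean(gc0$mean_bound - gc0$mean_unbound),
                100 * mean(gc_masked$mean_bound - gc_masked$mean_unbound)))

message("== control: drop sequences with significant off-core matches")
db <- drop_motif_sequences(tp$bound, x, bg, p_cutoff = 0.001, pv = pv)
du <- drop_motif_sequences(tp$unbound, x, bg, p_cutoff = 0.001, pv = pv)
m <- match_sizes(db, du, seed = 1L)
gc_dropped <- delta_profile(m[[1]], m[[2]], "GC")
message(sprintf("  dropped %d bound / %d unbound sequences; mean dGC %.3f pp",
                attr(db, "n_dropped"), attr(du, "n_dropped"),
                100 * mean(gc_dropped$mean_bound - gc_dropped$mean_unbound)))

ctrl <- data.frame(
  analysis = c("unmasked", "masked", "dropped"),
  mean_delta_gc_pp = 100 * c(mean(gc0$mean_bound - gc0$mean_unbound),
                             mean(gc_masked$mean_bound - gc_masked$mean_unbound),
                             mean(gc_dropped$mean_bound - gc_dropped$mean_unbound)),
  n_sig_positions = c(sum(gc0$q_greater <= 0.05),
                      sum(gc_masked$q_greater <= 0.05),
                      sum(gc_dropped$q_greater <= 0.05)))
write.table(ctrl, file.path(out, "masking_controls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(env_p_greater = p_env[["p_greater"]],
                          mean_env_bound = mean(eb),
                          mean_env_unbound = mean(eu)),
                     file.path(out, "env_comparison.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote homotypy outputs under ", out)
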