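#!/usr/bin/env Rscript
# Prediction schemes: L2-regularized regression over environment features
# (single, two-feature and combined models, with the shuffled-label cutoff
# and an in vitro -> in vivo style transfer) and the block-HMM
# log-likelihood-ratio scorer under its three background modes.

suppressMessages(library(motifenv))

out <- "results/predict"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

message("== regression models on independent planted GC/homotypic effects")
gen <- generate_pools(scenario_mlr(seed))
r <- run_mlr_models(gen, seed = seed)
auc_tab <- data.frame(model = names(r$cv),
                      auroc = vapply(r$cv, `[[`, 0, "auroc_mean"),
                      se = vapply(r$cv, `[[`, 0, "auroc_se"))
print(auc_tab, row.names = FALSE)
null_cut <- shuffled_null(r$features, r$labels, c("gc", "prot", "env"),
                          n_shuffles = 3, seed = seed)$null_cutoff
message(sprintf("  shuffled-label cutoff: %.3f", null_cut))
write.table(auc_tab, file.path(out, "mlr_aurocs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("== transfer: train on one generated domain, test on another")
gen2 <- generate_pools(scenario_mlr(seed + 50L, n = 1000L))
r2 <- run_mlr_models(gen2, models = list("gc"), seed = seed)
tr <- transfer_predict(r$features[, c("gc", "prot", "env")], r$labels,
                       r2$features[, c("gc", "prot", "env")], r2$labels,
                       seed = seed)
message(sprintf("  transfer AUROC %.3f (lambda %.3g)", tr$auroc, tr$lambda))

message("== HMM background modes over 20 homotypic replicates")
modes <- vapply(1:20, function(rr)
  run_hmm_modes(generate_pools(scenario_homotypic(seed = 8000 + rr))),
  c(genomic = 0, pfm_average = 0, pfm_inversed = 0))
hmm_tab <- data.frame(mode = rownames(modes),
                      auroc_mean = rowMeans(modes),
                      auroc_sd = apply(modes, 1, sd))
print(hmm_tab, row.names = FALSE)
# paired rank test between modes over replicates
p_avg_gen <- wilcox.test(modes["pfm_average", ], modes["genomic", ],
                         paired = TRUE, alternative = "greater")$p.value
p_gen_inv <- wilcox.test(modes["genomic", ], modes["pfm_inversed", ],
                         paired = TRUE, alternative = "greater")$p.value
message(sprintf("  pfm_average > genomic: p = %.2g; genomic > inversed: p = %.2g",
                p_avg_gen, p_gen_inv))
write.table(hmm_tab, file.path(out, "hmm_aurocs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(mlr_null_cutoff = null_cut,
                          transfer_auroc = tr$auroc,
                          hmm_p_avg_gt_genomic = p_avg_gen,
                          hmm_p_genomic_gt_inversed = p_gen_inv),
                     file.path(out, "predict_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote prediction outputs under ", out)
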