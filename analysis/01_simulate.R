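#!/usr/bin/env Rscript
# Generate the synthetic study inputs: in vitro probe pools under the null
# and under planted effects, and a toy genome with peaks and open chromatin
# for the in vivo path. All downstream scripts read from results/data/.

suppressMessages(library(motifenv))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

message("== null pools (equal GC, no plants)")
write_pools(generate_pools(scenario_null(seed, n = 1000L)),
            file.path(out, "null"))

message("== power pools (+4 pp flank GC in the bound pool, n = 5000)")
write_pools(generate_pools(scenario_power(seed)), file.path(out, "power"))

message("== paperlike pools (GC + homotypic + weak-site effects, 80 bp)")
write_pools(generate_pools(scenario_paperlike(seed, n = 2000L)),
            file.path(out, "paperlike"))

message("== homotypic pools for the HMM comparison")
write_pools(generate_pools(scenario_homotypic(seed, n = 500L)),
            file.path(out, "homotypic"))

message("== toy genome with peaks and DNase track")
cfg_g <- synthetic_config(seed = seed, genome_len = 2e5, n_chrom = 2L,
                          n_peaks = 30L, flank_gc_bound = 0.55)
geno <- generate_genome(cfg_g)
write_fasta(geno$genome, file.path(out, "genome.fasta"))
write_bed(geno$peaks, file.path(out, "peaks.bed"))
write_bed(geno$dnase, file.path(out, "dnase.bed"))
write_bed(geno$sites, file.path(out, "sites_truth.bed"))
write_pfm(cfg_g$motif, file.path(out, "genome_motif.meme"))

message("== pentamer propeller-twist table (synthetic, RC-symmetric)")
write_shape_table(synthetic_shape_table(1L), file.path(out, "shape_table.tsv"))

message("wrote inputs under ", out)
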