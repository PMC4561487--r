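test_that("random PFMs hit their information-content and GC targets", {
  # entropy extremes
  u <- random_pfm(5, 0, 0.5, seed = 1)
  expect_equal(unname(u$freq), matrix(0.25, 5, 4), tolerance = 0.01)
  c2 <- random_pfm(5, 2, 0.5, seed = 1)
  expect_true(all(apply(c2$freq, 1, max) > 0.99))
  # realized IC and GC across draws
  ic_of <- function(x) mean(apply(x$freq, 1, function(p) {
    p <- p[p > 0]; 2 + sum(p * log2(p))
  }))
  ics <- vapply(1:40, function(s) ic_of(random_pfm(8, 1.2, 0.6, seed = s,
                                                   pseudocount = 0)), 0)
  expect_lt(abs(mean(ics) - 1.2), 0.1)
  gcs <- vapply(1:40, function(s)
    sum(colMeans(random_pfm(8, 1.2, 0.6, seed = s, pseudocount = 0)$freq)[2:3]), 0)
  expect_lt(abs(mean(gcs) - 0.6), 0.05)
})

test_that("pool generation is bit-identical given (config, seed)", {
  cfg <- synthetic_config(seed = 301, n_bound = 60, n_unbound = 60,
                          probe_len = 40, weak_motif_rate = 1,
                          homotypic_flank_fraction = 0.2,
                          flank_gc_bound = 0.55)
  g1 <- generate_pools(cfg)
  g2 <- generate_pools(cfg)
  expect_identical(g1$bound, g2$bound)
  expect_identical(g1$unbound, g2$unbound)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_pools(synthetic_config(seed = 302, n_bound = 60,
                                        n_unbound = 60, probe_len = 40))
  expect_false(identical(g1$bound, g3$bound))
})

test_that("every sequence carries exactly one recorded core plant", {
  cfg <- synthetic_config(seed = 303, n_bound = 150, n_unbound = 100)
  gen <- generate_pools(cfg)
  tr <- gen$truth$cores
  expect_equal(nrow(tr), 250L)
  expect_setequal(tr$seq_id, c(names(gen$bound), names(gen$unbound)))
  L <- cfg$motif$L
  # the recorded window really holds the plant (forward frame after
  # orientation bookkeeping)
  for (i in sample(seq_len(nrow(tr)), 40)) {
    seqs <- if (tr$pool[i] == "bound") gen$bound else gen$unbound
    s <- seqs[[tr$seq_id[i]]]
    w <- substr(s, tr$offset[i], tr$offset[i] + L - 1L)
    if (tr$strand[i] == "-") w <- revcomp(w)
    expect_equal(nchar(w), L)
  }
  expect_true(all(tr$offset >= 7 & tr$offset <= 9))
})

test_that("realized flank GC tracks the configured values", {
  cfg <- synthetic_config(seed = 304, n_bound = 2500, n_unbound = 2500,
                          flank_gc_bound = 0.57, flank_gc_unbound = 0.50)
  tp <- truth_aligned_pools(generate_pools(cfg))
  gb <- mean(position_feature_matrix(tp$bound, "GC"))
  gu <- mean(position_feature_matrix(tp$unbound, "GC"))
  expect_lt(abs(gb - 0.57), 0.01)
  expect_lt(abs(gu - 0.50), 0.01)
})

test_that("weak plants appear at the recorded off-core coordinates", {
  cfg <- synthetic_config(seed = 305, n_bound = 400, n_unbound = 10,
                          probe_len = 80, weak_motif_rate = 3,
                          core_jitter = 0L)
  gen <- generate_pools(cfg)
  wk <- gen$truth$weak
  expect_gt(nrow(wk), 0.8 * 3 * 400)  # Poisson mean minus placement caps
  L <- cfg$motif$L
  core_off <- gen$truth$cores$offset[match(wk$seq_id, gen$truth$cores$seq_id)]
  # plants never overlap the core block
  expect_true(all(wk$offset + L - 1 < core_off | wk$offset > core_off + L - 1))
  # each plant passes the planting p-value threshold
  pv <- exact_pvalues(cfg$motif, background())
  for (i in sample(seq_len(nrow(wk)), 50)) {
    codes <- match(strsplit(wk$kmer[i], "")[[1]], BASES)
    expect_lte(motifenv:::kmer_grid_pvalue(pv, codes), cfg$weak_p)
  }
})

test_that("pools round-trip to FASTA with a truth sidecar", {
  cfg <- synthetic_config(seed = 306, n_bound = 20, n_unbound = 20)
  gen <- generate_pools(cfg)
  dir <- withr::local_tempdir()
  paths <- write_pools(gen, dir)
  expect_identical(read_fasta(paths[["bound"]]), gen$bound)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$cores$offset, gen$truth$cores$offset)
})

test_that("toy genomes respect their open-chromatin and peak contracts", {
  cfg <- synthetic_config(seed = 307, genome_len = 6e4, n_chrom = 2L,
                          n_peaks = 10L, open_len = 500L, open_fraction = 0.3)
  geno <- generate_genome(cfg)
  expect_equal(sum(nchar(geno$genome)), 6e4)
  # BED contracts: half-open, inside chromosomes, non-overlapping per chrom
  for (df in list(geno$peaks, geno$dnase, geno$sites)) {
    expect_true(all(df$start < df$end))
    expect_true(all(df$start >= 0))
    expect_true(all(df$end <= nchar(geno$genome)[df$chrom]))
  }
  for (ch in unique(geno$dnase$chrom)) {
    d <- geno$dnase[geno$dnase$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_equal(nrow(geno$peaks), 10L)
  # peaks lie inside open chromatin; all sites are inside open chromatin
  inside <- function(q, s) vapply(seq_len(nrow(q)), function(i)
    any(s$chrom == q$chrom[i] & s$start <= q$start[i] & s$end >= q$end[i]),
    logical(1))
  expect_true(all(inside(geno$peaks, geno$dnase)))
  expect_true(all(inside(geno$sites, geno$dnase)))
  # bound sites in peaks, unbound sites outside all peaks
  in_peak <- inside(geno$sites, geno$peaks)
  expect_true(all(in_peak[geno$sites$label == "bound"]))
  expect_false(any(in_peak[geno$sites$label == "unbound"]))
  # open_fraction = 1 tiles the whole genome
  cfg_full <- synthetic_config(seed = 308, genome_len = 2e4, n_chrom = 1L,
                               n_peaks = 5L, open_len = 500L,
                               open_fraction = 1)
  geno_full <- generate_genome(cfg_full)
  expect_equal(sum(geno_full$dnase$end - geno_full$dnase$start), 2e4)
})
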