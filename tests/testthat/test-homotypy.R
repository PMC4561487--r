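test_that("planted consensus copies in the flanks are counted in the top bin", {
  x <- fix_pfm4()
  cons <- consensus(x)
  # frame: 12 up-flank, core at 13..16, 12 down-flank; one exact copy in
  # each flank, both at >= 2 nt from the core
  seq1 <- paste0("TT", cons, "TTTTTT", cons, "TT", cons, "TTTTTT")
  pool <- make_pool(seq1, core_start = 13L, core_len = 4L)
  h <- homotypy_scores(pool, x, strands = "forward")
  # an exact 4-mer consensus has p = 4^-4 ~ 0.004: top achievable bin
  expect_equal(h$n_p001_05, 2L)
  # a copy straddling the core boundary by 1 bp contributes nothing
  seq2 <- paste0("TTTTTTTTT", cons, "TTTTTTTTTTT")  # starts at 10, core 13..16
  pool2 <- make_pool(seq2, core_start = 13L, core_len = 4L)
  h2 <- homotypy_scores(pool2, x, strands = "forward")
  expect_equal(h2$n_p001 + h2$n_p001_05, 0L)
})

test_that("the three p-value bins partition the off-core hit set", {
  x <- random_continuous_pfm(4, seed = 55)
  pool <- make_pool(random_dna(40, 30, seed = 56), core_start = 14L,
                    core_len = 4L)
  h <- homotypy_scores(pool, x)
  pv <- exact_pvalues(x, background())
  starts <- motifenv:::offcore_window_starts(pool, 4L)
  total <- 0L
  for (i in seq_along(pool$seqs)) {
    for (o in starts) for (strand in c("+", "-")) {
      w <- substr(pool$seqs[[i]], o, o + 3L)
      k <- if (strand == "+") w else revcomp(w)
      codes <- match(strsplit(k, "")[[1]], BASES)
      if (motifenv:::kmer_grid_pvalue(pv, codes) <= 0.1) total <- total + 1L
    }
  }
  expect_equal(sum(h$n_p001 + h$n_p001_05 + h$n_p05_10), total)
})

test_that("background off-core hit counts match the exact binomial expectation", {
  bg <- background()
  x <- random_continuous_pfm(5, seed = 57)
  pool <- make_pool(random_dna(3000, 40, seed = 58), core_start = 18L,
                    core_len = 5L)
  h <- homotypy_scores(pool, x, bg)
  # exact per-window hit probability from k-mer enumeration
  en <- enumerate_pvalues(x, bg)
  p_hit <- sum(en$prob[en$pvalue <= 0.001])
  W <- attr(h, "n_windows")
  expected <- W * p_hit
  se <- sqrt(W * p_hit * (1 - p_hit) / length(pool$seqs))
  expect_lt(abs(mean(h$n_p001) - expected), 3 * se + 1e-9)
})

test_that("environment similarity is a mean over off-core windows", {
  x <- fix_pfm4()
  # uniform PFM scores every window 0
  u <- pfm(matrix(0.25, 4, 4), pseudocount = 0)
  pool <- make_pool(random_dna(5, 24, seed = 59), core_start = 11L,
                    core_len = 4L)
  expect_true(all(env_similarity(pool, u) == 0))
  # enumeration oracle: mean of best-strand log-odds over eligible offsets
  sc <- env_similarity(pool, x)
  starts <- motifenv:::offcore_window_starts(pool, 4L)
  for (i in seq_along(pool$seqs)) {
    vals <- vapply(starts, function(o) {
      w <- substr(pool$seqs[[i]], o, o + 3L)
      max(log_odds(x, w), log_odds(x, revcomp(w)))
    }, 0)
    expect_equal(unname(sc[i]), mean(vals), tolerance = 1e-9)
  }
  # invariant under reverse-complementing the whole record (frame here is
  # symmetric: 10 bp flank each side)
  rcpool <- make_pool(revcomp(pool$seqs), core_start = 11L, core_len = 4L)
  expect_equal(unname(env_similarity(rcpool, x)), unname(sc), tolerance = 1e-9)
})

test_that("homotypic flanks outscore uniform flanks on environment similarity", {
  m <- random_pfm(6, 1.5, 0.7, seed = 61)
  cfg_h <- synthetic_config(seed = 62, n_bound = 400, n_unbound = 400,
                            probe_len = 60, motif = m, core_jitter = 0L,
                            homotypic_flank_fraction = 1)
  tp <- truth_aligned_pools(generate_pools(cfg_h))
  eb <- env_similarity(tp$bound, m)
  eu <- env_similarity(tp$unbound, m)
  p <- compare_position(eb, eu)
  expect_lt(p[["p_greater"]], 1e-6)
})

test_that("masking covers planted copies and is monotone in the cutoff", {
  x <- fix_pfm4()
  cons <- consensus(x)
  seq1 <- paste0("TTTT", cons, "TTTT", cons, "TTTTTTTT")  # plant at 5, core 13..16
  pool <- make_pool(seq1, core_start = 13L, core_len = 4L)
  m0 <- mask_motif_matches(pool, x, p_cutoff = 0)
  expect_false(any(m0$mask))
  m1 <- mask_motif_matches(pool, x, p_cutoff = 0.01)
  expect_true(all(m1$mask[1, 5:8]))
  expect_false(any(m1$mask[1, 13:16]))  # core never masked
  m2 <- mask_motif_matches(pool, x, p_cutoff = 0.2)
  expect_true(all(m2$mask[m1$mask]))  # looser cutoff masks a superset
  # masked cells become NA in feature matrices
  M <- position_feature_matrix(m1, "GC")
  expect_true(any(is.na(M)))
})

test_that("masking weak sites leaves a pure GC shift essentially unchanged", {
  cfg <- synthetic_config(seed = 63, n_bound = 1500, n_unbound = 1500,
                          probe_len = 40, flank_gc_bound = 0.58,
                          flank_gc_unbound = 0.50, core_jitter = 0L)
  tp <- truth_aligned_pools(generate_pools(cfg))
  st0 <- delta_profile(tp$bound, tp$unbound, "GC")
  mb <- mask_motif_matches(tp$bound, cfg$motif, p_cutoff = 0.05)
  mu <- mask_motif_matches(tp$unbound, cfg$motif, p_cutoff = 0.05)
  st1 <- delta_profile(mb, mu, "GC")
  d0 <- mean(st0$mean_bound - st0$mean_unbound)
  d1 <- mean(st1$mean_bound - st1$mean_unbound)
  expect_lt(abs(d1 - d0), 0.02)
  expect_true(all(st1$delta > 0))
})

test_that("dropping sequences with off-core matches equals a scan oracle", {
  x <- fix_pfm4()
  cons <- consensus(x)
  clean <- paste0("TTTTTTTTTTTT", cons, "TTTTTTTTTTTT")
  dirty <- paste0("TT", cons, "TTTTTT", cons, "TTTTTTTTTTTT")
  pool <- make_pool(c(clean, dirty, clean), core_start = 13L, core_len = 4L)
  kept <- drop_motif_sequences(pool, x, p_cutoff = 0.01)
  expect_identical(names(kept$seqs), c("s1", "s3"))
  expect_equal(attr(kept, "n_dropped"), 1L)
  # a pool made of consensus-repeat flanks empties entirely
  rep_pool <- make_pool(paste0(cons, cons, cons, cons, cons, cons),
                        core_start = 9L, core_len = 4L)
  expect_equal(length(drop_motif_sequences(rep_pool, x, p_cutoff = 0.01)$seqs), 0L)
})
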