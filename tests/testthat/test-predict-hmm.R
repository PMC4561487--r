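test_that("hmm_spec derives mode backgrounds and validates parameters", {
  x <- fix_pfm4()
  avg <- as.numeric(pfm_average_background(x))
  h1 <- hmm_spec(x, mode = "pfm_average")
  expect_equal(as.numeric(h1$beta), avg)
  h2 <- hmm_spec(x, mode = "pfm_inversed")
  # A<->G, T<->C mass swap exchanges the AT and GC totals
  expect_equal(as.numeric(h2$beta), avg[c(3, 4, 1, 2)])
  expect_equal(sum(as.numeric(h2$beta)[c(1, 4)]), sum(avg[c(2, 3)]))
  expect_error(hmm_spec(x, t_bg = 1), "t_bg")
  expect_error(hmm_spec(x, strand_bias = 1.2), "strand_bias")
})

test_that("sequence likelihoods equal the exhaustive-segmentation oracle", {
  x2 <- pfm(rbind(c(0.7, 0.1, 0.1, 0.1), c(0.2, 0.3, 0.4, 0.1)),
            pseudocount = 0)
  hmm <- hmm_spec(x2, beta = background(c(0.3, 0.2, 0.2, 0.3)),
                  t_bg = 0.99, strand_bias = 0.7)
  with_local_seed(201, {
    for (rep in 1:25) {
      n <- sample(1:8, 1)
      codes <- sample(1:4, n, replace = TRUE)
      seq <- paste(BASES[codes], collapse = "")
      got <- sequence_loglik(hmm, seq)
      want <- brute_force_loglik(hmm, codes)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
  # empty sequence and the background-only closed form for seq shorter
  # than L
  expect_equal(sequence_loglik(hmm, ""), 0)
  expect_equal(sequence_loglik(hmm, "G"),
               log(0.99) + log(0.2))
  expect_error(sequence_loglik(hmm, "ANA"), "N in sequence")
})

test_that("total probability over all sequences of a length stays below one", {
  x2 <- pfm(rbind(c(0.6, 0.2, 0.1, 0.1), c(0.1, 0.2, 0.3, 0.4)),
            pseudocount = 0)
  hmm <- hmm_spec(x2, beta = background(c(0.25, 0.3, 0.25, 0.2)),
                  t_bg = 0.95, strand_bias = 0.6)
  for (n in 1:6) {
    codes <- as.matrix(do.call(expand.grid, rep(list(1:4), n)))
    tot <- sum(exp(motifenv:::hmm_loglik_matrix(hmm, codes)))
    expect_lte(tot, 1 + 1e-12)
  }
})

test_that("LLR algebra: background-only parses and concatenation", {
  # L > n: only the background parse exists
  x <- fix_pfm4()
  beta <- background(c(0.3, 0.2, 0.2, 0.3))
  hmm <- hmm_spec(x, beta = beta, t_bg = 0.99)
  s <- "ACG"
  expect_equal(unname(llr(hmm, s, beta)), 3 * log(0.99))
  # hard-zero PFM: no window spanning a junction of two A-free strings can
  # emit a block, so llr is additive over the concatenation
  xz <- pfm(rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), pseudocount = 0)
  hz <- hmm_spec(xz, beta = beta, t_bg = 0.98, strand_bias = 1)
  u <- "GGCC"; v <- "CCGG"  # no A, no T: neither strand can host a block
  expect_equal(unname(llr(hz, paste0(u, v), beta)),
               unname(llr(hz, u, beta)) + unname(llr(hz, v, beta)),
               tolerance = 1e-12)
})

test_that("reverse-complement invariance holds for unbiased symmetric models", {
  x <- fix_pfm4()
  beta <- background(c(0.3, 0.2, 0.2, 0.3))  # AT/GC symmetric
  hmm <- hmm_spec(x, beta = beta, t_bg = 0.99, strand_bias = 0.5)
  for (s in random_dna(5, 25, seed = 211)) {
    expect_equal(sequence_loglik(hmm, s), sequence_loglik(hmm, revcomp(s)),
                 tolerance = 1e-12)
  }
})

test_that("inserting an exact consensus block never decreases the LLR", {
  x <- fix_pfm4()
  beta <- background()
  hmm <- hmm_spec(x, beta = beta, t_bg = 0.99, strand_bias = 0.5)
  for (s in random_dna(5, 20, seed = 212)) {
    base <- unname(llr(hmm, s, beta))
    ins <- paste0(substr(s, 1, 10), consensus(x), substr(s, 11, 20))
    expect_gte(unname(llr(hmm, ins, beta)), base - 1e-9)
  }
})

test_that("strand bias estimates recover planted orientation mixes", {
  m <- random_pfm(6, 1.8, 0.5, seed = 221)
  mk <- function(mix, seed) {
    cfg <- synthetic_config(seed = seed, n_bound = 1500, n_unbound = 50,
                            motif = m, orientation_mix = mix)
    generate_pools(cfg)$bound
  }
  # background flank hits add a little reverse-strand noise on top of the
  # all-forward plants
  expect_gt(estimate_strand_bias(mk(1, 222), m, p_cutoff = 0.001), 0.97)
  s70 <- estimate_strand_bias(mk(0.7, 223), m, p_cutoff = 0.001)
  expect_lt(abs(s70 - 0.7), 0.03)
  # palindromic consensus scores identically on both strands
  pal <- fix_palindrome()
  cfgp <- synthetic_config(seed = 224, n_bound = 500, n_unbound = 50,
                           probe_len = 20, motif = pal, orientation_mix = 0.5)
  sp <- estimate_strand_bias(generate_pools(cfgp)$bound, pal, p_cutoff = 0.01)
  expect_lt(abs(sp - 0.5), 0.05)
  # no hits at an impossible cutoff: neutral default
  expect_equal(estimate_strand_bias(c(a = "TTTTTTTT"), fix_pfm4(),
                                    p_cutoff = 1e-12), 0.5)
})

test_that("planted motifs raise LLR scores over matched motif-free probes", {
  m <- random_pfm(6, 1.8, 0.5, seed = 231)
  cfg <- synthetic_config(seed = 232, n_bound = 500, n_unbound = 500,
                          probe_len = 40, motif = m, core_jitter = 0L)
  gen <- generate_pools(cfg)
  beta <- background_from_seqs(gen$unbound)
  hmm <- hmm_spec(m, beta = beta, t_bg = 0.99, strand_bias = 1)
  planted <- llr(hmm, gen$bound, beta)
  # motif-free probes: flanks only, same composition
  free <- random_dna(500, 40, seed = 233)
  names(free) <- paste0("f", seq_along(free))
  p <- compare_position(unname(planted), unname(llr(hmm, free, beta)))
  expect_lt(p[["p_greater"]], 1e-6)
})

test_that("identical pools score an AUROC of exactly one half", {
  m <- random_pfm(6, 1.5, 0.6, seed = 241)
  cfg <- synthetic_config(seed = 242, n_bound = 80, n_unbound = 80)
  tp <- truth_aligned_pools(generate_pools(cfg))
  r <- hmm_auroc(tp$bound, tp$bound, cfg$motif, mode = "genomic")
  expect_equal(r$auroc, 0.5)
})
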