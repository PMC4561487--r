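test_that("position feature matrices count base classes per column", {
  # frame: 4 up-flank, core ACGT at 5..8, 4 down-flank; exclusion 2 leaves
  # columns 1-2 and 11-12 (relative -4,-3 and 3,4)
  seqs <- c("GAAAACGTAAGA", "GCAAACGTAAGT", "GGAAACGTAAGC", "GTAAACGTAAGG")
  pool <- make_pool(seqs, core_start = 5L, core_len = 4L)
  M <- position_feature_matrix(pool, "GC")
  expect_identical(colnames(M), c("-4", "-3", "3", "4"))
  expect_equal(unname(colMeans(M)), c(1, 0.5, 1, 0.5))
  # per-base features sum to one at each cell
  tot <- Reduce(`+`, lapply(c("A", "C", "G", "T"),
                            function(b) position_feature_matrix(pool, b)))
  expect_true(all(tot == 1))
  # independent character-counting oracle on a random pool
  cfg <- synthetic_config(seed = 21, n_bound = 40, n_unbound = 40,
                          flank_gc_bound = 0.6)
  tp <- truth_aligned_pools(generate_pools(cfg))
  M2 <- position_feature_matrix(tp$bound, "GC")
  ap <- data.frame(col = as.integer(colnames(M2)))
  chars <- do.call(rbind, strsplit(tp$bound$seqs, ""))
  core_end <- tp$bound$core_start + tp$bound$core_len - 1L
  cols <- ifelse(ap$col < 0, ap$col + tp$bound$core_start, ap$col + core_end)
  expect_equal(unname(colMeans(M2)),
               unname(colMeans(matrix(chars[, cols] %in% c("G", "C"),
                                      nrow(chars)))))
})

test_that("one-sided rank tests agree with a permutation oracle and are symmetric", {
  b <- c(rep(1, 8), rep(0, 2)); u <- c(rep(1, 2), rep(0, 8))
  p <- compare_position(b, u, test = "rank_sum")
  # exact permutation null of the rank-sum statistic over all label splits
  vals <- c(b, u); n <- 10
  combs <- utils::combn(20, n)
  r <- rank(vals)
  stat_obs <- sum(r[1:10])
  stats <- colSums(matrix(r[combs], nrow = n))
  expect_equal(p[["p_greater"]], mean(stats >= stat_obs), tolerance = 0.02)
  # swapping columns swaps the one-sided p-values
  q <- compare_position(u, b, test = "rank_sum")
  expect_equal(p[["p_greater"]], q[["p_less"]])
  expect_equal(p[["p_less"]], q[["p_greater"]])
  # identical columns carry no evidence either way
  same <- compare_position(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_true(all(same >= 0.5))
  expect_equal(unname(compare_position(rep(1, 5), rep(1, 5))), c(1, 1))
  expect_error(compare_position(numeric(0), c(1)), "empty")
})

test_that("rank-based p-values are invariant to positive scaling", {
  with_local_seed(8, {
    a <- rnorm(40); b <- rnorm(40) + 0.5
  })
  expect_equal(compare_position(a, b), compare_position(3.7 * a, 3.7 * b))
})

test_that("FDR q-values: BH step-up and Storey shrinkage", {
  expect_equal(fdr_qvalues(rep(1, 5), "BH"), rep(1, 5))
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.3, 0.6, 0.9, 0.04, 0.55, 0.7)
  bh <- fdr_qvalues(p, "BH"); st <- fdr_qvalues(p, "storey")
  expect_true(all(st <= bh + 1e-15))
  # order invariance up to reordering
  o <- c(3, 1, 4, 2, 8, 6, 5, 7)
  expect_equal(fdr_qvalues(p[o], "storey"), st[o])
  expect_identical(fdr_qvalues(numeric(0)), numeric(0))
  expect_error(fdr_qvalues(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("delta profiles recover a planted GC shift with the right sign", {
  cfg <- synthetic_config(seed = 31, n_bound = 2000, n_unbound = 2000,
                          flank_gc_bound = 0.60, flank_gc_unbound = 0.50)
  tp <- truth_aligned_pools(generate_pools(cfg))
  st <- delta_profile(tp$bound, tp$unbound, "GC")
  expect_true(all(st$delta > 0))
  expect_true(all(st$mean_bound > st$mean_unbound))
  # exchanging pool labels negates every delta
  sw <- delta_profile(tp$unbound, tp$bound, "GC")
  expect_equal(sw$delta, -st$delta, tolerance = 1e-9)
  expect_error(delta_profile(tp$bound, make_pool("AAAAACGTAAAAA", 5, 4)),
               "frame")
})

test_that("preference calls honor the five-position rule", {
  mk <- function(n_sig_gc, n_sig_at, n = 12) {
    q <- rep(0.5, n); ql <- rep(0.5, n)
    mb <- rep(0.5, n); mu <- rep(0.5, n)
    if (n_sig_gc > 0) { q[1:n_sig_gc] <- 0.01; mb[1:n_sig_gc] <- 0.6 }
    if (n_sig_at > 0) { ql[(n - n_sig_at + 1):n] <- 0.01
                        mu[(n - n_sig_at + 1):n] <- 0.6 }
    structure(data.frame(position = 1:n, mean_bound = mb, mean_unbound = mu,
                         p_greater = q, p_less = ql, q_greater = q,
                         q_less = ql,
                         delta = ifelse(mb > mu, -log10(q),
                                        ifelse(mb < mu, log10(ql), 0))),
              class = c("position_stats", "data.frame"))
  }
  expect_identical(call_preference(mk(4, 0))$call, "none")
  expect_identical(call_preference(mk(5, 0))$call, "high-GC")
  expect_identical(call_preference(mk(0, 6))$call, "high-AT")
  # planted AT preference through the full pipeline path
  cfg <- synthetic_config(seed = 33, n_bound = 2500, n_unbound = 2500,
                          flank_gc_bound = 0.44, flank_gc_unbound = 0.50)
  tp <- truth_aligned_pools(generate_pools(cfg))
  pref <- call_preference(delta_profile(tp$bound, tp$unbound, "GC"))
  expect_identical(pref$call, "high-AT")
  expect_lt(pref$mean_delta_gc, 0)
})
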