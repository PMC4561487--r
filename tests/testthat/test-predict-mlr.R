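test_that("AUROC is the Mann-Whitney probability with ties at one half", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1)
  # 2 of 4 ordered pairs correct by hand count
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 0, 1)), 0.5)
  expect_equal(auroc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
  # invariance under strictly monotone transforms
  with_local_seed(101, {
    s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  })
  l[1] <- 1; l[2] <- 0
  expect_equal(auroc(exp(s), l), auroc(s, l))
  expect_equal(auroc(10 + 3 * s, l), auroc(s, l))
})

test_that("feature extraction matches closed forms and a scan oracle", {
  x <- fix_pfm4()
  tab <- synthetic_shape_table(seed = 1)
  # all-AT flanks: gc exactly 0
  at <- make_pool(paste0(strrep("AT", 6), consensus(x), strrep("TA", 6)),
                  core_start = 13L, core_len = 4L)
  f <- extract_features(at, x, shape_table = tab)
  expect_equal(f$gc, 0)
  # uniform PFM: env and clusters identically 0
  u <- pfm(matrix(0.25, 4, 4), pseudocount = 0)
  pool <- make_pool(random_dna(8, 30, seed = 102), core_start = 14L,
                    core_len = 4L)
  fu <- extract_features(pool, u, shape_table = tab)
  expect_true(all(fu$env == 0))
  expect_true(all(fu$clusters == 0))
  # planted consensus copies: cluster sum equals the sum of qualifying
  # window scores from the hit-level oracle
  cons <- consensus(x)
  seq1 <- paste0("TT", cons, "TTTTTT", cons, "TT", cons, "TTTTTT")
  pl <- make_pool(seq1, core_start = 13L, core_len = 4L)
  pv <- exact_pvalues(x, background())
  h <- homotypy_scores(pl, x, bins = c(0.01, 0.05, 0.1), pv = pv)
  starts <- motifenv:::offcore_window_starts(pl, 4L)
  o_sum <- 0
  for (o in starts) for (st in c("+", "-")) {
    w <- substr(seq1, o, o + 3L)
    k <- if (st == "+") w else revcomp(w)
    codes <- match(strsplit(k, "")[[1]], BASES)
    if (motifenv:::kmer_grid_pvalue(pv, codes) <= 0.01)
      o_sum <- o_sum + log_odds(x, k)
  }
  expect_gt(o_sum, 0)
  expect_equal(h$env_sum_significant, o_sum, tolerance = 1e-9)
})

test_that("motif-strength matching equalizes score distributions", {
  mkpool <- function(n, mean_score, seed, label) {
    cfg <- synthetic_config(seed = seed, n_bound = n, n_unbound = n)
    tp <- truth_aligned_pools(generate_pools(cfg))
    p <- tp[[if (label == "bound") "bound" else "unbound"]]
    p$meta$score <- with_local_seed(seed + 1, rnorm(n, mean_score, 1))
    p
  }
  pb <- mkpool(800, 12, 111, "bound")
  pu <- mkpool(800, 9, 112, "unbound")
  # a 3-sigma score separation needs fine bins for residual within-bin
  # skew to vanish
  m <- match_motif_strength(pb, pu, n_bins = 25, seed = 3)
  expect_equal(length(m[[1]]$seqs), length(m[[2]]$seqs))
  expect_lt(abs(mean(m[[1]]$meta$score) - mean(m[[2]]$meta$score)), 0.1)
  expect_gt(attr(m, "match_p"), 0.2)
  # identical distributions: only size equalization
  pb2 <- mkpool(300, 10, 113, "bound"); pu2 <- mkpool(300, 10, 113, "unbound")
  pu2$meta$score <- pb2$meta$score
  m2 <- match_motif_strength(pb2, pu2, n_bins = 10, seed = 3)
  expect_equal(length(m2[[1]]$seqs), length(m2[[2]]$seqs))
  # n_bins = 1 degenerates to plain size matching
  m3 <- match_motif_strength(pb, pu, n_bins = 1, seed = 3)
  expect_equal(length(m3[[1]]$seqs), min(length(pb$seqs), length(pu$seqs)))
})

test_that("ridge_cv separates separable data and stays at chance when shuffled", {
  with_local_seed(121, {
    n <- 400
    f <- data.frame(gc = c(rnorm(n / 2, 2), rnorm(n / 2, -2)) * 0.25)
    lab <- rep(c(1, 0), each = n / 2)
  })
  r <- ridge_cv(f, lab, "gc", seed = 1)
  expect_gt(r$auroc_mean, 0.99)
  expect_length(r$auroc_per_fold, 10L)
  # shuffled labels sit inside the 0.5 +/- 3/sqrt(n) band across seeds
  devs <- vapply(1:8, function(s) {
    ls <- with_local_seed(300 + s, sample(lab))
    ridge_cv(f, ls, "gc", seed = s)$auroc_mean - 0.5
  }, 0)
  expect_true(all(abs(devs) < 3 / sqrt(400)))
})

test_that("regularization limits drive AUROC as expected", {
  with_local_seed(131, {
    n <- 200
    f <- data.frame(a = c(rnorm(n / 2, 1.5), rnorm(n / 2, -1.5)))
    lab <- rep(c(1, 0), each = n / 2)
  })
  # lambda -> 0 on separable one-feature data reaches near-perfect AUROC
  r0 <- ridge_cv(f, lab, "a", lambda_grid = 1e-8, seed = 2)
  expect_gt(r0$auroc_mean, 0.98)
  # a one-feature linear score is invariant to shrinkage magnitude, so a
  # huge lambda changes nothing for ranking; a constant column does
  f$const <- 1
  expect_warning(rc <- ridge_cv(f, lab, c("a", "const"), seed = 2),
                 "constant")
  expect_gt(rc$auroc_mean, 0.98)
})

test_that("a pure-noise feature costs almost nothing next to a real one", {
  with_local_seed(141, {
    n <- 4000
    f <- data.frame(real = rnorm(n) + rep(c(0.5, 0), each = n / 2),
                    noise = rnorm(n))
    lab <- rep(c(1, 0), each = n / 2)
  })
  r1 <- ridge_cv(f, lab, "real", folds = 10, seed = 4)
  r2 <- ridge_cv(f, lab, c("real", "noise"), folds = 10, seed = 4)
  expect_gt(r2$auroc_mean, r1$auroc_mean - 0.02)
})

test_that("the closed-form ridge solve minimizes the penalized objective", {
  with_local_seed(151, {
    X <- matrix(rnorm(200 * 3), 200, 3)
    X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
    y <- rbinom(200, 1, plogis(X %*% c(1, -0.5, 0.2)))
  })
  lam <- 2.5
  fit <- motifenv:::ridge_fit(X, y, lam)
  # independent numeric minimizer of ||y - b0 - X b||^2 + lam ||b||^2
  obj <- function(par) sum((y - par[1] - X %*% par[-1])^2) + lam * sum(par[-1]^2)
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$beta), opt$par[-1], tolerance = 1e-5)
  expect_equal(obj(c(fit$b0, fit$beta)), opt$value, tolerance = 1e-9)
})

test_that("shuffled-label cutoffs are reproducible and concentrate with n", {
  with_local_seed(161, {
    f_small <- data.frame(a = rnorm(200)); l_small <- rep(c(1, 0), each = 100)
    f_big <- data.frame(a = rnorm(2000)); l_big <- rep(c(1, 0), each = 1000)
  })
  s1 <- shuffled_null(f_small, l_small, "a", n_shuffles = 3, seed = 5)
  s2 <- shuffled_null(f_small, l_small, "a", n_shuffles = 3, seed = 5)
  expect_identical(s1, s2)
  s3 <- shuffled_null(f_big, l_big, "a", n_shuffles = 3, seed = 5)
  expect_lt(abs(s3$null_cutoff - 0.5), abs(s1$null_cutoff - 0.5) + 0.02)
})

test_that("transfer prediction carries effects across domains", {
  mk <- function(n, flip, seed) {
    with_local_seed(seed, {
      eff <- if (flip) -0.8 else 0.8
      data.frame(gc = rnorm(n) + rep(c(eff, 0), each = n / 2),
                 prot = rnorm(n))
    })
  }
  tr <- mk(600, FALSE, 171); lab_tr <- rep(c(1, 0), each = 300)
  te <- mk(600, FALSE, 172); lab_te <- rep(c(1, 0), each = 300)
  r <- transfer_predict(tr, lab_tr, te, lab_te, c("gc", "prot"), seed = 6)
  expect_gt(r$auroc, 0.6)
  # train == test equals resubstitution
  rr <- transfer_predict(tr, lab_tr, tr, lab_tr, c("gc", "prot"), seed = 6)
  fit <- rr$fit
  expect_equal(rr$auroc,
               auroc(motifenv:::ridge_predict(fit, as.matrix(tr)), lab_tr))
  # flipping the effect direction in the test domain anti-learns
  te_flip <- mk(600, TRUE, 173)
  r2 <- transfer_predict(tr, lab_tr, te_flip, lab_te, c("gc", "prot"), seed = 6)
  expect_lt(r2$auroc, 0.5)
})
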