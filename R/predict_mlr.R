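#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Environment feature vectors of an aligned pool
#'
#' Computes the four environment features the regression models use, every
#' one over the flanks only (core motif and `core_exclusion` bp each side
#' excluded): mean GC fraction, mean propeller twist (degrees), homotypic
#' environment score (mean off-core window log-odds, bits) and homotypic
#' cluster sum (sum of off-core window scores with p <= 0.001, bits). The
#' core-motif log-odds score is carried along for motif-strength matching
#' but is never a model feature.
#'
#' @param pool an `aligned_pool`.
#' @param x a `pfm`.
#' @param bg a `dna_background`.
#' @param shape_table a `shape_table`.
#' @param pv optional precomputed [exact_pvalues()] table.
#' @return data.frame: `seq_id`, `gc`, `prot`, `env`, `clusters`,
#'   `motif_score`.
#' @export
extract_features <- function(pool, x, bg = background(), shape_table,
                             pv = NULL) {
  gc <- rowMeans(position_feature_matrix(pool, "GC"), na.rm = TRUE)
  prot <- rowMeans(shape_feature_matrix(pool, shape_table), na.rm = TRUE)
  h <- homotypy_scores(pool, x, bg, pv = pv)
  codes <- seqs_to_code_matrix(pool$seqs)
  core <- codes[, core_columns(pool), drop = FALSE]
  lod <- log_odds_matrix(x, bg)
  ms <- rowSums(matrix(lod[cbind(rep(seq_len(x$L), each = nrow(core)),
                                 as.vector(core))],
                       nrow(core), x$L))
  data.frame(seq_id = names(pool$seqs), gc = unname(gc), prot = unname(prot),
             env = h$env_score, clusters = h$env_sum_significant,
             motif_score = ms, stringsAsFactors = FALSE)
}

#' Match motif-strength distributions between pools
#'
#' Bins the pooled core-motif scores into `n_bins` quantile bins and
#' subsamples each pool within every bin to the common minimum count, so the
#' surviving pools carry the same motif-strength distribution and the
#' environment models cannot exploit core-motif strength.
#'
#' @param pool_b,pool_u `aligned_pool`s whose `meta` carries a `score`
#'   column (as produced by [align_best_hit()]); if absent, scores are
#'   computed from the core block.
#' @param x,bg,shape_table used only when scores must be recomputed
#'   (`x`, `bg`).
#' @param n_bins number of quantile bins (default 10).
#' @param seed subsampling seed.
#' @return list of the two matched pools; the number of bins dropped
#'   because one pool was empty there is attached as attribute
#'   `n_bins_dropped`, and the rank-sum p-value comparing the matched score
#'   distributions as attribute `match_p`.
#' @export
match_motif_strength <- function(pool_b, pool_u, x = NULL, bg = background(),
                                 n_bins = 10L, seed = 1L) {
  get_scores <- function(pool) {
    if (!is.null(pool$meta$score)) return(pool$meta$score)
    if (is.null(x)) stop("no scores in pool meta and no PFM supplied")
    codes <- seqs_to_code_matrix(pool$seqs)
    core <- codes[, core_columns(pool), drop = FALSE]
    lod <- log_odds_matrix(x, bg)
    rowSums(matrix(lod[cbind(rep(seq_len(x$L), each = nrow(core)),
                             as.vector(core))], nrow(core), x$L))
  }
  sb <- get_scores(pool_b); su <- get_scores(pool_u)
  edges <- unique(quantile(c(sb, su), probs = seq(0, 1, length.out = n_bins + 1L)))
  bin_b <- cut(sb, edges, include.lowest = TRUE, labels = FALSE)
  bin_u <- cut(su, edges, include.lowest = TRUE, labels = FALSE)
  keep_b <- integer(0); keep_u <- integer(0); dropped <- 0L
  for (b in seq_len(length(edges) - 1L)) {
    ib <- which(bin_b == b); iu <- which(bin_u == b)
    if (length(ib) == 0L || length(iu) == 0L) {
      if (length(ib) + length(iu) > 0L) dropped <- dropped + 1L
      next
    }
    m <- min(length(ib), length(iu))
    keep_b <- c(keep_b, if (length(ib) > m) ib[sample_with_seed(length(ib), m, seed + 2L * b)] else ib)
    keep_u <- c(keep_u, if (length(iu) > m) iu[sample_with_seed(length(iu), m, seed + 2L * b + 1L)] else iu)
  }
  take <- function(pool, idx) {
    idx <- sort(idx)
    pool$seqs <- pool$seqs[idx]
    pool$meta <- pool$meta[idx, , drop = FALSE]
    if (!is.null(pool$mask)) pool$mask <- pool$mask[idx, , drop = FALSE]
    pool
  }
  out <- list(take(pool_b, keep_b), take(pool_u, keep_u))
  attr(out, "n_bins_dropped") <- dropped
  attr(out, "match_p") <- suppressWarnings(
    wilcox.test(sb[keep_b], su[keep_u])$p.value)
  out
}

# closed-form ridge fit on a standardized design: minimizes
# ||y - b0 - X beta||^2 + lambda ||beta||^2 with the intercept unpenalized.
# Returns list(beta, b0, center, scale); constant columns get coefficient 0.
ridge_fit <- function(X, y, lambda) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  const <- scl == 0 | is.na(scl)
  scl[const] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  Xs[, const] <- 0
  yc <- y - mean(y)
  p <- ncol(X)
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
  beta[const] <- 0
  list(beta = drop(beta), b0 = mean(y), center = ctr, scale = scl,
       constant = const)
}

ridge_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, `/`)
  Xs[, fit$constant] <- 0
  drop(Xs %*% fit$beta) + fit$b0
}

default_lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

#' Nested cross-validated ridge regression scored by AUROC
#'
#' Outer stratified k-fold cross-validation of an L2-regularized linear
#' (least-squares) model on 0/1 labels. Within each outer training set the
#' penalty lambda is chosen by an embedded stratified k-fold CV maximizing
#' the mean inner AUROC; features are standardized on each training portion
#' and the transform applied to its held-out part. Constant feature columns
#' get coefficient 0 with a warning.
#'
#' @param features data.frame or matrix of feature columns.
#' @param labels 0/1 (or logical) labels.
#' @param feature_subset character vector of feature column names to use.
#' @param folds,inner_folds outer and inner fold counts (default 10).
#' @param lambda_grid penalty grid (default 13 points log-spaced 1e-3..1e3).
#' @param seed controls fold assignment; results are fully deterministic
#'   given (seed, fold counts, lambda_grid).
#' @return list of class `cv_result`: `model_name`, `features`,
#'   `auroc_per_fold`, `auroc_mean`, `auroc_se` (s.d. of fold AUROCs /
#'   sqrt(folds)), `lambda_chosen_per_fold`, `oof_scores` (out-of-fold
#'   predictions in input order).
#' @export
ridge_cv <- function(features, labels, feature_subset = colnames(features),
                     folds = 10L, inner_folds = 10L,
                     lambda_grid = default_lambda_grid(), seed = 1L) {
  X <- as.matrix(as.data.frame(features)[, feature_subset, drop = FALSE])
  y <- as.numeric(as.logical(labels))
  if (min(table(y)) < 2L * folds)
    stop("need at least ", 2L * folds, " samples per class for ", folds, "-fold CV")
  if (any(apply(X, 2L, sd) == 0))
    warning("constant feature column(s): ",
            paste(feature_subset[apply(X, 2L, sd) == 0], collapse = ", "),
            " (coefficient fixed at 0)")
  fold <- make_stratified_folds(y, folds, seed)
  auc_fold <- numeric(folds); lam_fold <- numeric(folds)
  oof <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    ifold <- make_stratified_folds(ytr, inner_folds, seed + 1000L + f)
    inner_auc <- vapply(lambda_grid, function(lam) {
      aucs <- vapply(seq_len(inner_folds), function(g) {
        itr <- ifold != g
        fit <- ridge_fit(Xtr[itr, , drop = FALSE], ytr[itr], lam)
        pr <- ridge_predict(fit, Xtr[!itr, , drop = FALSE])
        if (length(unique(ytr[!itr])) < 2L) return(NA_real_)
        auroc(pr, ytr[!itr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    lam <- lambda_grid[which.max(inner_auc)]
    fit <- ridge_fit(Xtr, ytr, lam)
    pr <- ridge_predict(fit, X[te, , drop = FALSE])
    oof[te] <- pr
    auc_fold[f] <- auroc(pr, y[te])
    lam_fold[f] <- lam
  }
  structure(list(model_name = paste(feature_subset, collapse = "+"),
                 features = feature_subset,
                 auroc_per_fold = auc_fold,
                 auroc_mean = mean(auc_fold),
                 auroc_se = sd(auc_fold) / sqrt(folds),
                 lambda_chosen_per_fold = lam_fold,
                 oof_scores = oof),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("ridge CV [%s]: AUROC %.3f (se %.3f), lambda %s\n",
              x$model_name, x$auroc_mean, x$auroc_se,
              paste(signif(unique(x$lambda_chosen_per_fold), 2), collapse = ",")))
  invisible(x)
}

#' Empirical AUROC significance cutoff from shuffled labels
#'
#' Reruns the full nested-CV ridge model on label permutations and returns
#' the maximum AUROC observed, the empirical bar a real model must clear.
#'
#' @inheritParams ridge_cv
#' @param n_shuffles number of label permutations (default 10).
#' @return list: `null_cutoff` (max shuffled AUROC), `null_aurocs`.
#' @export
shuffled_null <- function(features, labels, feature_subset = colnames(features),
                          n_shuffles = 10L, folds = 10L, inner_folds = 10L,
                          lambda_grid = default_lambda_grid(), seed = 1L) {
  y <- as.numeric(as.logical(labels))
  aucs <- vapply(seq_len(n_shuffles), function(s) {
    ys <- with_seed(seed + 7919L * s, sample(y))
    ridge_cv(features, ys, feature_subset, folds = folds,
             inner_folds = inner_folds, lambda_grid = lambda_grid,
             seed = seed + s)$auroc_mean
  }, numeric(1))
  list(null_cutoff = max(aucs), null_aurocs = aucs)
}

#' Train on one domain, test on another
#'
#' Chooses lambda by stratified CV on the training data (maximizing CV
#' AUROC), standardizes on the training data only, fits the ridge model and
#' scores the untouched test set.
#'
#' @param train_features,train_labels training domain data.
#' @param test_features,test_labels test domain data (same feature columns).
#' @inheritParams ridge_cv
#' @return list: `auroc` on the test set, `lambda`, `fit`.
#' @export
transfer_predict <- function(train_features, train_labels,
                             test_features, test_labels,
                             feature_subset = colnames(train_features),
                             folds = 10L, lambda_grid = default_lambda_grid(),
                             seed = 1L) {
  Xtr <- as.matrix(as.data.frame(train_features)[, feature_subset, drop = FALSE])
  Xte <- as.matrix(as.data.frame(test_features)[, feature_subset, drop = FALSE])
  ytr <- as.numeric(as.logical(train_labels))
  yte <- as.numeric(as.logical(test_labels))
  fold <- make_stratified_folds(ytr, folds, seed)
  cv_auc <- vapply(lambda_grid, function(lam) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- ridge_fit(Xtr[tr, , drop = FALSE], ytr[tr], lam)
      if (length(unique(ytr[!tr])) < 2L) return(NA_real_)
      auroc(ridge_predict(fit, Xtr[!tr, , drop = FALSE]), ytr[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  lam <- lambda_grid[which.max(cv_auc)]
  fit <- ridge_fit(Xtr, ytr, lam)
  list(auroc = auroc(ridge_predict(fit, Xte), yte), lambda = lam, fit = fit)
}
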