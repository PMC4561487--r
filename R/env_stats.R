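#' Per-position feature matrix of an aligned pool
#'
#' For nucleotide features each cell is a 0/1 indicator of the base class at
#' that aligned position; only flank positions outside the core block and the
#' core-exclusion zone are returned. Cells masked by
#' [mask_motif_matches()] come out `NA`.
#'
#' @param pool an `aligned_pool`.
#' @param feature one of `"GC"`, `"A"`, `"C"`, `"G"`, `"T"`.
#' @return numeric matrix sequences x positions; column names are relative
#'   positions (negative upstream of the core start, positive downstream of
#'   the core end).
#' @export
position_feature_matrix <- function(pool, feature = c("GC", "A", "C", "G", "T")) {
  feature <- match.arg(feature)
  ap <- analysis_positions(pool)
  if (nrow(ap) == 0L) stop("pool has no analysis positions outside the core/exclusion zone")
  codes <- seqs_to_code_matrix(pool$seqs)[, ap$column, drop = FALSE]
  target <- switch(feature, GC = c(2L, 3L), A = 1L, C = 2L, G = 3L, T = 4L)
  M <- matrix(as.numeric(codes %in% target), nrow(codes), ncol(codes))
  M[is.na(codes)] <- NA_real_
  if (!is.null(pool$mask)) {
    M[pool$mask[, ap$column, drop = FALSE]] <- NA_real_
  }
  colnames(M) <- ap$position
  rownames(M) <- names(pool$seqs)
  M
}

#' One-sided rank tests for a single aligned position
#'
#' Compares a bound against an unbound column of feature values with the
#' Wilcoxon rank-sum (unpaired, the default) or signed-rank (index-paired)
#' test and returns both one-sided p-values. The exact distribution is used
#' for n <= 25 tie-free data; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param bound_col,unbound_col numeric vectors (`NA`s dropped; signed-rank
#'   drops pairs with an `NA` member).
#' @param test `"rank_sum"` or `"signed_rank"`.
#' @return named numeric vector `c(p_greater, p_less)` for the hypotheses
#'   bound > unbound and bound < unbound.
#' @export
compare_position <- function(bound_col, unbound_col,
                             test = c("rank_sum", "signed_rank")) {
  test <- match.arg(test)
  if (test == "signed_rank") {
    if (length(bound_col) != length(unbound_col))
      stop("signed_rank requires equal-length, index-paired columns")
    ok <- !is.na(bound_col) & !is.na(unbound_col)
    bound_col <- bound_col[ok]; unbound_col <- unbound_col[ok]
  } else {
    bound_col <- bound_col[!is.na(bound_col)]
    unbound_col <- unbound_col[!is.na(unbound_col)]
  }
  if (length(bound_col) == 0L || length(unbound_col) == 0L)
    stop("empty column in compare_position")
  vals <- c(bound_col, unbound_col)
  if (test == "signed_rank" && all(bound_col == unbound_col))
    return(c(p_greater = 1, p_less = 1))
  if (length(unique(vals)) == 1L)
    return(c(p_greater = 1, p_less = 1))
  n <- max(length(bound_col), length(unbound_col))
  exact <- n <= 25 && !anyDuplicated(vals)
  run <- function(alt) {
    if (test == "rank_sum")
      suppressWarnings(wilcox.test(bound_col, unbound_col, alternative = alt,
                                   exact = exact, correct = TRUE))$p.value
    else
      suppressWarnings(wilcox.test(bound_col, unbound_col, alternative = alt,
                                   paired = TRUE, exact = exact, correct = TRUE))$p.value
  }
  c(p_greater = run("greater"), p_less = run("less"))
}

#' FDR q-values
#'
#' Benjamini-Hochberg step-up adjustment, or Storey q-values with pi0
#' estimated at lambda = 0.5 and add-one smoothing,
#' `pi0 = min(1, (1 + #\{p > 0.5\}) / (0.5 m))`, `q = pi0 * BH` clipped to
#' (0, 1]. The smoothing keeps pi0 away from 0 for the short profiles this
#' package tests (a handful of flank positions), where the raw
#' `mean(p > 0.5) / 0.5` estimate degenerates.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param method `"storey"` (default) or `"BH"`.
#' @return q-values, same length and order as the input.
#' @export
fdr_qvalues <- function(pvalues, method = c("storey", "BH")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must be in (0, 1]")
  bh <- p.adjust(pvalues, method = "BH")
  if (method == "BH") return(bh)
  pi0 <- min(1, (1 + sum(pvalues > 0.5)) / (0.5 * length(pvalues)))
  pmin(pmax(pi0 * bh, .Machine$double.xmin), 1)
}

# core of the positional comparison, shared by nucleotide-content, shape and
# environment-similarity profiles. Mb, Mu: sequences x positions matrices
# with identical column sets (columns named by relative position).
delta_profile_matrices <- function(Mb, Mu, feature,
                                   test = c("rank_sum", "signed_rank"),
                                   fdr_method = c("storey", "BH")) {
  test <- match.arg(test)
  fdr_method <- match.arg(fdr_method)
  if (!identical(colnames(Mb), colnames(Mu)))
    stop("bound and unbound pools are not frame-compatible")
  # positions undefined in either pool (frame ends for pentamer features,
  # fully masked columns) are excluded rather than imputed
  keep <- colSums(!is.na(Mb)) > 0L & colSums(!is.na(Mu)) > 0L
  Mb <- Mb[, keep, drop = FALSE]; Mu <- Mu[, keep, drop = FALSE]
  np <- ncol(Mb)
  pg <- pl <- mb <- mu <- numeric(np)
  for (j in seq_len(np)) {
    p <- compare_position(Mb[, j], Mu[, j], test = test)
    pg[j] <- p[["p_greater"]]; pl[j] <- p[["p_less"]]
    mb[j] <- mean(Mb[, j], na.rm = TRUE); mu[j] <- mean(Mu[, j], na.rm = TRUE)
  }
  # each one-sided family corrected separately, within this profile
  qg <- fdr_qvalues(pg, fdr_method)
  ql <- fdr_qvalues(pl, fdr_method)
  delta <- ifelse(mb > mu, -log10(qg), ifelse(mb < mu, log10(ql), 0))
  res <- data.frame(position = as.integer(colnames(Mb)),
                    mean_bound = mb, mean_unbound = mu,
                    p_greater = pg, p_less = pl,
                    q_greater = qg, q_less = ql,
                    delta = delta)
  attr(res, "feature") <- feature
  class(res) <- c("position_stats", "data.frame")
  res
}

#' Positional bound-vs-unbound significance profile
#'
#' For each flank position, compares the feature between the two pools with a
#' one-sided rank test in both directions, corrects each one-sided family for
#' multiple testing across positions, and reports the signed significance
#' `delta`: `-log10(q_greater)` where the bound mean is higher, `log10(q_less)`
#' (negative) where the unbound mean is higher.
#'
#' @param pool_b,pool_u bound and unbound `aligned_pool`s (size-matched,
#'   same frame).
#' @param feature nucleotide feature, see [position_feature_matrix()].
#' @param test,fdr_method see [compare_position()], [fdr_qvalues()].
#' @return `position_stats` data.frame, one row per analysis position.
#' @export
delta_profile <- function(pool_b, pool_u, feature = "GC",
                          test = c("rank_sum", "signed_rank"),
                          fdr_method = c("storey", "BH")) {
  Mb <- position_feature_matrix(pool_b, feature)
  Mu <- position_feature_matrix(pool_u, feature)
  delta_profile_matrices(Mb, Mu, feature, test = test, fdr_method = fdr_method)
}

#' Call an environment preference from a GC profile
#'
#' A TF is called high-GC (high-AT) when at least `min_positions` positions
#' are significant at `q_threshold` with the bound (unbound) mean higher.
#'
#' @param stats a `position_stats` from [delta_profile()] on the GC feature.
#' @param min_positions minimum significant positions for a call (default 5).
#' @param q_threshold q-value threshold (default 0.05).
#' @param tf TF identifier carried into the result.
#' @return one-row data.frame: `tf`, `call` (high-GC / high-AT / none),
#'   `n_significant_positions`, `mean_delta_gc` (percentage points,
#'   bound - unbound).
#' @export
call_preference <- function(stats, min_positions = 5L, q_threshold = 0.05,
                            tf = "TF") {
  n_gc <- sum(stats$q_greater <= q_threshold & stats$mean_bound > stats$mean_unbound)
  n_at <- sum(stats$q_less <= q_threshold & stats$mean_bound < stats$mean_unbound)
  call <- "none"; n_sig <- max(n_gc, n_at)
  if (n_gc >= min_positions && n_gc >= n_at) call <- "high-GC"
  else if (n_at >= min_positions) call <- "high-AT"
  data.frame(tf = tf, call = call,
             n_significant_positions = n_sig,
             mean_delta_gc = 100 * mean(stats$mean_bound - stats$mean_unbound),
             stringsAsFactors = FALSE)
}

#' Write a position_stats profile as TSV
#' @param stats a `position_stats`.
#' @param path output path.
#' @export
write_profile_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
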