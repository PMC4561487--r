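# window starts whose L-wide window fits in the aligned frame and shares no
# position with the core block
offcore_window_starts <- function(pool, L) {
  frame_len <- nchar(pool$seqs[[1]])
  core_end <- pool$core_start + pool$core_len - 1L
  starts <- seq_len(max(frame_len - L + 1L, 0L))
  starts[(starts + L - 1L) < pool$core_start | starts > core_end]
}

#' Homotypic scores of every sequence in an aligned pool
#'
#' Slides the PFM over every off-core window of the aligned frame (windows
#' sharing any position with the core block are excluded) and reports, per
#' sequence: hit counts in the three p-value bins (<= 0.001, 0.001-0.05,
#' 0.05-0.1, both strands counted), the homotypic-environment score (mean
#' over off-core windows of the better-strand log-odds, no threshold), and
#' the homotypic-cluster sum (sum of per-strand window scores with
#' p <= 0.001).
#'
#' @param pool an `aligned_pool`.
#' @param x a `pfm`.
#' @param bg a `dna_background`.
#' @param bins upper edges of the three p-value bins.
#' @param strands `"both"` (default) or `"forward"`.
#' @param pv optional precomputed [exact_pvalues()] table.
#' @return data.frame: `seq_id`, `n_p001`, `n_p001_05`, `n_p05_10`,
#'   `env_score`, `env_sum_significant`, plus an `n_windows` attribute.
#' @export
homotypy_scores <- function(pool, x, bg = background(),
                            bins = c(0.001, 0.05, 0.1),
                            strands = c("both", "forward"), pv = NULL) {
  strands <- match.arg(strands)
  if (is.null(pv)) pv <- exact_pvalues(x, bg)
  starts <- offcore_window_starts(pool, x$L)
  if (length(starts) == 0L)
    stop("flanks too short: no off-core window of width ", x$L)
  codes <- seqs_to_code_matrix(pool$seqs)
  Sf <- window_score_matrix(codes, log_odds_matrix(x, bg))[, starts, drop = FALSE]
  Pf <- grid_window_pvalues(pv, codes, "+")[, starts, drop = FALSE]
  if (strands == "both") {
    Sr <- window_score_matrix(codes, rc_log_odds_matrix(x, bg))[, starts, drop = FALSE]
    Pr <- grid_window_pvalues(pv, codes, "-")[, starts, drop = FALSE]
    Senv <- pmax(Sf, Sr)
  } else {
    Sr <- NULL; Pr <- NULL
    Senv <- Sf
  }
  bin_count <- function(P, lo, hi) {
    # lo exclusive, hi inclusive; lo = 0 means p <= hi
    rowSums(P > lo & P <= hi, na.rm = TRUE)
  }
  n1 <- bin_count(Pf, 0, bins[1]); n2 <- bin_count(Pf, bins[1], bins[2])
  n3 <- bin_count(Pf, bins[2], bins[3])
  sig_sum <- rowSums(Sf * (Pf <= bins[1]), na.rm = TRUE)
  if (strands == "both") {
    n1 <- n1 + bin_count(Pr, 0, bins[1]); n2 <- n2 + bin_count(Pr, bins[1], bins[2])
    n3 <- n3 + bin_count(Pr, bins[2], bins[3])
    sig_sum <- sig_sum + rowSums(Sr * (Pr <= bins[1]), na.rm = TRUE)
  }
  res <- data.frame(seq_id = names(pool$seqs),
                    n_p001 = n1, n_p001_05 = n2, n_p05_10 = n3,
                    env_score = rowMeans(Senv, na.rm = TRUE),
                    env_sum_significant = sig_sum,
                    stringsAsFactors = FALSE)
  attr(res, "n_windows") <- length(starts) * (if (strands == "both") 2L else 1L)
  res
}

#' Off-core motif-hit counts per p-value bin, with a pool comparison
#'
#' @inheritParams homotypy_scores
#' @param pool_u optional unbound pool; when given, per-bin counts are
#'   compared between pools with a rank test and the comparison table is
#'   attached as the `comparison` attribute (columns: bin, mean_bound,
#'   mean_unbound, p_greater, p_less).
#' @return per-sequence count data.frame (see [homotypy_scores()]).
#' @export
count_clusters <- function(pool, x, bg = background(), bins = c(0.001, 0.05, 0.1),
                           pool_u = NULL, strands = "both", pv = NULL) {
  hb <- homotypy_scores(pool, x, bg, bins = bins, strands = strands, pv = pv)
  if (!is.null(pool_u)) {
    hu <- homotypy_scores(pool_u, x, bg, bins = bins, strands = strands, pv = pv)
    cols <- c("n_p001", "n_p001_05", "n_p05_10")
    cmp <- do.call(rbind, lapply(cols, function(cl) {
      p <- compare_position(hb[[cl]], hu[[cl]], test = "rank_sum")
      data.frame(bin = cl, mean_bound = mean(hb[[cl]]),
                 mean_unbound = mean(hu[[cl]]),
                 p_greater = p[["p_greater"]], p_less = p[["p_less"]],
                 stringsAsFactors = FALSE)
    }))
    attr(hb, "comparison") <- cmp
  }
  hb
}

#' Homotypic-environment similarity score per sequence
#'
#' Mean over all off-core windows of the window's log-odds similarity to the
#' PFM (better strand when `strands = "both"`), with no significance
#' threshold.
#'
#' @inheritParams homotypy_scores
#' @return named numeric vector of environment scores.
#' @export
env_similarity <- function(pool, x, bg = background(),
                           strands = c("both", "forward"), pv = NULL) {
  h <- homotypy_scores(pool, x, bg, strands = match.arg(strands), pv = pv)
  setNames(h$env_score, h$seq_id)
}

#' Mask positions covered by significant off-core motif matches
#'
#' Flags every aligned position covered by an off-core hit with
#' p <= `p_cutoff` (both strands) as excluded; downstream positional
#' statistics treat masked cells as missing. Used as a control that
#' nucleotide-content differences are not driven by discrete weak sites.
#'
#' @inheritParams homotypy_scores
#' @param p_cutoff hit p-value cutoff defining a significant match.
#' @return the pool with an updated `mask` (logical sequences x frame
#'   matrix).
#' @export
mask_motif_matches <- function(pool, x, bg = background(), p_cutoff = 0.001,
                               pv = NULL) {
  if (is.null(pv)) pv <- exact_pvalues(x, bg)
  starts <- offcore_window_starts(pool, x$L)
  frame_len <- nchar(pool$seqs[[1]])
  mask <- matrix(FALSE, length(pool$seqs), frame_len)
  if (length(starts) > 0L && p_cutoff > 0) {
    codes <- seqs_to_code_matrix(pool$seqs)
    for (st in c("+", "-")) {
      P <- grid_window_pvalues(pv, codes, st)[, starts, drop = FALSE]
      hit <- which(!is.na(P) & P <= p_cutoff, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        for (k in seq_len(nrow(hit))) {
          j0 <- starts[hit[k, 2L]]
          mask[hit[k, 1L], j0:(j0 + x$L - 1L)] <- TRUE
        }
      }
    }
  }
  if (!is.null(pool$mask)) mask <- mask | pool$mask
  pool$mask <- mask
  pool
}

#' Drop sequences with significant off-core motif matches
#'
#' @inheritParams mask_motif_matches
#' @return the pool restricted to sequences without any off-core hit at
#'   p <= `p_cutoff`; the number removed is attached as attribute
#'   `n_dropped`.
#' @export
drop_motif_sequences <- function(pool, x, bg = background(), p_cutoff = 0.001,
                                 pv = NULL) {
  h <- homotypy_scores(pool, x, bg, bins = c(p_cutoff, 1, 1), pv = pv)
  keep <- h$n_p001 == 0L
  dropped <- sum(!keep)
  pool$seqs <- pool$seqs[keep]
  pool$meta <- pool$meta[keep, , drop = FALSE]
  if (!is.null(pool$mask)) pool$mask <- pool$mask[keep, , drop = FALSE]
  attr(pool, "n_dropped") <- dropped
  pool
}
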