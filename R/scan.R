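# Window scoring over an integer code matrix.
# codes: n_seq x len matrix, lod: L x 4 score matrix.
# Returns n_seq x (len - L + 1) matrix of window scores; windows touching an
# NA code (non-ACGT base) come out NA.
window_score_matrix <- function(codes, lod) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  L <- nrow(lod)
  len <- ncol(codes)
  W <- len - L + 1L
  if (W < 1L) return(matrix(numeric(0), nrow = nrow(codes), ncol = 0L))
  S <- matrix(0, nrow(codes), W)
  for (j in seq_len(L)) {
    block <- codes[, j:(j + W - 1L), drop = FALSE]
    S <- S + matrix(lod[j, block], nrow(codes), W)
  }
  S
}

#' Exact p-values for PFM log-odds scores
#'
#' Dynamic program over motif positions that convolves the per-position score
#' distribution under the background, on a discretized score grid. Gives the
#' exact null tail probability P(score >= s) for every achievable score, the
#' same construction FIMO-style scanners use to honor p-value cutoffs.
#'
#' @param x a `pfm` (L <= 30 at the default granularity).
#' @param bg a `dna_background`.
#' @param granularity width of a score bin in bits (default 1e-3).
#' @return object of class `pfm_pvalues`: the discretized log-odds matrix,
#'   grid origin and the tail vector. Use [score_pvalue()] to query it.
#' @export
exact_pvalues <- function(x, bg = background(), granularity = 1e-3) {
  if (granularity <= 0) stop("granularity must be > 0")
  lod <- log_odds_matrix(x, bg)
  ilod <- round(lod / granularity)
  if (x$L > 30 && granularity < 1e-3) stop("motif too long for the p-value table at this granularity")
  mins <- apply(ilod, 1L, min)
  maxs <- apply(ilod, 1L, max)
  dist <- 1  # probability mass by offset from the running minimum
  bgp <- as.numeric(bg)
  for (j in seq_len(x$L)) {
    off <- ilod[j, ] - mins[j]
    new <- numeric(length(dist) + (maxs[j] - mins[j]))
    for (b in 1:4) {
      idx <- seq_along(dist) + off[b]
      new[idx] <- new[idx] + bgp[b] * dist
    }
    dist <- new
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  structure(list(granularity = granularity, ilod = ilod,
                 imin = sum(mins), tail = tail),
            class = "pfm_pvalues")
}

#' Tail probability of a log-odds score under the background
#'
#' @param tab a `pfm_pvalues` table from [exact_pvalues()].
#' @param score numeric vector of log2-odds scores.
#' @return P(score' >= score) under the background, evaluated on the
#'   discretized grid (scores are rounded to the grid before lookup).
#' @export
score_pvalue <- function(tab, score) {
  idx <- round(score / tab$granularity) - tab$imin + 1
  idx <- pmin(pmax(idx, 1), length(tab$tail) + 1)
  c(tab$tail, 0)[idx]
}

# integer grid representation of scores, used wherever equality of scores
# must be decided (tie detection) to avoid float artifacts
score_grid_index <- function(tab, score) round(score / tab$granularity)

# grid log-odds matrix for a strand: the reverse-strand matrix is the
# forward one with rows reversed and columns complemented, exactly
grid_lod <- function(tab, strand = "+") {
  if (strand == "+") tab$ilod
  else tab$ilod[rev(seq_len(nrow(tab$ilod))), COMP_CODE, drop = FALSE]
}

# window p-values computed on the DP's own integer grid (per-position
# rounded scores summed), so table lookups are exact, tie groups included
grid_window_pvalues <- function(tab, codes, strand = "+") {
  I <- window_score_matrix(codes, grid_lod(tab, strand))
  idx <- I - tab$imin + 1
  p <- matrix(tab$tail[idx], nrow(I), ncol(I))
  p
}

# grid sums for tie comparison / best-hit selection
grid_window_scores <- function(tab, codes, strand = "+") {
  window_score_matrix(codes, grid_lod(tab, strand))
}

# exact p-value of a single k-mer given as integer codes
kmer_grid_pvalue <- function(tab, codes) {
  I <- sum(tab$ilod[cbind(seq_len(nrow(tab$ilod)), codes)])
  tab$tail[I - tab$imin + 1]
}

#' Scan sequences for PFM hits
#'
#' Slides the PFM over every window of each sequence, scores it in log2-odds
#' against the background, assigns each score its exact p-value, and reports
#' windows at or below the p-value cutoff. Reverse-strand hits are scored on
#' the reverse complement of the window and reported in forward coordinates.
#' Windows containing a non-ACGT base are skipped.
#'
#' @param x a `pfm`.
#' @param seqs named character vector of sequences (any lengths).
#' @param bg a `dna_background`.
#' @param p_cutoff report hits with p-value <= this (default 1e-4).
#' @param strands `"both"` or `"forward"`.
#' @param pv optional precomputed [exact_pvalues()] table.
#' @return data.frame with columns `seq_id`, `offset` (1-based start on the
#'   forward sequence), `strand`, `score`, `pvalue`.
#' @export
scan_pfm <- function(x, seqs, bg = background(), p_cutoff = 1e-4,
                     strands = c("both", "forward"), pv = NULL) {
  strands <- match.arg(strands)
  if (is.null(pv)) pv <- exact_pvalues(x, bg)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lod_f <- log_odds_matrix(x, bg)
  lod_r <- rc_log_odds_matrix(x, bg)
  by_len <- split(seq_along(seqs), nchar(seqs))
  out <- list()
  for (grp in by_len) {
    len <- nchar(seqs[[grp[1L]]])
    if (len < x$L) next
    codes <- seqs_to_code_matrix(seqs[grp])
    for (st in if (strands == "both") c("+", "-") else "+") {
      S <- window_score_matrix(codes, if (st == "+") lod_f else lod_r)
      p <- grid_window_pvalues(pv, codes, st)
      keep <- which(!is.na(S) & p <= p_cutoff, arr.ind = TRUE)
      if (nrow(keep) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = names(seqs)[grp][keep[, 1L]],
        offset = keep[, 2L],
        strand = st,
        score = S[keep],
        pvalue = p[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$seq_id, names(seqs)), res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Write motif hits as TSV
#' @param hits data.frame from [scan_pfm()].
#' @param path output path. Offsets are converted to 0-based for the file.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$offset <- out$offset - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
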