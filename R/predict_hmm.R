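#' Two-state block HMM specification
#'
#' Generative model of a sequence as an interleaving of single background
#' characters and whole motif blocks: at every emission boundary the model
#' emits one background base with probability `t_bg` (default 0.99) or a
#' complete L-bp motif block with probability `1 - t_bg`, the block forward
#' with probability `s` (the precalculated strand bias) and reverse
#' otherwise. Background emissions come from `beta`, chosen per `mode`:
#' `"genomic"` (nucleotide frequencies of the TF's unbound pool),
#' `"pfm_average"` (column-average of the PFM), or `"pfm_inversed"`
#' (pfm_average with the A/G and T/C masses swapped, exchanging the AT and
#' GC totals).
#'
#' @param x a `pfm` (block emission probabilities).
#' @param beta a `dna_background` used when `mode` needs none of the
#'   derived settings (mode `"genomic"` uses `beta` as given).
#' @param t_bg background emission probability per step (default 0.99).
#' @param strand_bias probability a motif block is forward-oriented.
#' @param mode background emission mode.
#' @return object of class `hmm_spec`.
#' @export
hmm_spec <- function(x, beta = background(), t_bg = 0.99, strand_bias = 0.5,
                     mode = c("genomic", "pfm_average", "pfm_inversed")) {
  mode <- match.arg(mode)
  if (t_bg <= 0 || t_bg >= 1) stop("t_bg must be in (0, 1)")
  if (strand_bias < 0 || strand_bias > 1) stop("strand_bias must be in [0, 1]")
  if (mode == "pfm_average") beta <- pfm_average_background(x)
  if (mode == "pfm_inversed") {
    avg <- as.numeric(pfm_average_background(x))
    # swap A<->G and T<->C mass: AT total becomes GC total and vice versa
    beta <- background(avg[c(3L, 4L, 1L, 2L)])
  }
  structure(list(pfm = x, beta = beta, t_bg = t_bg, strand_bias = strand_bias,
                 mode = mode), class = "hmm_spec")
}

#' Strand bias of a motif in a bound pool
#'
#' Fraction of motif hits (p <= `p_cutoff`, default 0.001) found in the
#' forward orientation; 0.5 when there are no hits.
#'
#' @param bound_seqs character vector of bound sequences (raw probes or an
#'   `aligned_pool`'s sequences).
#' @param x a `pfm`.
#' @param bg a `dna_background`.
#' @param p_cutoff hit p-value cutoff.
#' @param pv optional precomputed [exact_pvalues()] table.
#' @return strand bias s in [0, 1].
#' @export
estimate_strand_bias <- function(bound_seqs, x, bg = background(),
                                 p_cutoff = 0.001, pv = NULL) {
  if (inherits(bound_seqs, "aligned_pool")) bound_seqs <- bound_seqs$seqs
  hits <- scan_pfm(x, bound_seqs, bg, p_cutoff = p_cutoff, strands = "both",
                   pv = pv)
  if (nrow(hits) == 0L) return(0.5)
  mean(hits$strand == "+")
}

# per-sequence log-likelihood under the block HMM, vectorized over a pool of
# equal-length sequences. Forward recursion over emission boundaries:
#   F(0) = 1
#   F(i) = t * beta(x_i) * F(i-1)
#        + (1-t) * [i >= L] * (s * Pfwd(i-L+1..i) + (1-s) * Prev(...)) * F(i-L)
# computed in log space.
hmm_loglik_matrix <- function(hmm, codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  n <- ncol(codes); m <- nrow(codes)
  if (any(is.na(codes))) stop("N in sequence: mask or drop before HMM scoring")
  L <- hmm$pfm$L
  lbeta <- log(as.numeric(hmm$beta))
  lt <- log(hmm$t_bg); l1t <- log1p(-hmm$t_bg)
  emis <- matrix(lbeta[codes], m, n)
  if (n == 0L) return(numeric(m))
  # motif-block log-probabilities for windows ending at position i
  lpf <- log(hmm$pfm$freq)
  lpr <- lpf[rev(seq_len(L)), COMP_CODE, drop = FALSE]  # revcomp-window prob
  W <- n - L + 1L
  if (W >= 1L) {
    Bf <- window_score_matrix(codes, lpf)
    Br <- window_score_matrix(codes, lpr)
    s <- hmm$strand_bias
    if (s <= 0) Bl <- Br + log(1 - s)
    else if (s >= 1) Bl <- Bf + log(s)
    else {
      hi <- pmax(Bf + log(s), Br + log(1 - s))
      lo <- pmin(Bf + log(s), Br + log(1 - s))
      Bl <- hi + log1p(exp(lo - hi))
    }
  }
  logF <- matrix(-Inf, m, n + 1L)
  logF[, 1L] <- 0
  for (i in seq_len(n)) {
    v <- lt + emis[, i] + logF[, i]
    if (i >= L) {
      w <- l1t + Bl[, i - L + 1L] + logF[, i - L + 1L]
      hi <- pmax(v, w); lo <- pmin(v, w)
      v <- ifelse(is.finite(hi), hi + log1p(exp(lo - hi)), hi)
    }
    logF[, i + 1L] <- v
  }
  logF[, n + 1L]
}

#' Log-likelihood of a sequence under the block HMM
#'
#' @param hmm an `hmm_spec`.
#' @param seq character scalar over ACGT (error on N).
#' @return log P(seq | hmm) (natural log).
#' @export
sequence_loglik <- function(hmm, seq) {
  if (nchar(seq) == 0L) return(0)
  hmm_loglik_matrix(hmm, matrix(seq_to_codes(seq), nrow = 1L))
}

#' Log-likelihood ratio of the HMM against a fixed genomic background
#'
#' `log P(seq | hmm) - sum_i log genomic_beta(x_i)`; the genomic background
#' is estimated from the TF's unbound pool.
#'
#' @param hmm an `hmm_spec`.
#' @param seqs character vector of equal-length sequences (or one sequence).
#' @param genomic_beta a `dna_background` for the denominator.
#' @return numeric vector of LLR scores.
#' @export
llr <- function(hmm, seqs, genomic_beta) {
  if (length(seqs) == 0L) return(numeric(0))
  codes <- seqs_to_code_matrix(seqs)
  num <- hmm_loglik_matrix(hmm, codes)
  lg <- log(as.numeric(genomic_beta))
  den <- rowSums(matrix(lg[codes], nrow(codes), ncol(codes)))
  setNames(num - den, names(seqs))
}

#' AUROC of HMM log-likelihood-ratio scores, bound versus unbound
#'
#' Builds the HMM for the requested background mode (strand bias estimated
#' from the bound pool, genomic background from the unbound pool), scores
#' both pools by LLR and returns the AUROC.
#'
#' @param bound_pool,unbound_pool `aligned_pool`s (or character vectors of
#'   equal-length sequences).
#' @param x a `pfm`.
#' @param mode background emission mode, see [hmm_spec()].
#' @param bg scanning background for the strand-bias estimate.
#' @param t_bg background emission probability (default 0.99).
#' @return list: `auroc`, `hmm`, `scores_bound`, `scores_unbound`.
#' @export
hmm_auroc <- function(bound_pool, unbound_pool, x,
                      mode = c("genomic", "pfm_average", "pfm_inversed"),
                      bg = background(), t_bg = 0.99) {
  mode <- match.arg(mode)
  bseqs <- if (inherits(bound_pool, "aligned_pool")) bound_pool$seqs else bound_pool
  useqs <- if (inherits(unbound_pool, "aligned_pool")) unbound_pool$seqs else unbound_pool
  genomic_beta <- background_from_seqs(useqs)
  s <- estimate_strand_bias(bseqs, x, bg)
  hmm <- hmm_spec(x, beta = genomic_beta, t_bg = t_bg, strand_bias = s,
                  mode = mode)
  sb <- llr(hmm, bseqs, genomic_beta)
  su <- llr(hmm, useqs, genomic_beta)
  list(auroc = auroc(c(sb, su), c(rep(1L, length(sb)), rep(0L, length(su)))),
       hmm = hmm, scores_bound = sb, scores_unbound = su)
}
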