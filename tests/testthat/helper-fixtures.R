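# shared fixtures: small informative motifs, enumeration oracles, and a
# quick way to build aligned pools from literal sequence strings

BASES <- c("A", "C", "G", "T")

# asymmetric, informative 4-position motif (consensus ACGG, clearly
# non-palindromic), continuous column values so score ties are not
# structural
fix_pfm4 <- function(pseudocount = 0.01) {
  pfm(rbind(c(0.82, 0.07, 0.06, 0.05),
            c(0.05, 0.81, 0.08, 0.06),
            c(0.07, 0.05, 0.80, 0.08),
            c(0.06, 0.08, 0.81, 0.05)),
      name = "fix4", pseudocount = pseudocount)
}

# palindromic consensus ACGCGT
fix_palindrome <- function(pseudocount = 0.01) {
  half <- rbind(c(0.85, 0.05, 0.05, 0.05),
                c(0.05, 0.85, 0.05, 0.05),
                c(0.05, 0.05, 0.85, 0.05))
  pfm(rbind(half, half[3:1, 4:1]), name = "pal", pseudocount = pseudocount)
}

# random PFM with continuous (Dirichlet-like) columns, no structural ties
random_continuous_pfm <- function(L, seed, conc = 0.8) {
  with_local_seed(seed, {
    f <- matrix(rgamma(L * 4, conc), L, 4)
    pfm(f / rowSums(f), name = paste0("rnd", L), pseudocount = 0.01)
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len, seed, gc = 0.5) {
  with_local_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(BASES, len, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), "")
  })
}

# all k-mers over ACGT as strings
all_kmers <- function(L) {
  g <- do.call(expand.grid, rep(list(BASES), L))
  apply(g[, rev(seq_len(L)), drop = FALSE], 1L, paste, collapse = "")
}

# enumeration oracle for exact p-values: per-kmer grid score (independent
# re-rounding of the per-position log-odds at the same granularity) and the
# background-probability tail over all k-mers
enumerate_pvalues <- function(x, bg = background(), granularity = 1e-3) {
  L <- x$L
  lod <- log_odds_matrix(x, bg)
  ig <- round(lod / granularity)
  codes <- as.matrix(do.call(expand.grid, rep(list(1:4), L)))
  gs <- rowSums(matrix(ig[cbind(rep(seq_len(L), each = nrow(codes)),
                                as.vector(codes))], nrow(codes), L))
  prob <- apply(matrix(as.numeric(bg)[codes], nrow(codes), L), 1L, prod)
  score <- rowSums(matrix(lod[cbind(rep(seq_len(L), each = nrow(codes)),
                                    as.vector(codes))], nrow(codes), L))
  kmer <- apply(codes, 1L, function(k) paste(BASES[k], collapse = ""))
  tails <- vapply(gs, function(g) sum(prob[gs >= g]), 0)
  data.frame(kmer = kmer, grid = gs, score = score, prob = prob,
             pvalue = tails, stringsAsFactors = FALSE)
}

# scanning oracle: enumerate every window of every sequence, score by
# log_odds on both strands, p-value by k-mer-enumeration tail
oracle_scan <- function(x, seqs, bg = background(), p_cutoff,
                        strands = "both") {
  en <- enumerate_pvalues(x, bg)
  ptab <- setNames(en$pvalue, en$kmer)
  stab <- setNames(en$score, en$kmer)
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) < x$L) next
    for (o in seq_len(nchar(s) - x$L + 1L)) {
      w <- substr(s, o, o + x$L - 1L)
      if (grepl("[^ACGT]", w)) next
      for (st in if (strands == "both") c("+", "-") else "+") {
        k <- if (st == "+") w else revcomp(w)
        if (ptab[[k]] <= p_cutoff)
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = names(seqs)[i], offset = o, strand = st,
            score = stab[[k]], pvalue = ptab[[k]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(seq_id = character(), offset = integer(),
                                       strand = character(), score = numeric(),
                                       pvalue = numeric()))
  out <- do.call(rbind, rows)
  out[order(match(out$seq_id, names(seqs)), out$offset, out$strand), ]
}

# brute-force sum over all tilings of a sequence into single background
# characters and non-overlapping motif blocks, both orientations
brute_force_loglik <- function(hmm, codes) {
  L <- hmm$pfm$L
  beta <- as.numeric(hmm$beta)
  t <- hmm$t_bg; s <- hmm$strand_bias
  recurse <- function(i) {
    if (i == 0L) return(1)
    v <- t * beta[codes[i]] * recurse(i - 1L)
    if (i >= L) {
      k <- codes[(i - L + 1L):i]
      pf <- prod(hmm$pfm$freq[cbind(seq_len(L), k)])
      rk <- motifenv:::COMP_CODE[rev(k)]
      pr <- prod(hmm$pfm$freq[cbind(seq_len(L), rk)])
      v <- v + (1 - t) * (s * pf + (1 - s) * pr) * recurse(i - L)
    }
    v
  }
  log(recurse(length(codes)))
}

# build an aligned pool from literal aligned strings
make_pool <- function(seqs, core_start, core_len, label = "bound",
                      core_exclusion = 2L) {
  len <- nchar(seqs[[1]])
  aligned_pool(setNames(seqs, paste0("s", seq_along(seqs))), label = label,
               flank_up = core_start - 1L,
               flank_down = len - core_start - core_len + 1L,
               core_len = core_len, core_exclusion = core_exclusion)
}
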