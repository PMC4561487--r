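#' Aligned sequence pool
#'
#' Container for a bound or unbound pool aligned so that the core motif
#' occupies a fixed block. The aligned frame is
#' `flank_up + core_len + flank_down` bp wide with the core starting at
#' column `flank_up + 1`. Positions within `core_exclusion` bp of the core
#' are excluded from all positional statistics.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @param label `"bound"` or `"unbound"`.
#' @param flank_up,flank_down usable flank widths (bp).
#' @param core_len core motif length (bp).
#' @param core_exclusion bp adjacent to the core excluded from statistics
#'   (default 2).
#' @param meta optional per-sequence data.frame (seq_id, strand, score, ...).
#' @return object of class `aligned_pool`.
#' @export
aligned_pool <- function(seqs, label = c("bound", "unbound"),
                         flank_up, flank_down, core_len,
                         core_exclusion = 2L, meta = NULL) {
  label <- match.arg(label)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned sequences must all have the same length")
  if (len != flank_up + core_len + flank_down)
    stop("frame width ", len, " != flank_up + core_len + flank_down")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(meta)) meta <- data.frame(seq_id = names(seqs), stringsAsFactors = FALSE)
  structure(list(label = label, seqs = seqs,
                 flank_up = as.integer(flank_up), flank_down = as.integer(flank_down),
                 core_start = as.integer(flank_up) + 1L,
                 core_len = as.integer(core_len),
                 core_exclusion = as.integer(core_exclusion),
                 meta = meta, mask = NULL),
            class = "aligned_pool")
}

#' @export
print.aligned_pool <- function(x, ...) {
  cat(sprintf("aligned_pool (%s): %d sequences, frame %d bp, core at %d..%d, flanks %d/%d\n",
              x$label, length(x$seqs), nchar(x$seqs[[1]]),
              x$core_start, x$core_start + x$core_len - 1L,
              x$flank_up, x$flank_down))
  invisible(x)
}

#' @export
length.aligned_pool <- function(x) length(x$seqs)

# columns of the aligned frame that enter positional statistics, with their
# relative coordinates (negative upstream of the core start, positive
# downstream of the core end; 0 never occurs)
analysis_positions <- function(pool) {
  up_cols <- seq_len(pool$flank_up - pool$core_exclusion)
  core_end <- pool$core_start + pool$core_len - 1L
  down_n <- pool$flank_down - pool$core_exclusion
  down_cols <- if (down_n > 0L) core_end + pool$core_exclusion + seq_len(down_n) else integer(0)
  if (pool$flank_up - pool$core_exclusion <= 0L) up_cols <- integer(0)
  data.frame(
    column = c(up_cols, down_cols),
    position = c(up_cols - pool$core_start,
                 down_cols - core_end))
}

# columns covered by the core block
core_columns <- function(pool) seq.int(pool$core_start, pool$core_start + pool$core_len - 1L)

#' Align pools on their best motif hit
#'
#' Scans every sequence with the PFM, keeps the unique highest-scoring hit at
#' or below the p-value cutoff, reverse-complements records whose best hit is
#' on the reverse strand into the common frame, and trims each record to a
#' fixed window of `flank_up`/`flank_down` bp around the core. Records are
#' discarded (and counted by reason) when no window passes the cutoff
#' (`"no_hit"`), when the top score is tied across two or more windows
#' (`"tie"`, scores compared on the p-value table's discretized grid), or
#' when the requested window runs off the sequence (`"flank"`).
#'
#' @param seqs named character vector of probes/regions.
#' @param x a `pfm`.
#' @param bg a `dna_background`.
#' @param p_cutoff hit p-value cutoff for the alignment step (default 1e-4).
#' @param strands `"both"` or `"forward"`; `"auto"` scans both strands iff
#'   the motif is palindromic.
#' @param flank_up,flank_down requested flank widths (default 10, the
#'   in vitro window).
#' @param core_exclusion stored on the pool (default 2).
#' @param label pool label.
#' @param min_pool_size error if fewer survivors than this (default 1000,
#'   the study's inclusion filter); set 0 to disable.
#' @return an `aligned_pool` with a `discarded` attribute: data.frame of
#'   seq_id and reason for every dropped record.
#' @export
align_best_hit <- function(seqs, x, bg = background(), p_cutoff = 1e-4,
                           strands = c("both", "forward", "auto"),
                           flank_up = 10L, flank_down = 10L,
                           core_exclusion = 2L,
                           label = c("bound", "unbound"),
                           min_pool_size = 1000L) {
  strands <- match.arg(strands)
  label <- match.arg(label)
  if (strands == "auto") strands <- if (is_palindromic(x)) "both" else "forward"
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pv <- exact_pvalues(x, bg)
  lod_f <- log_odds_matrix(x, bg)
  lod_r <- rc_log_odds_matrix(x, bg)
  L <- x$L

  n <- length(seqs)
  reason <- character(n)
  keep_off <- integer(n); keep_strand <- character(n)
  keep_score <- numeric(n); keep_p <- numeric(n)

  by_len <- split(seq_len(n), nchar(seqs))
  for (grp in by_len) {
    len <- nchar(seqs[[grp[1L]]])
    if (len < L) { reason[grp] <- "no_hit"; next }
    codes <- seqs_to_code_matrix(seqs[grp])
    Sf <- window_score_matrix(codes, lod_f)
    S <- Sf
    G <- grid_window_scores(pv, codes, "+")
    if (strands == "both") {
      S <- cbind(S, window_score_matrix(codes, lod_r))
      G <- cbind(G, grid_window_scores(pv, codes, "-"))
    }
    W <- ncol(Sf)
    for (k in seq_along(grp)) {
      i <- grp[k]
      g <- G[k, ]
      if (all(is.na(g))) { reason[i] <- "no_hit"; next }
      best <- max(g, na.rm = TRUE)
      hits <- which(!is.na(g) & g == best)
      p <- pv$tail[best - pv$imin + 1]
      if (p > p_cutoff) { reason[i] <- "no_hit"; next }
      if (length(hits) > 1L) { reason[i] <- "tie"; next }
      j <- hits[1L]
      if (j <= W) { keep_off[i] <- j; keep_strand[i] <- "+" }
      else { keep_off[i] <- j - W; keep_strand[i] <- "-" }
      keep_score[i] <- S[k, j]; keep_p[i] <- p
    }
  }

  # build the common frame
  aligned <- character(0); ids <- character(0)
  meta_rows <- list()
  for (i in which(reason == "")) {
    s <- seqs[[i]]; len <- nchar(s); o <- keep_off[i]
    if (keep_strand[i] == "-") {
      s <- revcomp(s)
      o <- len - (o + L - 1L) + 1L
    }
    if (o - flank_up < 1L || o + L - 1L + flank_down > len) {
      reason[i] <- "flank"
      next
    }
    aligned[length(aligned) + 1L] <- substr(s, o - flank_up, o + L - 1L + flank_down)
    ids[length(ids) + 1L] <- names(seqs)[i]
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      seq_id = names(seqs)[i], strand = keep_strand[i],
      score = keep_score[i], pvalue = keep_p[i],
      src_offset = keep_off[i], stringsAsFactors = FALSE)
  }
  if (min_pool_size > 0L && length(aligned) < min_pool_size)
    stop("pool too small after alignment: ", length(aligned),
         " sequences (< ", min_pool_size, ")")
  if (length(aligned) == 0L)
    stop("no sequences survived alignment (reasons: ",
         paste(sprintf("%s=%d", names(table(reason[reason != ""])),
                       table(reason[reason != ""])), collapse = ", "), ")")
  names(aligned) <- ids
  pool <- aligned_pool(aligned, label = label,
                       flank_up = flank_up, flank_down = flank_down,
                       core_len = L, core_exclusion = core_exclusion,
                       meta = do.call(rbind, meta_rows))
  attr(pool, "discarded") <- data.frame(
    seq_id = names(seqs)[reason != ""],
    reason = reason[reason != ""], stringsAsFactors = FALSE)
  pool
}

#' Subsample the larger of two pools to match sizes
#'
#' @param a,b `aligned_pool`s.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return list of the two pools, the larger subsampled without replacement.
#' @export
match_sizes <- function(a, b, seed = 1L) {
  na <- length(a$seqs); nb <- length(b$seqs)
  if (na == 0L || nb == 0L) stop("cannot size-match an empty pool")
  n <- min(na, nb)
  subsample <- function(pool, n, seed) {
    if (length(pool$seqs) == n) return(pool)
    idx <- sort(sample_with_seed(length(pool$seqs), n, seed))
    pool$seqs <- pool$seqs[idx]
    pool$meta <- pool$meta[idx, , drop = FALSE]
    if (!is.null(pool$mask)) pool$mask <- pool$mask[idx, , drop = FALSE]
    pool
  }
  list(subsample(a, n, seed), subsample(b, n, seed + 1L))
}

# sample() under a local RNG state so callers' RNG streams are untouched
sample_with_seed <- function(pop, size, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(pop, size)
}

#' Write an aligned pool as FASTA plus a JSON frame sidecar
#' @param pool an `aligned_pool`.
#' @param fasta_path output FASTA path; the sidecar goes to
#'   `paste0(fasta_path, ".json")`.
#' @export
write_pool <- function(pool, fasta_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pool$seqs), fasta_path)
  meta <- list(label = pool$label, flank_up = pool$flank_up,
               flank_down = pool$flank_down, core_start = pool$core_start,
               core_len = pool$core_len, core_exclusion = pool$core_exclusion)
  jsonlite::write_json(meta, paste0(fasta_path, ".json"), auto_unbox = TRUE)
  invisible(fasta_path)
}

#' Read an aligned pool written by [write_pool()]
#' @param fasta_path FASTA path with a `.json` sidecar next to it.
#' @return an `aligned_pool`.
#' @export
read_pool <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  meta <- jsonlite::read_json(paste0(fasta_path, ".json"), simplifyVector = TRUE)
  aligned_pool(setNames(as.character(ss), names(ss)),
               label = meta$label, flank_up = meta$flank_up,
               flank_down = meta$flank_down, core_len = meta$core_len,
               core_exclusion = meta$core_exclusion)
}

#' Read sequences from a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
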