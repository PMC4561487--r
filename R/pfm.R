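#' @importFrom stats wilcox.test p.adjust quantile rbinom rpois runif rnorm sd setNames complete.cases
#' @importFrom utils write.table read.delim head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")
# complement in code space: A<->T, C<->G
COMP_CODE <- c(4L, 3L, 2L, 1L)

#' Position frequency matrix
#'
#' Constructs a PFM object from an L x 4 matrix of per-position nucleotide
#' probabilities (columns in A, C, G, T order). A pseudocount is added to
#' every cell and rows are renormalized, so downstream log-odds scores are
#' finite even for consensus-like columns.
#'
#' @param freq numeric L x 4 matrix (or data frame) of column probabilities;
#'   rows are motif positions, columns A, C, G, T. Rows need not sum to one
#'   exactly before normalization but must be non-negative with positive sum.
#' @param name motif identifier.
#' @param pseudocount probability mass added to each cell before
#'   renormalization (default 0.01).
#' @return object of class `pfm` with elements `name`, `L`, `freq`
#'   (pseudocounted, rows summing to 1) and `pseudocount`.
#' @export
pfm <- function(freq, name = "motif", pseudocount = 0.01) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("PFM must have 4 columns (A, C, G, T)")
  if (nrow(freq) < 1L) stop("PFM must have at least one position")
  if (any(freq < 0) || any(!is.finite(freq))) stop("PFM entries must be finite and >= 0")
  rs <- rowSums(freq)
  if (any(rs <= 0)) stop("PFM row sum <= 0 at position ", which(rs <= 0)[1])
  freq <- freq / rs
  freq <- freq + pseudocount
  freq <- freq / rowSums(freq)
  dimnames(freq) <- list(NULL, DNA_BASES)
  structure(list(name = name, L = nrow(freq), freq = freq, pseudocount = pseudocount),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s': %d positions, pseudocount %g\n", x$name, x$L, x$pseudocount))
  cat("consensus:", consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PFM (most probable base per position)
#' @param x a `pfm`.
#' @return character scalar over ACGT.
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x$freq, 1L, which.max)], collapse = "")
}

#' Background nucleotide distribution
#'
#' @param probs numeric 4-vector of probabilities over A, C, G, T;
#'   defaults to uniform.
#' @return named, normalized numeric 4-vector of class `dna_background`.
#' @export
background <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L) stop("background needs 4 probabilities (A, C, G, T)")
  if (any(probs <= 0) || any(!is.finite(probs))) stop("background probabilities must be > 0")
  probs <- probs / sum(probs)
  structure(setNames(probs, DNA_BASES), class = "dna_background")
}

#' Background estimated from sequences (mononucleotide frequencies)
#' @param seqs character vector of ACGT(N) sequences; N is ignored.
#' @inheritParams pfm
#' @return a `dna_background`.
#' @export
background_from_seqs <- function(seqs, pseudocount = 1) {
  codes <- unlist(lapply(seqs, seq_to_codes), use.names = FALSE)
  counts <- tabulate(codes, nbins = 4L) + pseudocount
  background(counts / sum(counts))
}

#' Reverse complement of a PFM
#' @param x a `pfm`.
#' @return a `pfm` whose consensus is the reverse complement of `x`'s.
#' @export
revcomp_pfm <- function(x) {
  f <- x$freq[rev(seq_len(x$L)), COMP_CODE, drop = FALSE]
  # already pseudocounted/normalized; rebuild without adding more mass
  dimnames(f) <- list(NULL, DNA_BASES)
  structure(list(name = paste0(x$name, "_rc"), L = x$L, freq = f,
                 pseudocount = x$pseudocount), class = "pfm")
}

#' Is a PFM (near-)palindromic?
#'
#' A PFM is called palindromic when the root-mean-square per-cell distance to
#' its reverse complement is below `tol`; palindromic motifs are scanned on
#' both strands by default in the in vitro path.
#' @param x a `pfm`.
#' @param tol per-cell RMS distance threshold (default 0.05).
#' @export
is_palindromic <- function(x, tol = 0.05) {
  rc <- revcomp_pfm(x)
  sqrt(mean((x$freq - rc$freq)^2)) < tol
}

#' Average nucleotide composition of a PFM (column means)
#' @param x a `pfm`.
#' @return a `dna_background` of the position-averaged base frequencies.
#' @export
pfm_average_background <- function(x) background(colMeans(x$freq))

## ---- sequence <-> integer codes -----------------------------------------

#' Encode a DNA string as integer codes (A=1, C=2, G=3, T=4, other=NA)
#' @param seq character scalar.
#' @return integer vector.
#' @export
seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Encode equal-length sequences as an integer matrix (one row per sequence)
#' @param seqs character vector, all the same nchar.
#' @return integer matrix n x len; NA for non-ACGT characters.
#' @export
seqs_to_code_matrix <- function(seqs) {
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must all have the same length")
  m <- matrix(match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                    DNA_BASES),
              nrow = length(seqs), ncol = len, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

codes_to_seq <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Reverse complement of DNA strings
#' @param seqs character vector over ACGTN.
#' @return character vector.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

## ---- log-odds ------------------------------------------------------------

#' Log-odds matrix of a PFM against a background (log2)
#' @param x a `pfm`.
#' @param bg a `dna_background`.
#' @return L x 4 numeric matrix, `lod[i, b] = log2(freq[i, b] / bg[b])`.
#' @export
log_odds_matrix <- function(x, bg = background()) {
  sweep(log2(x$freq), 2L, log2(as.numeric(bg)), `-`)
}

# reverse-strand scoring matrix: applying it to a forward window w gives
# log_odds(pfm, revcomp(w), bg) exactly, for any background
rc_log_odds_matrix <- function(x, bg = background()) {
  lod <- log_odds_matrix(x, bg)
  lod[rev(seq_len(x$L)), COMP_CODE, drop = FALSE]
}

#' Log-odds score of a single k-mer
#' @param x a `pfm`.
#' @param kmer character scalar of length `x$L` over ACGT.
#' @param bg a `dna_background`.
#' @return log2 odds score.
#' @export
log_odds <- function(x, kmer, bg = background()) {
  codes <- seq_to_codes(kmer)
  if (length(codes) != x$L) stop("k-mer length ", length(codes), " != motif length ", x$L)
  if (anyNA(codes)) stop("k-mer contains a non-ACGT character")
  lod <- log_odds_matrix(x, bg)
  sum(lod[cbind(seq_len(x$L), codes)])
}

## ---- MEME motif format I/O ----------------------------------------------

#' Read a PFM from a MEME motif format file
#'
#' Minimal MEME (version 4+) text parser: finds `MOTIF` blocks followed by a
#' `letter-probability matrix` header and rows of four probabilities.
#'
#' @param path file path.
#' @param name motif name to select; default the first motif in the file.
#' @param pseudocount passed to [pfm()].
#' @return a `pfm`.
#' @export
read_pfm <- function(path, name = NULL, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty MEME file: ", path)
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) stop("no MOTIF block found in ", path)
  names_avail <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[motif_idx])
  pick <- if (is.null(name)) 1L else match(name, names_avail)
  if (is.na(pick)) stop("motif '", name, "' not found in ", path)
  start <- motif_idx[pick]
  end <- if (pick < length(motif_idx)) motif_idx[pick + 1L] - 1L else length(lines)
  block <- lines[start:end]
  hdr <- grep("letter-probability matrix", block)
  if (length(hdr) == 0L) stop("no letter-probability matrix for motif '",
                              names_avail[pick], "' in ", path)
  rows <- list()
  for (i in seq.int(hdr[1L] + 1L, length(block))) {
    ln <- trimws(block[i])
    if (ln == "" || grepl("^(URL|MOTIF)", ln)) break
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != 4L || anyNA(vals))
      stop("malformed letter-probability row at line ", start + hdr[1L] + length(rows),
           " of ", path, ": '", ln, "'")
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("letter-probability matrix has no rows in ", path)
  pfm(do.call(rbind, rows), name = names_avail[pick], pseudocount = pseudocount)
}

#' Write a PFM in MEME motif format
#'
#' Writes the stored (pseudocounted) probabilities; reading the file back
#' with pseudocount 0 reproduces them.
#'
#' @param x a `pfm`.
#' @param path output file path.
#' @param bg background written into the header's frequencies line.
#' @export
write_pfm <- function(x, path, bg = background()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", DNA_BASES, as.numeric(bg)), collapse = " "),
    "",
    paste("MOTIF", x$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1000 E= 0", x$L)
  ), con)
  writeLines(apply(x$freq, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}
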