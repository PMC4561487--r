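all_pentamers <- function() {
  g <- expand.grid(b5 = DNA_BASES, b4 = DNA_BASES, b3 = DNA_BASES,
                   b2 = DNA_BASES, b1 = DNA_BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5)
}

#' Load a pentamer propeller-twist table
#'
#' Reads a two-column TSV (pentamer, value in degrees). Accepts either the
#' full 1024-pentamer table or a 512-row reverse-complement-reduced one, in
#' which case the missing strand is synthesized (propeller twist is a
#' base-pair parameter, so value(revcomp(p)) == value(p)).
#'
#' @param path TSV path; a header line is optional.
#' @return object of class `shape_table`: named numeric vector over all 1024
#'   pentamers.
#' @export
load_shape_table <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) df <- df[-1, , drop = FALSE]  # header line
  pent <- toupper(df[[1]]); val <- as.numeric(df[[2]])
  if (any(is.na(val))) stop("non-numeric shape values at rows: ",
                            paste(head(which(is.na(val))), collapse = ", "))
  if (any(nchar(pent) != 5L) || any(grepl("[^ACGT]", pent)))
    stop("malformed pentamers: ", paste(head(pent[nchar(pent) != 5L | grepl("[^ACGT]", pent)]), collapse = ", "))
  if (anyDuplicated(pent))
    stop("duplicated pentamer rows: ", paste(head(unique(pent[duplicated(pent)])), collapse = ", "))
  tab <- setNames(val, pent)
  rc <- revcomp(pent)
  has_rc <- rc %in% pent
  bad <- pent[has_rc & abs(tab[pent] - ifelse(has_rc, tab[rc], NA)) > 1e-6]
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0L)
    stop("asymmetric duplicate pentamers: ", paste(head(unique(pmin(bad, revcomp(bad)))), collapse = ", "))
  # a 512-row reverse-complement-reduced table gets the other strand
  # synthesized; anything else must list all 1024 pentamers itself
  if (length(pent) == 512L) {
    missing_rc <- setdiff(rc, pent)
    if (length(missing_rc) > 0L)
      tab <- c(tab, setNames(tab[pent[match(missing_rc, rc)]], missing_rc))
  }
  miss <- setdiff(all_pentamers(), names(tab))
  if (length(miss) > 0L)
    stop("missing pentamers: ", paste(head(miss), collapse = ", "),
         if (length(miss) > 6) sprintf(" (+%d more)", length(miss) - 6L) else "")
  structure(tab[all_pentamers()], class = "shape_table")
}

#' Write a shape table as TSV
#' @param table a `shape_table`.
#' @param path output path.
#' @param reduced write only 512 reverse-complement-canonical rows.
#' @export
write_shape_table <- function(table, path, reduced = FALSE) {
  pent <- names(table)
  if (reduced) {
    keep <- pent <= revcomp(pent)
    pent <- pent[keep]
  }
  write.table(data.frame(pentamer = pent, value = as.numeric(table[pent])),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Synthetic reverse-complement-symmetric propeller-twist table
#'
#' Builds a drop-in stand-in for the pentamer propeller-twist model used for
#' testing: values are an affine function of the pentamer's GC count (GC-rich
#' pentamers less negative, as observed for real propeller twist) plus
#' pentamer-specific noise, symmetrized over reverse complements. It is
#' synthetic; real analyses should supply the published pentamer table.
#'
#' @param seed RNG seed.
#' @param intercept,slope affine parameters in degrees (defaults -14, +1.8:
#'   roughly the observed propeller-twist range from AT-rich to GC-rich).
#' @param noise_sd per-pentamer noise s.d. in degrees.
#' @return a `shape_table`.
#' @export
synthetic_shape_table <- function(seed = 1L, intercept = -14, slope = 1.8,
                                  noise_sd = 0.4) {
  pent <- all_pentamers()
  canon <- pmin(pent, revcomp(pent))
  classes <- unique(canon)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  gc_count <- vapply(strsplit(classes, ""), function(b) sum(b %in% c("G", "C")), 0)
  class_val <- intercept + slope * gc_count + rnorm(length(classes), 0, noise_sd)
  structure(setNames(class_val[match(canon, classes)], pent), class = "shape_table")
}

#' Per-position propeller-twist profile of one sequence
#'
#' Value at position i is the table entry for the pentamer centered on i.
#' The first and last two positions (and positions whose pentamer contains a
#' non-ACGT base) are undefined (`NA`).
#'
#' @param seq character scalar, >= 5 bp.
#' @param table a `shape_table`.
#' @return numeric vector of length `nchar(seq)`.
#' @export
propeller_profile <- function(seq, table) {
  n <- nchar(seq)
  if (n < 5L) stop("sequence shorter than a pentamer")
  out <- rep(NA_real_, n)
  pents <- substring(seq, 1:(n - 4L), 5:n)
  vals <- unname(table[pents])  # non-ACGT pentamers -> NA
  out[3:(n - 2L)] <- vals
  out
}

# pentamer profile over flank analysis positions for a whole aligned pool,
# vectorized through the code matrix (pentamer index = base-4 expansion)
shape_feature_matrix <- function(pool, table) {
  ap <- analysis_positions(pool)
  codes <- seqs_to_code_matrix(pool$seqs)
  n <- nrow(codes); len <- ncol(codes)
  # pentamer id centered at column i (i in 3..len-2)
  vals <- matrix(NA_real_, n, len)
  tab_lookup <- as.numeric(table[all_pentamers()])
  centers <- 3:(len - 2L)
  idx <- matrix(0L, n, length(centers))
  ok <- matrix(TRUE, n, length(centers))
  for (k in 0:4) {
    b <- codes[, centers - 2L + k, drop = FALSE]
    ok <- ok & !is.na(b)
    b[is.na(b)] <- 1L
    idx <- idx * 4L + (b - 1L)
  }
  v <- matrix(tab_lookup[idx + 1L], n, length(centers))
  v[!ok] <- NA_real_
  vals[, centers] <- v
  M <- vals[, ap$column, drop = FALSE]
  if (!is.null(pool$mask)) M[pool$mask[, ap$column, drop = FALSE]] <- NA_real_
  colnames(M) <- ap$position
  rownames(M) <- names(pool$seqs)
  M
}

#' Positional propeller-twist comparison between pools
#'
#' Computes the per-position propeller-twist value of every sequence from
#' the pentamer table and runs the same one-sided rank test / FDR machinery
#' as the nucleotide-content comparison.
#'
#' @param pool_b,pool_u bound and unbound `aligned_pool`s.
#' @param table a `shape_table`.
#' @param test,fdr_method see [compare_position()], [fdr_qvalues()].
#' @return `position_stats` with feature `"propeller_twist"`.
#' @export
compare_shape <- function(pool_b, pool_u, table,
                          test = c("rank_sum", "signed_rank"),
                          fdr_method = c("storey", "BH")) {
  Mb <- shape_feature_matrix(pool_b, table)
  Mu <- shape_feature_matrix(pool_u, table)
  delta_profile_matrices(Mb, Mu, "propeller_twist",
                         test = test, fdr_method = fdr_method)
}
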