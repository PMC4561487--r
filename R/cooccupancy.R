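df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Fraction of one TF's motif sites proximal to another TF's sites
#'
#' Site pairs whose intervals overlap by at least 1 bp are discarded from
#' A's numerator and denominator (overlapping motifs are typically the same
#' underlying site matched by related PFMs). A surviving A site counts as
#' proximal when its closest edge-to-edge gap to any B site is at most
#' `window` bp.
#'
#' @param sites_a,sites_b data.frames with `chrom`, `start`, `end`
#'   (0-based half-open) for the two TFs' motif sites.
#' @param window proximity window in bp (default 300).
#' @param mode `"edge"` (default) measures gaps between closest interval
#'   edges; `"midpoint"` between interval midpoints.
#' @return one-row data.frame: `frac_a_near_b` (NA with `undefined = TRUE`
#'   when no A site survives the overlap discard), `n_a_used`,
#'   `n_discarded_overlap`.
#' @export
proximity_fraction <- function(sites_a, sites_b, window = 300L,
                               mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  ga <- df_to_granges(sites_a); gb <- df_to_granges(sites_b)
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(ov))
  ga_keep <- if (length(drop)) ga[-drop] else ga
  gb_keep <- gb
  if (length(ga_keep) == 0L)
    return(data.frame(frac_a_near_b = NA_real_, n_a_used = 0L,
                      n_discarded_overlap = length(drop), undefined = TRUE))
  if (mode == "edge") {
    d <- GenomicRanges::distanceToNearest(ga_keep, gb_keep)
    near <- logical(length(ga_keep))
    near[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance <= window
  } else {
    mida <- (GenomicRanges::start(ga_keep) + GenomicRanges::end(ga_keep)) / 2
    midb <- (GenomicRanges::start(gb_keep) + GenomicRanges::end(gb_keep)) / 2
    near <- vapply(seq_along(ga_keep), function(i) {
      same <- as.character(GenomicRanges::seqnames(gb_keep)) ==
        as.character(GenomicRanges::seqnames(ga_keep)[i])
      any(abs(midb[same] - mida[i]) <= window)
    }, logical(1))
  }
  data.frame(frac_a_near_b = mean(near), n_a_used = length(ga_keep),
             n_discarded_overlap = length(drop), undefined = FALSE)
}

#' Similarity of two TFs' GC-environment preferences
#'
#' Summarizes each TF's GC profile as the mean signed significance
#' (delta = signed -log10 q) over positions and returns the ratio of the two
#' summaries, oriented so the larger-magnitude summary is the denominator:
#' the result lies in [-1, 1], 1 meaning identical direction and strength,
#' negative values opposite preferences.
#'
#' @param stats_a,stats_b `position_stats` GC profiles over the same window.
#' @return one-row data.frame: `ratio`, `summary_a`, `summary_b`,
#'   `degenerate` (TRUE when both summaries are exactly 0, in which case the
#'   ratio is defined as 1).
#' @export
gc_similarity <- function(stats_a, stats_b) {
  sa <- mean(stats_a$delta); sb <- mean(stats_b$delta)
  if (sa == 0 && sb == 0)
    return(data.frame(ratio = 1, summary_a = sa, summary_b = sb, degenerate = TRUE))
  num <- if (abs(sa) <= abs(sb)) sa else sb
  den <- if (abs(sa) <= abs(sb)) sb else sa
  data.frame(ratio = num / den, summary_a = sa, summary_b = sb, degenerate = FALSE)
}

#' Within- versus between-family co-occupancy fractions
#'
#' @param records data.frame of pairwise records with columns `tf_a`,
#'   `tf_b`, `frac_a_near_b` (e.g. stacked [proximity_fraction()] results).
#' @param family_map named character vector mapping TF name to family.
#' @return list with `within` and `between` fraction vectors and `p_value`
#'   of a two-sided rank-sum test (NA when either group is empty).
#' @export
family_partition <- function(records, family_map) {
  fa <- family_map[records$tf_a]; fb <- family_map[records$tf_b]
  ok <- !is.na(fa) & !is.na(fb) & !is.na(records$frac_a_near_b)
  within <- records$frac_a_near_b[ok & fa == fb]
  between <- records$frac_a_near_b[ok & fa != fb]
  p <- if (length(within) && length(between))
    suppressWarnings(wilcox.test(within, between)$p.value) else NA_real_
  list(within = within, between = between, p_value = p)
}
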