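IUPAC_CODES <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

iupac_allowed_matrix <- function(iupac_seed) {
  chars <- strsplit(toupper(iupac_seed), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  t(vapply(chars, function(ch) DNA_BASES %in% IUPAC_CODES[[ch]], logical(4)))
}

#' Refine an IUPAC seed into a PFM from peak sequences
#'
#' Collects every occurrence of the IUPAC motif seed allowing up to
#' `max_mismatch` mismatches (degenerate codes match any of their encoded
#' bases at zero mismatches), on both strands, stacks the matched k-mers in
#' motif orientation, and converts the column base counts into a PFM.
#'
#' @param peak_seqs character vector of peak sequences.
#' @param iupac_seed IUPAC motif string.
#' @param max_mismatch maximum mismatches per occurrence (default 1).
#' @param pseudocount passed to [pfm()].
#' @return a `pfm`; the number of stacked occurrences is attached as
#'   attribute `n_occurrences`.
#' @export
refine_iupac_to_pfm <- function(peak_seqs, iupac_seed, max_mismatch = 1L,
                                pseudocount = 0.01) {
  A <- iupac_allowed_matrix(iupac_seed)
  L <- nrow(A)
  Arc <- A[rev(seq_len(L)), COMP_CODE, drop = FALSE]
  counts <- matrix(0, L, 4L)
  n_occ <- 0L
  by_len <- split(seq_along(peak_seqs), nchar(peak_seqs))
  for (grp in by_len) {
    len <- nchar(peak_seqs[[grp[1L]]])
    if (len < L) next
    codes <- seqs_to_code_matrix(peak_seqs[grp])
    for (orient in c("+", "-")) {
      M <- if (orient == "+") A else Arc
      match_count <- window_score_matrix(codes, M * 1)
      hit <- which(!is.na(match_count) & match_count >= L - max_mismatch,
                   arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      n_occ <- n_occ + nrow(hit)
      for (k in seq_len(nrow(hit))) {
        w <- codes[hit[k, 1L], hit[k, 2L]:(hit[k, 2L] + L - 1L)]
        if (orient == "-") w <- COMP_CODE[rev(w)]
        counts[cbind(seq_len(L), w)] <- counts[cbind(seq_len(L), w)] + 1
      }
    }
  }
  if (n_occ == 0L) stop("no occurrences of seed '", iupac_seed, "' found")
  out <- pfm(counts / rowSums(counts), name = paste0("refined_", iupac_seed),
             pseudocount = pseudocount)
  attr(out, "n_occurrences") <- n_occ
  out
}

#' Read a BED file (0-based half-open) as a data.frame
#' @param path BED path; first three columns chrom, start, end; a fourth
#'   column, when present, is returned as `name`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

#' Write intervals as BED (0-based half-open, sorted)
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# hit midpoint inside any interval of df?
midpoint_in <- function(chrom, start0, end0, df) {
  mid <- (start0 + end0) / 2
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    ivs <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(ivs) == 0L) { out[i] <- FALSE; next }
    out[i] <- vapply(mid[i], function(m) any(m >= ivs$start & m < ivs$end),
                     logical(1))
  }
  out
}

#' Split genome-wide motif hits into bound and unbound aligned pools
#'
#' Scans the genome on both strands, keeps hits whose interval lies fully
#' inside an open-chromatin (DNase) interval, classifies each hit as bound
#' when its midpoint falls inside a ChIP-seq peak and unbound otherwise,
#' extracts +/- `flank` bp around the motif (reverse-strand hits
#' reverse-complemented into the motif frame; hits whose window crosses a
#' chromosome end are excluded), and size-matches the two pools.
#'
#' @param genome named character vector of chromosome sequences.
#' @param x a `pfm`.
#' @param peaks,dnase interval data.frames (chrom, start, end; 0-based
#'   half-open).
#' @param bg scanning background; default the genome's mononucleotide
#'   frequencies.
#' @param p_cutoff hit p-value cutoff (default 1e-4).
#' @param flank flank width in bp (default 300, the in vivo window).
#' @param core_exclusion stored on the pools (default 2).
#' @param seed size-matching seed.
#' @param min_pool_size error when either pool ends below this (default 10).
#' @return list: `bound`, `unbound` (`aligned_pool`s with hit coordinates in
#'   `meta`), `counts` (named integer vector of filter tallies).
#' @export
split_bound_unbound <- function(genome, x, peaks, dnase, bg = NULL,
                                p_cutoff = 1e-4, flank = 300L,
                                core_exclusion = 2L, seed = 1L,
                                min_pool_size = 10L) {
  if (is.null(bg)) bg <- background_from_seqs(genome)
  hits <- scan_pfm(x, genome, bg, p_cutoff = p_cutoff, strands = "both")
  counts <- c(hits = nrow(hits))
  if (nrow(hits) == 0L) stop("no motif hits in the genome at p <= ", p_cutoff)
  hits$start <- hits$offset - 1L
  hits$end <- hits$start + x$L
  # fully inside open chromatin
  open <- logical(nrow(hits))
  for (ch in unique(hits$seq_id)) {
    i <- hits$seq_id == ch
    ivs <- dnase[dnase$chrom == ch, , drop = FALSE]
    open[i] <- vapply(which(i), function(k)
      any(hits$start[k] >= ivs$start & hits$end[k] <= ivs$end), logical(1))
  }
  hits <- hits[open, , drop = FALSE]
  counts["in_open_chromatin"] <- nrow(hits)
  bound_flag <- midpoint_in(hits$seq_id, hits$start, hits$end, peaks)
  # flank windows inside the chromosome
  chrom_len <- setNames(nchar(genome), names(genome))
  fits <- hits$start - flank >= 0L & hits$end + flank <= chrom_len[hits$seq_id]
  counts["flank_excluded"] <- sum(!fits)
  hits <- hits[fits, , drop = FALSE]; bound_flag <- bound_flag[fits]
  extract <- function(rows) {
    seqs <- character(nrow(rows))
    for (k in seq_len(nrow(rows))) {
      s <- substr(genome[[rows$seq_id[k]]], rows$start[k] - flank + 1L,
                  rows$end[k] + flank)
      if (rows$strand[k] == "-") s <- revcomp(s)
      seqs[k] <- s
    }
    names(seqs) <- sprintf("%s_%d_%s", rows$seq_id, rows$start, rows$strand)
    seqs
  }
  make <- function(rows, label) {
    seqs <- extract(rows)
    aligned_pool(seqs, label = label, flank_up = flank, flank_down = flank,
                 core_len = x$L, core_exclusion = core_exclusion,
                 meta = data.frame(seq_id = names(seqs), chrom = rows$seq_id,
                                   start = rows$start, end = rows$end,
                                   strand = rows$strand, score = rows$score,
                                   pvalue = rows$pvalue,
                                   stringsAsFactors = FALSE))
  }
  nb <- sum(bound_flag); nu <- sum(!bound_flag)
  counts["bound_hits"] <- nb; counts["unbound_hits"] <- nu
  if (nu == 0L) stop("no unbound motif hits in open chromatin")
  if (nb == 0L) stop("no bound motif hits in open chromatin")
  pools <- match_sizes(make(hits[bound_flag, , drop = FALSE], "bound"),
                       make(hits[!bound_flag, , drop = FALSE], "unbound"),
                       seed = seed)
  if (length(pools[[1]]$seqs) < min_pool_size)
    stop("pools too small after split: ", length(pools[[1]]$seqs))
  list(bound = pools[[1]], unbound = pools[[2]], counts = counts)
}

#' Drop pool records inside GC-extreme promoters
#'
#' Removes records whose motif-hit midpoint lies inside a promoter whose GC
#' content is in the top or bottom `drop_fraction` of the supplied promoter
#' set, a control against promoter-class GC biases.
#'
#' @param pool an `aligned_pool` whose `meta` carries `chrom`, `start`,
#'   `end` (as built by [split_bound_unbound()]).
#' @param promoters data.frame: chrom, start, end, gc.
#' @param drop_fraction decile fraction cut at each extreme (default 0.10).
#' @return the filtered pool; removed count in attribute `n_dropped`.
#' @export
filter_promoter_gc_extremes <- function(pool, promoters = NULL,
                                        drop_fraction = 0.10) {
  if (is.null(promoters) || nrow(promoters) == 0L) {
    attr(pool, "n_dropped") <- 0L
    return(pool)
  }
  qs <- quantile(promoters$gc, c(drop_fraction, 1 - drop_fraction))
  extreme <- promoters[promoters$gc <= qs[[1]] | promoters$gc >= qs[[2]], ,
                       drop = FALSE]
  inside <- midpoint_in(pool$meta$chrom, pool$meta$start, pool$meta$end,
                        extreme)
  keep <- !inside
  dropped <- sum(inside)
  pool$seqs <- pool$seqs[keep]
  pool$meta <- pool$meta[keep, , drop = FALSE]
  if (!is.null(pool$mask)) pool$mask <- pool$mask[keep, , drop = FALSE]
  attr(pool, "n_dropped") <- dropped
  pool
}

# order-insensitive cheap hash of a config for output provenance
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Full run configuration
#'
#' Bundles every threshold and selection of the end-to-end flows; all
#' thresholds are echoed into the run's provenance output.
#'
#' @param mode `"invitro"` or `"invivo"`.
#' @param seed master seed for the run.
#' @param synth a `synthetic_config` for generated inputs.
#' @param strands alignment strand policy (see [align_best_hit()]).
#' @param p_align alignment hit p-value cutoff.
#' @param q_threshold,min_positions preference-call thresholds.
#' @param min_pool_size minimum pool size after alignment.
#' @param flank_up,flank_down analysis window; NULL = widest the probes
#'   support.
#' @param core_exclusion bp excluded next to the core (default 2).
#' @param test,fdr_method positional test and FDR method.
#' @param models list of feature subsets for the regression models.
#' @param folds,n_shuffles CV folds and label shuffles.
#' @param shape_seed seed of the synthetic shape table.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("invitro", "invivo"), seed = 1L,
                       synth = synthetic_config(seed = seed),
                       strands = "auto", p_align = 1e-4,
                       q_threshold = 0.05, min_positions = 5L,
                       min_pool_size = 100L,
                       flank_up = NULL, flank_down = NULL,
                       core_exclusion = 2L,
                       test = "rank_sum", fdr_method = "storey",
                       models = list("gc", "prot", "env", "clusters",
                                     c("gc", "prot"), c("gc", "env"),
                                     c("gc", "clusters"),
                                     c("gc", "prot", "env")),
                       folds = 10L, n_shuffles = 3L, shape_seed = 1L) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed),
                 synth = synth, strands = strands, p_align = p_align,
                 q_threshold = q_threshold, min_positions = min_positions,
                 min_pool_size = min_pool_size,
                 flank_up = flank_up, flank_down = flank_down,
                 core_exclusion = core_exclusion, test = test,
                 fdr_method = fdr_method, models = models, folds = folds,
                 n_shuffles = n_shuffles, shape_seed = shape_seed),
            class = "run_config")
}

#' Run the end-to-end analysis flow
#'
#' In vitro mode: generate probe pools, align them on the best motif hit,
#' size-match, and run the positional GC and propeller-twist comparisons,
#' the homotypic cluster/environment comparison, the regression models with
#' a shuffled-label cutoff, and the three-background HMM scorer. In vivo
#' mode: generate the toy genome, split motif hits into bound/unbound pools
#' by peak membership inside open chromatin, and run the same comparisons.
#' Every output is stamped with the seed and a config hash; sequence counts
#' at every filter are logged.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory; created if needed.
#' @return invisibly, a list with all result objects.
#' @export
run_all <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- cfg$synth$motif
  bg <- background()
  counts <- c()
  if (cfg$mode == "invitro") {
    gen <- generate_pools(cfg$synth)
    counts["generated_bound"] <- length(gen$bound)
    counts["generated_unbound"] <- length(gen$unbound)
    wmax <- with(gen$truth$cores,
                 min(min(offset) - 1L, cfg$synth$probe_len - max(offset + x$L - 1L)))
    fu <- if (is.null(cfg$flank_up)) wmax else cfg$flank_up
    fd <- if (is.null(cfg$flank_down)) wmax else cfg$flank_down
    strands <- cfg$strands
    if (strands == "auto" && cfg$synth$orientation_mix < 1) strands <- "both"
    ab <- align_best_hit(gen$bound, x, bg, p_cutoff = cfg$p_align,
                         strands = strands, flank_up = fu, flank_down = fd,
                         core_exclusion = cfg$core_exclusion,
                         label = "bound", min_pool_size = cfg$min_pool_size)
    au <- align_best_hit(gen$unbound, x, bg, p_cutoff = cfg$p_align,
                         strands = strands, flank_up = fu, flank_down = fd,
                         core_exclusion = cfg$core_exclusion,
                         label = "unbound", min_pool_size = cfg$min_pool_size)
    counts["aligned_bound"] <- length(ab$seqs)
    counts["aligned_unbound"] <- length(au$seqs)
    for (reason in c("no_hit", "tie", "flank")) {
      counts[paste0("discarded_bound_", reason)] <-
        sum(attr(ab, "discarded")$reason == reason)
      counts[paste0("discarded_unbound_", reason)] <-
        sum(attr(au, "discarded")$reason == reason)
    }
  } else {
    geno <- generate_genome(cfg$synth)
    bg <- background_from_seqs(geno$genome)
    sp <- split_bound_unbound(geno$genome, x, geno$peaks, geno$dnase, bg = bg,
                              p_cutoff = cfg$p_align,
                              flank = if (is.null(cfg$flank_up)) 300L else cfg$flank_up,
                              core_exclusion = cfg$core_exclusion,
                              seed = cfg$seed, min_pool_size = cfg$min_pool_size)
    ab <- sp$bound; au <- sp$unbound
    counts <- c(counts, sp$counts)
  }
  matched <- match_sizes(ab, au, seed = cfg$seed)
  pb <- matched[[1]]; pu <- matched[[2]]
  counts["matched_per_pool"] <- length(pb$seqs)

  shape_tab <- synthetic_shape_table(cfg$shape_seed)
  gc_stats <- delta_profile(pb, pu, "GC", test = cfg$test,
                            fdr_method = cfg$fdr_method)
  shape_stats <- compare_shape(pb, pu, shape_tab, test = cfg$test,
                               fdr_method = cfg$fdr_method)
  pref <- call_preference(gc_stats, min_positions = cfg$min_positions,
                          q_threshold = cfg$q_threshold, tf = x$name)

  pv <- exact_pvalues(x, bg)
  hb <- count_clusters(pb, x, bg, pool_u = pu, pv = pv)
  env_cmp <- compare_position(hb$env_score,
                              homotypy_scores(pu, x, bg, pv = pv)$env_score)

  feats_b <- extract_features(pb, x, bg, shape_tab, pv = pv)
  feats_u <- extract_features(pu, x, bg, shape_tab, pv = pv)
  feats <- rbind(feats_b, feats_u)
  labels <- c(rep(1L, nrow(feats_b)), rep(0L, nrow(feats_u)))
  mlr <- NULL; null_cut <- NULL; hmm_res <- NULL
  if (min(table(labels)) >= 2L * cfg$folds) {
    mlr <- lapply(cfg$models, function(fs)
      ridge_cv(feats, labels, fs, folds = cfg$folds, seed = cfg$seed))
    names(mlr) <- vapply(mlr, `[[`, "", "model_name")
    null_cut <- shuffled_null(feats, labels, c("gc", "prot", "env"),
                              n_shuffles = cfg$n_shuffles, folds = cfg$folds,
                              seed = cfg$seed)
    hmm_res <- lapply(c("genomic", "pfm_average", "pfm_inversed"),
                      function(m) hmm_auroc(pb, pu, x, mode = m, bg = bg))
    names(hmm_res) <- c("genomic", "pfm_average", "pfm_inversed")
  }

  # ---- outputs ----
  prov <- list(seed = cfg$seed, config_hash = config_hash(cfg),
               motif = x$name, mode = cfg$mode, counts = as.list(counts))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write_profile_tsv(gc_stats, file.path(out_dir, "gc_profile.tsv"))
  write_profile_tsv(shape_stats, file.path(out_dir, "shape_profile.tsv"))
  write.table(pref, file.path(out_dir, "preference.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(attr(hb, "comparison"), file.path(out_dir, "homotypy_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(env_p_greater = env_cmp[["p_greater"]],
                            env_p_less = env_cmp[["p_less"]]),
                       file.path(out_dir, "env_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(mlr)) {
    jsonlite::write_json(
      lapply(mlr, function(m) list(model = m$model_name,
                                   auroc_mean = m$auroc_mean,
                                   auroc_per_fold = m$auroc_per_fold,
                                   lambda = m$lambda_chosen_per_fold)),
      file.path(out_dir, "mlr_results.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(null_cutoff = null_cut$null_cutoff,
                              null_aurocs = null_cut$null_aurocs),
                         file.path(out_dir, "mlr_null.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(lapply(hmm_res, function(h) h$auroc),
                         file.path(out_dir, "hmm_results.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(bound = pb, unbound = pu, gc_stats = gc_stats,
                 shape_stats = shape_stats, preference = pref,
                 homotypy = hb, env_comparison = env_cmp, mlr = mlr,
                 mlr_null = null_cut, hmm = hmm_res, counts = counts))
}
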