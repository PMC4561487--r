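#' Random PFM with controlled information content and GC composition
#'
#' Each column is a consensus-plus-noise distribution `(1 - e)` on the
#' consensus base and `e/3` on the rest, with `e` solved so the column
#' information content equals `ic_per_column` exactly; consensus identities
#' are drawn so the column-average GC mass comes out within 0.05 of
#' `gc_target`.
#'
#' @param length motif length (positions).
#' @param ic_per_column information content per column in bits (0..2).
#' @param gc_target column-average GC mass target (default 0.5).
#' @param seed RNG seed.
#' @param name motif name.
#' @param pseudocount passed to [pfm()] (default 0: the drawn columns are
#'   already strictly positive unless `ic_per_column = 2`).
#' @return a `pfm`.
#' @export
random_pfm <- function(length, ic_per_column = 1.5, gc_target = 0.5,
                       seed = 1L, name = "synthetic", pseudocount = 0.001) {
  if (ic_per_column < 0 || ic_per_column > 2) stop("ic_per_column must be in [0, 2]")
  # information content of a consensus column with error mass e
  ic_of_e <- function(e) {
    p <- c(1 - e, rep(e / 3, 3))
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }
  e <- if (ic_per_column >= 2) 0 else if (ic_per_column <= 0) 0.75 else
    stats::uniroot(function(e) ic_of_e(e) - ic_per_column,
                   c(1e-9, 0.75), tol = 1e-12)$root
  # per-column GC mass is (1 - 2e/3) for a G/C consensus, 2e/3 for A/T
  gc_hi <- 1 - 2 * e / 3; gc_lo <- 2 * e / 3
  n_gc <- if (gc_hi == gc_lo) 0L else
    round(length * (gc_target - gc_lo) / (gc_hi - gc_lo))
  n_gc <- max(0L, min(length, n_gc))
  with_seed(seed, {
    is_gc <- sample(c(rep(TRUE, n_gc), rep(FALSE, length - n_gc)))
    cons <- ifelse(is_gc, sample(c(2L, 3L), length, replace = TRUE),
                   sample(c(1L, 4L), length, replace = TRUE))
    freq <- matrix(e / 3, length, 4L)
    freq[cbind(seq_len(length), cons)] <- 1 - e
    pfm(freq, name = name, pseudocount = pseudocount)
  })
}

#' Configuration of the synthetic probe-pool generator
#'
#' Defaults emulate the in vitro study conditions: 20-bp probes (the
#' dominant probe length), a 6-bp core motif planted near the probe center
#' (offset uniform over center +/- 1), equal flank GC in both pools, no weak
#' sites and no homotypic flank composition, i.e. the null. Scenario
#' configs override the planted effects.
#'
#' @param seed generator seed; outputs are bit-identical given (config, seed).
#' @param n_bound,n_unbound pool sizes.
#' @param probe_len probe length in bp.
#' @param motif a `pfm`; default `random_pfm(6, 1.5, 0.5, seed)`.
#' @param core_jitter core plant offset is uniform over center +/- this.
#' @param flank_gc_bound,flank_gc_unbound flank GC fractions of each pool.
#' @param weak_motif_rate expected planted off-core weak sites per bound
#'   sequence (Poisson; plants are rejection-sampled from a
#'   temperature-softened PFM until their p-value passes `weak_p`).
#' @param weak_p planting p-value threshold (default 0.001).
#' @param weak_temperature softening temperature (> 1 flattens the PFM).
#' @param homotypic_flank_fraction fraction of bound flank positions drawn
#'   from the PFM column-average base distribution instead of the GC model.
#' @param orientation_mix probability a core plant is forward-oriented.
#' @param weak_orientation_mix same for weak plants.
#' @param genome_len,n_chrom,n_peaks,peak_len,open_len,open_fraction,genome_gc,env_halfwidth
#'   toy-genome parameters for the in vivo path.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_bound = 1000L, n_unbound = 1000L,
                             probe_len = 20L, motif = NULL, core_jitter = 1L,
                             flank_gc_bound = 0.5, flank_gc_unbound = 0.5,
                             weak_motif_rate = 0, weak_p = 0.001,
                             weak_temperature = 1.5,
                             homotypic_flank_fraction = 0,
                             orientation_mix = 1,
                             weak_orientation_mix = 0.5,
                             genome_len = 2e5, n_chrom = 2L, n_peaks = 30L,
                             peak_len = 300L, open_len = 1000L,
                             open_fraction = 0.3, genome_gc = 0.41,
                             env_halfwidth = 50L) {
  if (is.null(motif)) motif <- random_pfm(6L, 1.5, 0.5, seed = seed)
  cfg <- list(seed = as.integer(seed), n_bound = n_bound, n_unbound = n_unbound,
              probe_len = as.integer(probe_len), motif = motif,
              core_jitter = as.integer(core_jitter),
              flank_gc_bound = flank_gc_bound, flank_gc_unbound = flank_gc_unbound,
              weak_motif_rate = weak_motif_rate, weak_p = weak_p,
              weak_temperature = weak_temperature,
              homotypic_flank_fraction = homotypic_flank_fraction,
              orientation_mix = orientation_mix,
              weak_orientation_mix = weak_orientation_mix,
              genome_len = genome_len, n_chrom = as.integer(n_chrom),
              n_peaks = as.integer(n_peaks), peak_len = as.integer(peak_len),
              open_len = as.integer(open_len), open_fraction = open_fraction,
              genome_gc = genome_gc, env_halfwidth = as.integer(env_halfwidth))
  probs <- unlist(cfg[c("flank_gc_bound", "flank_gc_unbound", "weak_p",
                        "homotypic_flank_fraction", "orientation_mix",
                        "weak_orientation_mix", "open_fraction", "genome_gc")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (probe_len < cfg$motif$L + 2L * 3L)
    stop("probe_len too short for the motif plus exclusion flanks")
  structure(cfg, class = "synthetic_config")
}

# one flank base: GC model with probability gc of {G, C}
draw_flank <- function(n, gc) {
  sample(1:4, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# sample a k-mer (codes) from a PFM, optionally temperature-softened
sample_kmer <- function(x, temperature = 1) {
  f <- x$freq
  if (temperature != 1) {
    f <- f^(1 / temperature)
    f <- f / rowSums(f)
  }
  vapply(seq_len(x$L), function(i) sample(1:4, 1L, prob = f[i, ]), 0L)
}

#' Generate bound and unbound probe pools with planted effects
#'
#' Every sequence carries exactly one core-motif plant, sampled base-by-base
#' from the PFM, at a recorded offset and orientation. Bound flank positions
#' are drawn at `flank_gc_bound` (with `homotypic_flank_fraction` of them
#' replaced by draws from the PFM's column-average distribution) and get
#' Poisson(`weak_motif_rate`) weak off-core plants, rejection-sampled from
#' the softened PFM until their exact p-value passes `weak_p`. Unbound
#' flanks are drawn at `flank_gc_unbound` with no plants.
#'
#' @param cfg a `synthetic_config`.
#' @return list of class `synthetic_pools`: `bound`, `unbound` (named
#'   character vectors), `truth` (list: `cores` data.frame with pool, seq_id,
#'   offset, strand; `weak` data.frame with seq_id, offset, strand, kmer),
#'   `cfg`.
#' @export
generate_pools <- function(cfg) {
  x <- cfg$motif; L <- x$L
  center <- (cfg$probe_len - L) %/% 2L + 1L
  offsets_range <- seq.int(max(1L, center - cfg$core_jitter),
                           min(cfg$probe_len - L + 1L, center + cfg$core_jitter))
  pv <- exact_pvalues(x)
  avg_bg <- as.numeric(pfm_average_background(x))
  with_seed(cfg$seed, {
    make_pool <- function(n, gc, label) {
      codes <- matrix(draw_flank(n * cfg$probe_len, gc), n, cfg$probe_len)
      if (label == "bound" && cfg$homotypic_flank_fraction > 0) {
        swap <- matrix(runif(n * cfg$probe_len) < cfg$homotypic_flank_fraction,
                       n, cfg$probe_len)
        repl <- sample(1:4, sum(swap), replace = TRUE, prob = avg_bg)
        codes[swap] <- repl
      }
      offs <- offsets_range[sample.int(length(offsets_range), n, replace = TRUE)]
      strands <- ifelse(runif(n) < cfg$orientation_mix, "+", "-")
      weak_rows <- list()
      for (i in seq_len(n)) {
        km <- sample_kmer(x)
        if (strands[i] == "-") km <- COMP_CODE[rev(km)]
        codes[i, offs[i]:(offs[i] + L - 1L)] <- km
        if (label == "bound" && cfg$weak_motif_rate > 0) {
          k <- rpois(1L, cfg$weak_motif_rate)
          if (k > 0L) {
            core_cols <- offs[i]:(offs[i] + L - 1L)
            starts <- setdiff(seq_len(cfg$probe_len - L + 1L),
                              (offs[i] - L + 1L):(offs[i] + L - 1L))
            starts <- starts[starts >= 1L]
            placed <- integer(0)
            for (s0 in sample(starts)) {
              if (length(placed) >= k) break
              if (any(abs(s0 - placed) < L)) next
              placed <- c(placed, s0)
            }
            for (s0 in placed) {
              repeat {
                wk <- sample_kmer(x, cfg$weak_temperature)
                if (kmer_grid_pvalue(pv, wk) <= cfg$weak_p) break
              }
              wstrand <- if (runif(1) < cfg$weak_orientation_mix) "+" else "-"
              wseq <- if (wstrand == "-") COMP_CODE[rev(wk)] else wk
              codes[i, s0:(s0 + L - 1L)] <- wseq
              weak_rows[[length(weak_rows) + 1L]] <- data.frame(
                seq_id = paste0(label, i), offset = s0, strand = wstrand,
                kmer = codes_to_seq(wk), stringsAsFactors = FALSE)
            }
          }
        }
      }
      seqs <- apply(codes, 1L, codes_to_seq)
      names(seqs) <- paste0(label, seq_len(n))
      list(seqs = seqs,
           cores = data.frame(pool = label, seq_id = names(seqs),
                              offset = offs, strand = strands,
                              stringsAsFactors = FALSE),
           weak = if (length(weak_rows)) do.call(rbind, weak_rows) else
             data.frame(seq_id = character(), offset = integer(),
                        strand = character(), kmer = character(),
                        stringsAsFactors = FALSE))
    }
    b <- make_pool(cfg$n_bound, cfg$flank_gc_bound, "bound")
    u <- make_pool(cfg$n_unbound, cfg$flank_gc_unbound, "unbound")
    structure(list(bound = b$seqs, unbound = u$seqs,
                   truth = list(cores = rbind(b$cores, u$cores),
                                weak = b$weak),
                   cfg = cfg),
              class = "synthetic_pools")
  })
}

#' Aligned pools straight from generator truth
#'
#' Aligns the generated pools on the recorded core plant positions (reverse
#' plants reverse-complemented into the forward frame), bypassing the
#' scanner. The common frame uses the widest symmetric flank window all
#' plants can supply unless `flank_up`/`flank_down` are given.
#'
#' @param gen a `synthetic_pools` object.
#' @param flank_up,flank_down requested flank widths; default the widest
#'   window every plant offset supports.
#' @param core_exclusion stored on the pools (default 2).
#' @return list with elements `bound` and `unbound` (`aligned_pool`s).
#' @export
truth_aligned_pools <- function(gen, flank_up = NULL, flank_down = NULL,
                                core_exclusion = 2L) {
  cfg <- gen$cfg; L <- cfg$motif$L
  cores <- gen$truth$cores
  wmax_up <- min(cores$offset) - 1L
  wmax_down <- cfg$probe_len - max(cores$offset + L - 1L)
  if (is.null(flank_up)) flank_up <- min(wmax_up, wmax_down)
  if (is.null(flank_down)) flank_down <- min(wmax_up, wmax_down)
  one <- function(seqs, label) {
    tr <- cores[cores$pool == label, ]
    tr <- tr[match(names(seqs), tr$seq_id), ]
    out <- character(length(seqs))
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]; o <- tr$offset[i]
      if (tr$strand[i] == "-") {
        s <- revcomp(s)
        o <- nchar(s) - (o + L - 1L) + 1L
      }
      if (o - flank_up < 1L || o + L - 1L + flank_down > nchar(s))
        stop("requested flank window runs off a probe (offset ", o, ")")
      out[i] <- substr(s, o - flank_up, o + L - 1L + flank_down)
    }
    names(out) <- names(seqs)
    aligned_pool(out, label = label, flank_up = flank_up,
                 flank_down = flank_down, core_len = L,
                 core_exclusion = core_exclusion,
                 meta = data.frame(seq_id = names(seqs), strand = tr$strand,
                                   stringsAsFactors = FALSE))
  }
  list(bound = one(gen$bound, "bound"), unbound = one(gen$unbound, "unbound"))
}

#' Write generated pools to FASTA plus a truth JSON
#' @param gen a `synthetic_pools`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pools <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- file.path(dir, "bound.fasta"); pu <- file.path(dir, "unbound.fasta")
  pt <- file.path(dir, "truth.json")
  write_fasta(gen$bound, pb); write_fasta(gen$unbound, pu)
  cfg <- unclass(gen$cfg)
  cfg$motif <- unname(apply(cfg$motif$freq, 1L, c, simplify = FALSE))
  jsonlite::write_json(list(cores = gen$truth$cores, weak = gen$truth$weak,
                            cfg = cfg),
                       pt, auto_unbox = TRUE, digits = NA)
  invisible(c(bound = pb, unbound = pu, truth = pt))
}

#' Read pools written by [write_pools()] back into a `synthetic_pools`
#' @param dir directory holding `bound.fasta`, `unbound.fasta`,
#'   `truth.json`.
#' @return a `synthetic_pools` object (motif reconstructed with its stored
#'   probabilities; pseudocount already applied at generation time).
#' @export
read_pools <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  freq <- truth$cfg$motif
  if (is.list(freq)) freq <- do.call(rbind, freq)
  motif <- pfm(freq, pseudocount = 0)
  cfg <- do.call(synthetic_config,
                 c(truth$cfg[setdiff(names(truth$cfg), "motif")],
                   list(motif = motif)))
  structure(list(bound = read_fasta(file.path(dir, "bound.fasta")),
                 unbound = read_fasta(file.path(dir, "unbound.fasta")),
                 truth = truth[c("cores", "weak")], cfg = cfg),
            class = "synthetic_pools")
}

#' Generate a toy genome with peaks, open chromatin and planted motifs
#'
#' Builds a random-background genome at `genome_gc`, places non-overlapping
#' open-chromatin intervals covering about `open_fraction` of it, puts
#' ChIP-seq-like peaks of `peak_len` bp inside `n_peaks` of those intervals,
#' and plants one motif instance at the center of every open interval:
#' in-peak plants ("bound") get their +/- `env_halfwidth` bp environment
#' rewritten at `flank_gc_bound` with the homotypic fraction, out-of-peak
#' plants ("unbound") at `flank_gc_unbound` without effects.
#'
#' @param cfg a `synthetic_config`.
#' @return list of class `synthetic_genome`: `genome` (named character),
#'   `peaks`, `dnase`, `sites` (data.frames with `chrom`, `start`, `end`,
#'   0-based half-open; `sites` adds `label` and `strand`), `cfg`.
#' @export
generate_genome <- function(cfg) {
  x <- cfg$motif; L <- x$L
  chrom_len <- as.integer(cfg$genome_len / cfg$n_chrom)
  avg_bg <- as.numeric(pfm_average_background(x))
  with_seed(cfg$seed + 1L, {
    n_open_per_chrom <- max(1L, round(cfg$open_fraction * chrom_len / cfg$open_len))
    genome <- list(); peaks <- list(); dnase <- list(); sites <- list()
    peak_quota <- cfg$n_peaks
    for (ch in seq_len(cfg$n_chrom)) {
      chrom <- paste0("chr", ch)
      codes <- draw_flank(chrom_len, cfg$genome_gc)
      # non-overlapping open intervals: equally spaced anchors, jittered
      # within the per-interval slack so any open_fraction up to 1 is exact
      n_open <- min(n_open_per_chrom, chrom_len %/% cfg$open_len)
      spacing <- chrom_len / n_open
      slack <- floor(spacing) - cfg$open_len
      jitter <- if (slack > 0L) sample.int(slack + 1L, n_open, replace = TRUE) - 1L
                else rep(0L, n_open)
      open_start <- as.integer(floor((seq_len(n_open) - 1L) * spacing)) + jitter
      open_end <- open_start + cfg$open_len  # 0-based half-open
      is_peak <- rep(FALSE, n_open)
      n_pk <- min(peak_quota, n_open)
      if (n_pk > 0L) is_peak[sample(n_open, n_pk)] <- TRUE
      peak_quota <- peak_quota - n_pk
      for (k in seq_len(n_open)) {
        mid <- (open_start[k] + open_end[k]) %/% 2L
        m_start <- mid - L %/% 2L  # 0-based
        label <- if (is_peak[k]) "bound" else "unbound"
        gc <- if (is_peak[k]) cfg$flank_gc_bound else cfg$flank_gc_unbound
        env_lo <- max(0L, m_start - cfg$env_halfwidth)
        env_hi <- min(chrom_len, m_start + L + cfg$env_halfwidth)
        env_idx <- (env_lo + 1L):env_hi
        codes[env_idx] <- draw_flank(length(env_idx), gc)
        if (is_peak[k] && cfg$homotypic_flank_fraction > 0) {
          swap <- runif(length(env_idx)) < cfg$homotypic_flank_fraction
          codes[env_idx[swap]] <- sample(1:4, sum(swap), replace = TRUE,
                                         prob = avg_bg)
        }
        km <- sample_kmer(x)
        strand <- if (runif(1) < cfg$orientation_mix) "+" else "-"
        if (strand == "-") km <- COMP_CODE[rev(km)]
        codes[(m_start + 1L):(m_start + L)] <- km
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = chrom, start = m_start, end = m_start + L,
          label = label, strand = strand, stringsAsFactors = FALSE)
        if (is_peak[k]) {
          p_start <- max(open_start[k], mid - cfg$peak_len %/% 2L)
          p_end <- min(open_end[k], p_start + cfg$peak_len)
          peaks[[length(peaks) + 1L]] <- data.frame(
            chrom = chrom, start = p_start, end = p_end,
            stringsAsFactors = FALSE)
        }
      }
      dnase[[length(dnase) + 1L]] <- data.frame(
        chrom = chrom, start = open_start, end = open_end,
        stringsAsFactors = FALSE)
      genome[[chrom]] <- codes_to_seq(codes)
    }
    structure(list(genome = unlist(genome),
                   peaks = do.call(rbind, peaks),
                   dnase = do.call(rbind, dnase),
                   sites = do.call(rbind, sites),
                   cfg = cfg),
              class = "synthetic_genome")
  })
}

#' Synthetic multi-TF motif-site sets with family-coupled peak sharing
#'
#' Generates interval sets of motif sites for several TFs on a toy
#' chromosome. Each family owns a set of shared anchor positions; a
#' same-family TF draws `shared_fraction` of its sites near family anchors
#' (within the co-occupancy window) and the rest uniformly, so same-family
#' pairs end up with more proximal sites than cross-family pairs.
#'
#' @param n_per_family named integer vector: family -> number of TFs.
#' @param n_sites sites per TF.
#' @param genome_len chromosome length (bp).
#' @param site_len motif site width (bp).
#' @param shared_fraction fraction of sites drawn near family anchors.
#' @param seed RNG seed.
#' @return list: `sites` (named list of data.frames per TF), `family_map`.
#' @export
generate_tf_sites <- function(n_per_family = c(famA = 3L, famB = 3L),
                              n_sites = 200L, genome_len = 1e6,
                              site_len = 8L, shared_fraction = 0.5,
                              seed = 1L) {
  with_seed(seed, {
    sites <- list(); fam_map <- character(0)
    for (fam in names(n_per_family)) {
      anchors <- sort(sample.int(genome_len - 1000L, n_sites))
      for (t in seq_len(n_per_family[[fam]])) {
        tf <- paste0(fam, "_tf", t)
        n_shared <- round(shared_fraction * n_sites)
        near <- sample(anchors, n_shared) + sample(50:250, n_shared, replace = TRUE)
        far <- sample.int(genome_len - site_len, n_sites - n_shared)
        start <- sort(c(near, far))
        sites[[tf]] <- data.frame(chrom = "chr1", start = start,
                                  end = start + site_len, tf = tf,
                                  stringsAsFactors = FALSE)
        fam_map[tf] <- fam
      }
    }
    list(sites = sites, family_map = fam_map)
  })
}
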