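#' Study-condition scenario configurations
#'
#' Fixed synthetic-data conditions used by the workflow drivers, the test
#' suite and the acceptance script, so every consumer runs the same study.
#' Effect sizes follow the reported study conditions: a 4-percentage-point
#' flank GC shift (the in vivo average), about three weak off-core sites
#' per bound sequence, and a homotypic flank composition strong enough to
#' discriminate without saturating AUROC at 1.
#'
#' * `scenario_null`: equal flank GC, no plants — the label-shuffle analogue.
#' * `scenario_power`: +4 pp flank GC in the bound pool at n = 5000/pool.
#' * `scenario_homotypic`: GC-rich motif, bound flanks 40% PFM-average
#'   composition; drives the HMM background-mode comparison.
#' * `scenario_mlr`: independent GC (+4 pp) and homotypic (0.25) effects in
#'   80-bp probes; no discrete weak-site plants, so the cluster feature
#'   carries only the signal embedded in the environment.
#' * `scenario_clusters`: Poisson(3) weak off-core plants per bound 80-bp
#'   probe at the 0.001 planting threshold.
#' * `scenario_paperlike`: all three effects together at moderate size, the
#'   end-to-end configuration.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n sequences per pool.
#' @return a `synthetic_config`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_null <- function(seed, n = 400L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = n)
}

#' @rdname scenarios
#' @export
scenario_power <- function(seed, n = 5000L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = n,
                   flank_gc_bound = 0.54, flank_gc_unbound = 0.50)
}

#' @rdname scenarios
#' @export
scenario_homotypic <- function(seed, n = 300L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = n, probe_len = 60L,
                   motif = random_pfm(6L, 1.5, 0.75, seed = seed + 500L),
                   core_jitter = 0L, homotypic_flank_fraction = 0.4)
}

#' @rdname scenarios
#' @export
scenario_mlr <- function(seed, n = 2000L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = n, probe_len = 80L,
                   motif = random_pfm(6L, 1.5, 0.6, seed = seed + 600L),
                   core_jitter = 0L, flank_gc_bound = 0.54,
                   flank_gc_unbound = 0.50, homotypic_flank_fraction = 0.25)
}

#' @rdname scenarios
#' @export
scenario_clusters <- function(seed, n = 1000L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = 50L, probe_len = 80L,
                   core_jitter = 0L, weak_motif_rate = 3)
}

#' @rdname scenarios
#' @export
scenario_paperlike <- function(seed, n = 400L) {
  synthetic_config(seed = seed, n_bound = n, n_unbound = n, probe_len = 80L,
                   flank_gc_bound = 0.54, flank_gc_unbound = 0.50,
                   homotypic_flank_fraction = 0.25, weak_motif_rate = 0.3)
}

#' Environment-model AUROCs for a generated scenario
#'
#' Truth-aligns the pools of a generated scenario, matches motif strength,
#' extracts the four environment features and runs the cross-validated
#' regression for each requested feature subset.
#'
#' @param gen a `synthetic_pools` object.
#' @param models list of feature subsets.
#' @param shape_seed seed of the synthetic shape table.
#' @param folds CV folds.
#' @param seed CV fold/subsampling seed.
#' @return list: `cv` (named list of `cv_result`), `features`, `labels`.
#' @export
run_mlr_models <- function(gen,
                           models = list("gc", "prot", "env", "clusters",
                                         c("gc", "prot"), c("gc", "env"),
                                         c("gc", "clusters"),
                                         c("gc", "prot", "env")),
                           shape_seed = 1L, folds = 10L, seed = 1L) {
  x <- gen$cfg$motif
  bg <- background()
  tp <- truth_aligned_pools(gen)
  matched <- match_motif_strength(tp$bound, tp$unbound, x = x, bg = bg,
                                  seed = seed)
  tab <- synthetic_shape_table(shape_seed)
  pv <- exact_pvalues(x, bg)
  fb <- extract_features(matched[[1]], x, bg, tab, pv = pv)
  fu <- extract_features(matched[[2]], x, bg, tab, pv = pv)
  feats <- rbind(fb, fu)
  labels <- c(rep(1L, nrow(fb)), rep(0L, nrow(fu)))
  cv <- lapply(models, function(fs)
    ridge_cv(feats, labels, fs, folds = folds, seed = seed))
  names(cv) <- vapply(cv, `[[`, "", "model_name")
  list(cv = cv, features = feats, labels = labels)
}

#' HMM background-mode AUROCs for a generated scenario
#'
#' @param gen a `synthetic_pools` object.
#' @param modes background emission modes to score.
#' @return named numeric vector of AUROCs.
#' @export
run_hmm_modes <- function(gen, modes = c("genomic", "pfm_average",
                                         "pfm_inversed")) {
  tp <- truth_aligned_pools(gen)
  vapply(modes, function(m)
    hmm_auroc(tp$bound, tp$unbound, gen$cfg$motif, mode = m)$auroc, 0)
}

#' Align a generated in vitro scenario through the scanning pipeline
#'
#' Runs the production path (best-hit alignment at the study p-cutoff,
#' size matching) rather than truth alignment.
#'
#' @param gen a `synthetic_pools` object.
#' @param p_cutoff alignment p-value cutoff (1e-3: the finest level a 6-bp
#'   motif's discrete p-value grid supports).
#' @param min_pool_size inclusion filter after alignment.
#' @param seed size-matching seed.
#' @return list with `bound` and `unbound` size-matched `aligned_pool`s.
#' @export
align_scenario <- function(gen, p_cutoff = 1e-3, min_pool_size = 0L,
                           seed = 1L) {
  cfg <- gen$cfg
  x <- cfg$motif
  wmax <- with(gen$truth$cores,
               min(min(offset) - 1L, cfg$probe_len - max(offset + x$L - 1L)))
  strands <- if (cfg$orientation_mix < 1) "both" else "forward"
  ab <- align_best_hit(gen$bound, x, p_cutoff = p_cutoff, strands = strands,
                       flank_up = wmax, flank_down = wmax,
                       label = "bound", min_pool_size = min_pool_size)
  au <- align_best_hit(gen$unbound, x, p_cutoff = p_cutoff, strands = strands,
                       flank_up = wmax, flank_down = wmax,
                       label = "unbound", min_pool_size = min_pool_size)
  m <- match_sizes(ab, au, seed = seed)
  list(bound = m[[1]], unbound = m[[2]])
}
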