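#' Planted-effect recovery metrics for one synthetic experiment
#'
#' Runs the full pipeline on a simulated two-condition experiment and scores
#' it against the generator's manifest: sensitivity of remodeled-window
#' calling (fraction of planted remodeled windows with `p_adj <= alpha`),
#' empirical false discovery rate among calls (windows overlapping released
#' RBP sites are excluded from the false-positive count, since their
#' accessibility genuinely changes), and the mean AUROC of the condition-a
#' replicate-averaged reactivity scored against the planted structures of
#' hairpin windows, restricted to positions outside RBP footprints (bound
#' protein masks the structural signal by design).
#'
#' @param config a [sim_config()].
#' @param alpha adjusted-p threshold for remodeled calls.
#' @return list `sensitivity`, `fdr`, `auroc_structure`, `n_remodeled`,
#'   `n_called`, plus the `stats` table.
#' @export
planted_recovery <- function(config, alpha = 0.05) {
  sim <- simulate_experiment(config)
  pl <- run_pipeline(sim, w = config$w)
  man <- sim$truth$manifest
  idx <- match(pl$stats$window_id, man$window_id)
  rem <- man$remodeled[idx]
  ambiguous <- man$released_site_overlap[idx] & !rem
  called <- pl$stats$window_id %in%
    call_remodeled(pl$stats, alpha = alpha)$window_id
  tp <- sum(called & rem)
  fp <- sum(called & !rem & !ambiguous)
  conds <- attr(pl$mat, "samples")$condition
  avg_a <- rowMeans(pl$mat[, conds == "a", drop = FALSE])
  occl <- occlusion_factor(sim$truth, unique(sim$truth$sites$rbp))
  aucs <- c()
  for (wi in which(man$structured)) {
    tx <- sim$truth$transcripts[[man$transcript_id[wi]]]
    memb <- tx$ac_positions[which(tx$membership == man$window_index[wi])]
    free <- occl[[tx$id]][memb + 1L] == 1
    keyi <- match(paste(man$transcript_id[wi], memb, sep = ":"),
                  rownames(pl$mat))
    ok <- free & !is.na(keyi)
    if (sum(ok) < 5) next
    a <- auroc(avg_a[keyi[ok]], tx$pairing[memb[ok] + 1L] == 0)
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  list(sensitivity = mean(called[rem]),
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       auroc_structure = mean(aucs),
       n_remodeled = sum(rem), n_called = sum(called), stats = pl$stats)
}

#' Released-RBP detection for one synthetic experiment
#'
#' Re-runs the pipeline at the RBP footprint window size, maps the planted
#' CLIP sites onto those windows, computes scrambled-null enrichment of
#' significantly changing windows per RBP, and reports whether each planted
#' released RBP is selected as an enriched hit.
#'
#' @param config a [sim_config()].
#' @param w window size for the RBP analysis (default 20 A/C datapoints).
#' @param null_draws scrambles averaged into the null count.
#' @return list `hit` (logical: every released RBP selected as enriched),
#'   `results` (the [rbp_enrichment()] table), `released` (RBP names).
#' @export
released_rbp_hit <- function(config, w = 20, null_draws = 10) {
  sim <- simulate_experiment(config)
  pl <- run_pipeline(sim, w = w)
  targets <- map_sites_to_windows(sim$truth$sites, pl$stats)
  significant <- !is.na(pl$stats$p_adj) & pl$stats$p_adj <= 0.05
  res <- rbp_enrichment(targets, significant, seed = config$seed,
                        null_draws = null_draws)
  hits <- select_rbp_hits(res)
  enriched <- hits$rbp[hits$direction == "enriched"]
  list(hit = all(sim$truth$released_rbps %in% enriched), results = res,
       released = sim$truth$released_rbps)
}

#' Null-calibration summary of the remodeling test
#'
#' Simulates condition pairs from one generative profile per window (no
#' planted effect), applies the within-vs-between correlation t-test and BH
#' correction, and summarizes calibration: the Kolmogorov-Smirnov uniformity
#' p-value of the raw p-values and the `p_adj <= alpha` call rate with its
#' binomial standard error bound.
#'
#' @param n_windows number of null windows.
#' @param seed integer seed.
#' @param n_reps replicates per condition.
#' @param alpha call threshold.
#' @return list `ks_p`, `ks_D`, `call_rate`, `bound` (= alpha + 2 SE),
#'   `p_values`.
#' @export
null_calibration <- function(n_windows = 2000, seed, n_reps = 2,
                             alpha = 0.05) {
  sim <- simulate_window_set(n_windows = n_windows, n_reps = n_reps,
                             effect = 0, seed = seed)
  p <- vapply(sim$mats, function(m) remodeling_test(m, sim$conditions), 0)
  p_ok <- p[!is.na(p)]
  ks <- suppressWarnings(ks.test(p_ok, "punif"))
  p_adj <- bh_adjust(p)
  rate <- mean(p_adj <= alpha, na.rm = TRUE)
  list(ks_p = ks$p.value, ks_D = unname(ks$statistic), call_rate = rate,
       bound = alpha + 2 * sqrt(alpha * (1 - alpha) / length(p_ok)),
       p_values = p)
}
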