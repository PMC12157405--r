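#' Read a CLIP binding-site BED6
#'
#' BED6 intervals (0-based half-open, stranded) with the name field carrying
#' the RBP identifier.
#'
#' @param path BED file path.
#' @return data.frame `contig`, `start`, `end`, `rbp`, `strand` (half-open).
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    rbp = S4Vectors::mcols(gr)$name,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("invalid intervals (start >= end)")
  out
}

#' Map CLIP sites onto windows
#'
#' A window is a target of an RBP when any of that RBP's sites overlaps the
#' window's nucleotide span by at least one base (half-open semantics: a site
#' abutting the span contributes zero overlap and does not count). Strands
#' must match; `.`/`*` sites match either strand.
#'
#' @param sites site table from [read_sites_bed()].
#' @param stats window table from [window_stats()] (uses `transcript_id`,
#'   `span_start`, `span_end`; spans are inclusive of both member positions).
#' @param strand optional strand per window (default `+` for transcript-space
#'   windows).
#' @return logical matrix, windows x RBPs, with `window_id` row names.
#' @export
map_sites_to_windows <- function(sites, stats, strand = NULL) {
  if (!any(sites$contig %in% stats$transcript_id))
    stop("site contigs do not match window transcript ids (coordinate-system mismatch?)")
  if (is.null(strand)) strand <- rep("+", nrow(stats))
  win_gr <- GenomicRanges::GRanges(stats$transcript_id,
                                   IRanges::IRanges(stats$span_start + 1L,
                                                    stats$span_end + 1L),
                                   strand = strand)
  site_gr <- GenomicRanges::GRanges(sites$contig,
                                    IRanges::IRanges(sites$start + 1L, sites$end),
                                    strand = ifelse(sites$strand == ".", "*", sites$strand))
  rbps <- sort(unique(sites$rbp))
  targets <- matrix(FALSE, nrow(stats), length(rbps),
                    dimnames = list(stats$window_id, rbps))
  hits <- GenomicRanges::findOverlaps(win_gr, site_gr, minoverlap = 1L,
                                      ignore.strand = FALSE)
  if (length(hits) > 0)
    targets[cbind(S4Vectors::queryHits(hits),
                  match(sites$rbp[S4Vectors::subjectHits(hits)], rbps))] <- TRUE
  targets
}

#' Scrambled-location null for RBP target labels
#'
#' Builds the null by reassigning each RBP's target-window labels uniformly at
#' random, preserving the per-RBP target count. The randomization is
#' restricted to windows bearing at least one annotated CLIP site of any RBP;
#' CLIP-free windows never receive a null label, so the null controls for
#' CLIP-site density rather than comparing against the whole transcriptome.
#'
#' @param targets logical windows x RBPs matrix from
#'   [map_sites_to_windows()].
#' @param seed integer seed; required for reproducibility.
#' @return logical matrix of the same shape with scrambled labels.
#' @export
scrambled_null <- function(targets, seed) {
  if (missing(seed)) stop("a seed is required")
  eligible <- which(rowSums(targets) > 0)
  out <- targets & FALSE
  set.seed(seed)
  for (r in seq_len(ncol(targets))) {
    k <- sum(targets[, r])
    if (k > length(eligible))
      stop("eligible window set smaller than target count for ",
           colnames(targets)[r])
    out[sample(eligible, k), r] <- TRUE
  }
  out
}

#' RBP enrichment among significantly remodeled windows
#'
#' For each RBP: `k` = significantly changing target windows, `N_t` = target
#' windows, `n_sig` = significantly changing windows in the dataset, `M` =
#' total windows. The fold change divides `k` by the same count under the
#' scrambled-location null (`k_null`, averaged over `null_draws` scrambles);
#' the p-value is hypergeometric in (k, M, n_sig, N_t) — upper-tail
#' `P(X >= k)` when k exceeds its expectation (enrichment), lower-tail
#' otherwise (depletion); the point-mass `P(X = k)` is available via
#' `p_mode = "pmf"`.
#'
#' @param targets logical windows x RBPs matrix.
#' @param significant logical vector per window (e.g. `p_adj <= 0.05` from the
#'   differential step).
#' @param seed seed for the scrambled null.
#' @param null_draws number of scrambles averaged into `k_null` (default 1,
#'   the literal single-scramble null; increase for a stabler fold).
#' @param p_mode `"tail"` (default) or `"pmf"`.
#' @return data.frame, one row per RBP: `rbp`, `k`, `N_t`, `n_sig`, `M`,
#'   `k_null`, `fold`, `log2fc`, `p`, `p_adj` (BH across RBPs), `tail`,
#'   `flag`.
#' @export
rbp_enrichment <- function(targets, significant, seed, null_draws = 1,
                           p_mode = c("tail", "pmf")) {
  p_mode <- match.arg(p_mode)
  if (missing(seed)) stop("a seed is required")
  if (length(significant) != nrow(targets))
    stop("one significance label per window required")
  M <- nrow(targets)
  n_sig <- sum(significant)
  k_null_mat <- vapply(seq_len(null_draws), function(d) {
    null <- scrambled_null(targets, seed = seed + d - 1L)
    colSums(null & significant)
  }, numeric(ncol(targets)))
  k_null <- rowMeans(matrix(k_null_mat, ncol = null_draws))
  res <- lapply(seq_len(ncol(targets)), function(r) {
    N_t <- sum(targets[, r])
    k <- sum(targets[, r] & significant)
    expect <- N_t * n_sig / M
    tail <- if (k >= expect) "enrichment" else "depletion"
    p <- switch(p_mode,
      tail = if (tail == "enrichment")
               phyper(k - 1, n_sig, M - n_sig, N_t, lower.tail = FALSE)
             else phyper(k, n_sig, M - n_sig, N_t),
      pmf = stats::dhyper(k, n_sig, M - n_sig, N_t))
    kn <- k_null[r]
    fold <- if (kn > 0) k / kn else NA_real_
    data.frame(rbp = colnames(targets)[r], k = k, N_t = N_t, n_sig = n_sig,
               M = M, k_null = kn, fold = fold, log2fc = log2(fold), p = p,
               tail = tail,
               flag = if (kn == 0) "null_zero" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Select RBP hits
#'
#' Strict thresholds on the fold change and raw hypergeometric p-value:
#' `|log2fc| > log2fc_min` and `p < p_max`. Enriched and depleted hits are
#' labelled by the `direction` column. BH-adjusted p-values are carried along
#' for reference but selection uses the raw p, matching the screening rule the
#' enrichment analysis was designed around.
#'
#' @param results data.frame from [rbp_enrichment()].
#' @param log2fc_min minimum absolute log2 fold change (exclusive; default
#'   1.1).
#' @param p_max maximum p-value (exclusive; default 0.001).
#' @return subset of `results` with a `direction` column (`enriched` /
#'   `depleted`).
#' @export
select_rbp_hits <- function(results, log2fc_min = 1.1, p_max = 0.001) {
  keep <- !is.na(results$log2fc) & abs(results$log2fc) > log2fc_min &
    results$p < p_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "enriched", "depleted")
  rownames(out) <- NULL
  out
}
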