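#' Call highly structured transcripts / windows by threshold
#'
#' A subject is called structured when its mean within-condition replicate
#' Pearson R and its summary Gini index (Gini of the replicate-averaged
#' reactivity profile) both meet their thresholds; boundaries are inclusive,
#' so a transcript sitting exactly at (R = 0.65, Gini = 0.40) is called at the
#' transcript defaults. Transcript defaults (R >= 0.6, Gini >= 0.4) are looser
#' than window defaults (R >= 0.8, Gini >= 0.5): short local elements must
#' clear a stricter bar. Subjects with missing metrics are excluded (not
#' called) and reported with `passed = NA`.
#'
#' @param stats data.frame from [transcript_stats()] or [window_stats()] with
#'   columns `gini` and `mean_r_within`.
#' @param r_min minimum mean within-condition pairwise Pearson R.
#' @param gini_min minimum summary Gini index.
#' @return the input with logical column `passed` appended (NA when a metric
#'   is missing).
#' @export
call_structured <- function(stats, r_min, gini_min) {
  passed <- stats$mean_r_within >= r_min & stats$gini >= gini_min
  stats$passed <- passed
  stats$r_min <- r_min
  stats$gini_min <- gini_min
  stats
}

#' @rdname call_structured
#' @export
call_structured_transcripts <- function(stats, r_min = 0.6, gini_min = 0.4) {
  call_structured(stats, r_min, gini_min)
}

#' @rdname call_structured
#' @export
call_structured_windows <- function(stats, r_min = 0.8, gini_min = 0.5) {
  call_structured(stats, r_min, gini_min)
}

#' Read a region annotation BED
#'
#' BED intervals (0-based half-open) labelling transcript regions; the BED
#' name field carries the region label (`5UTR`, `CDS`, `3UTR`,
#' `ncRNA-body`). Regions of one transcript must not overlap.
#'
#' @param path BED file path.
#' @return data.frame `transcript_id`, `start`, `end`, `region` (half-open).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    region = S4Vectors::mcols(gr)$name,
    stringsAsFactors = FALSE)
  sp <- split(out, out$transcript_id)
  for (d in sp) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping region annotations for transcript ", d$transcript_id[1])
  }
  out
}

#' Annotate windows with mRNA regions
#'
#' Labels every window with each region its member A/C positions fall into.
#' The primary label is the region containing the majority of member
#' positions; a partial-overlap flag records windows straddling a region
#' boundary. Windows entirely outside the annotation get `"unannotated"`.
#'
#' @param stats window table from [window_stats()] (its `membership` attribute
#'   supplies member positions; alternatively pass `membership`).
#' @param regions region table from [read_regions_bed()] (0-based half-open).
#' @param membership optional data.frame `contig`, `position`, `window_id`.
#' @return `stats` with columns `region` (primary label), `regions_all`
#'   (comma-separated labels) and `partial_overlap` appended.
#' @export
annotate_windows <- function(stats, regions, membership = NULL) {
  if (is.null(membership)) membership <- attr(stats, "membership")
  if (is.null(membership)) stop("window membership table required")
  memb <- membership[!is.na(membership$window_id), , drop = FALSE]
  pos_gr <- GenomicRanges::GRanges(memb$contig,
                                   IRanges::IRanges(memb$position + 1L, width = 1L))
  reg_gr <- GenomicRanges::GRanges(regions$transcript_id,
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(pos_gr, reg_gr)
  lab <- rep("unannotated", nrow(memb))
  lab[S4Vectors::queryHits(hits)] <- regions$region[S4Vectors::subjectHits(hits)]
  tab <- table(memb$window_id, lab)
  primary <- colnames(tab)[max.col(tab, ties.method = "first")]
  names(primary) <- rownames(tab)
  all_lab <- vapply(rownames(tab), function(wid)
    paste(colnames(tab)[tab[wid, ] > 0], collapse = ","), "")
  n_lab <- vapply(rownames(tab), function(wid) sum(tab[wid, ] > 0), 0L)
  idx <- match(stats$window_id, rownames(tab))
  stats$region <- unname(primary[idx])
  stats$regions_all <- unname(all_lab[idx])
  stats$partial_overlap <- unname(n_lab[idx] > 1L)
  stats
}

#' Region enrichment of called windows (hypergeometric test)
#'
#' Given `k` called windows in a region out of `n` called, against `K` windows
#' in the region out of `M` total, reports the fold enrichment
#' `(k/n) / (K/M)` and a hypergeometric p-value: upper tail `P(X >= k)` for
#' enrichment, lower tail `P(X <= k)` for depletion. The point-mass `P(X = k)`
#' is available for strict fidelity to pipelines that evaluate the pmf.
#'
#' @param k called windows carrying the region label.
#' @param K all windows carrying the region label.
#' @param n called windows total.
#' @param M all windows total.
#' @param tail `"enrichment"`, `"depletion"`, or `"pmf"`.
#' @return list `fold`, `p`, `tail`, `flag` (non-empty when K = 0 makes the
#'   fold undefined).
#' @export
region_enrichment <- function(k, K, n, M, tail = c("enrichment", "depletion", "pmf")) {
  tail <- match.arg(tail)
  if (K == 0)
    return(list(fold = NA_real_, p = 1, tail = tail, flag = "empty_region"))
  fold <- (k / n) / (K / M)
  p <- switch(tail,
    enrichment = phyper(k - 1, K, M - K, n, lower.tail = FALSE),
    depletion = phyper(k, K, M - K, n),
    pmf = stats::dhyper(k, K, M - K, n))
  list(fold = fold, p = p, tail = tail, flag = "")
}
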