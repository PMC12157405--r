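#' @importFrom stats cor t.test p.adjust phyper quantile rbinom rbeta rlnorm
#'   runif setNames ks.test
#' @importFrom utils read.delim read.table write.table head combn
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Read a per-base base-call count table
#'
#' Reads the tab-separated pileup summary consumed by the pipeline: one row per
#' reference position with the number of A/C/G/T calls observed on the
#' annotated strand. Lines starting with `#` are treated as comments; the first
#' non-comment line must be a header with at least the columns
#' `contig`, `position`, `strand`, `ref_base`, `A`, `C`, `G`, `T`.
#'
#' Positions are 0-based. Deleted bases and Ns are not part of the four count
#' columns and play no role in mismatch rates (substitutions only).
#'
#' @param path path to the tab-separated counts file.
#' @return a `data.frame` with columns `contig`, `position`, `strand`,
#'   `ref_base`, `A`, `C`, `G`, `T`.
#' @export
read_basecall_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("contig", "position", "strand", "ref_base", VALID_BASES)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("base-call table is missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Write a base-call count table
#'
#' @param counts data.frame as returned by [read_basecall_counts()].
#' @param path output path.
#' @export
write_basecall_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-base base-call counts (0-based positions, strand-resolved)", con)
  suppressWarnings(write.table(counts, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Compute per-base mismatch rates from base-call counts
#'
#' For every position the mismatch count is the number of substitution calls,
#' i.e. total A+C+G+T calls minus calls matching the reference base; the
#' mismatch rate divides by the substitution-informative depth (deletions and
#' Ns are excluded from both numerator and denominator). Positions with zero
#' depth are absent from the output (their rate is undefined, not zero).
#'
#' @param counts data.frame of base-call counts (see [read_basecall_counts()]).
#' @param sample_id sample identifier.
#' @param condition condition label.
#' @param replicate replicate index (>= 1).
#' @param treated logical; `TRUE` for a DMS-treated sample, `FALSE` for the
#'   untreated control.
#' @return a `tram_profile`: a data.frame with columns `contig`, `position`,
#'   `strand`, `ref_base`, `coverage`, `mismatch_count`, `mismatch_rate` and
#'   sample metadata attached as attributes.
#' @export
compute_mismatch_rates <- function(counts, sample_id, condition = "cond",
                                   replicate = 1L, treated = TRUE) {
  bad <- which(!(counts$ref_base %in% VALID_BASES))
  if (length(bad) > 0)
    stop("unknown ref_base at row(s) ", paste(head(bad, 5), collapse = ", "),
         " (contig ", counts$contig[bad[1]], ", position ",
         counts$position[bad[1]], ")")
  cnt <- as.matrix(counts[VALID_BASES])
  neg <- which(rowSums(cnt < 0) > 0)
  if (length(neg) > 0)
    stop("negative base-call count at row(s) ", paste(head(neg, 5), collapse = ", "),
         " (contig ", counts$contig[neg[1]], ", position ",
         counts$position[neg[1]], ")")
  coverage <- rowSums(cnt)
  ref_calls <- cnt[cbind(seq_len(nrow(cnt)), match(counts$ref_base, VALID_BASES))]
  keep <- coverage > 0
  prof <- data.frame(
    contig = counts$contig[keep],
    position = counts$position[keep],
    strand = counts$strand[keep],
    ref_base = counts$ref_base[keep],
    coverage = as.integer(coverage[keep]),
    mismatch_count = as.integer(coverage[keep] - ref_calls[keep]),
    stringsAsFactors = FALSE
  )
  prof$mismatch_rate <- prof$mismatch_count / prof$coverage
  ord <- order(prof$contig, prof$position)
  prof <- prof[ord, , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof,
            class = c("tram_profile", "data.frame"),
            sample_id = sample_id, condition = condition,
            replicate = as.integer(replicate), treated = isTRUE(treated))
}

#' @export
print.tram_profile <- function(x, ...) {
  cat(sprintf("<tram_profile> %s (%s, rep %d, %s): %d positions on %d contig(s)\n",
              attr(x, "sample_id"), attr(x, "condition"), attr(x, "replicate"),
              if (attr(x, "treated")) "DMS" else "control",
              nrow(x), length(unique(x$contig))))
  invisible(x)
}

#' Write / read a mutational profile TSV
#'
#' The profile TSV stores one row per covered reference position with a
#' `#`-prefixed metadata header carrying the sample annotation, so that a
#' written profile re-reads to an identical object (rates are serialized at
#' full double precision).
#'
#' @param profile a `tram_profile`.
#' @param path file path.
#' @return `write_profile` returns the path invisibly; `read_profile` returns
#'   a `tram_profile`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample_id=%s\tcondition=%s\treplicate=%d\ttreated=%s",
                     attr(profile, "sample_id"), attr(profile, "condition"),
                     attr(profile, "replicate"), attr(profile, "treated")), con)
  df <- as.data.frame(profile)
  df$mismatch_rate <- sprintf("%.17g", df$mismatch_rate)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    stop("profile TSV must start with a '#' metadata line: ", path)
  meta <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  meta <- setNames(kv[, 2], kv[, 1])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(mismatch_rate = "numeric"))
  structure(df,
            class = c("tram_profile", "data.frame"),
            sample_id = unname(meta["sample_id"]),
            condition = unname(meta["condition"]),
            replicate = as.integer(meta["replicate"]),
            treated = as.logical(meta["treated"]))
}

pos_key <- function(contig, position) paste(contig, position, sep = ":")

#' Intersection coverage filter across samples
#'
#' Keeps exactly the positions whose coverage is at least `min_coverage` in
#' *every* supplied profile (DMS and control alike); the boundary is inclusive
#' ("at least"). Positions absent from any profile are dropped.
#'
#' @param profiles a list of `tram_profile` objects on one coordinate system.
#' @param min_coverage minimum per-sample read depth (default 100).
#' @return a data.frame with columns `contig`, `position` of retained
#'   positions, ordered by contig then position.
#' @export
coverage_mask <- function(profiles, min_coverage = 100) {
  if (length(profiles) == 0) stop("empty profile set")
  keys <- lapply(profiles, function(p)
    pos_key(p$contig, p$position)[p$coverage >= min_coverage])
  keep <- Reduce(intersect, keys)
  ref <- profiles[[1]]
  idx <- match(keep, pos_key(ref$contig, ref$position))
  out <- data.frame(contig = ref$contig[idx], position = ref$position[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a reference base an adenine/cytosine on its annotated strand?
#'
#' Base-call tables are assumed strand-resolved upstream; on the minus strand
#' the recorded reference base is complemented before the A/C test, so a
#' genomic T (transcribed A) counts as DMS-informative.
#' @keywords internal
is_ac_base <- function(ref_base, strand) {
  ifelse(strand == "-", ref_base %in% c("T", "G"), ref_base %in% c("A", "C"))
}

#' Control-subtract a DMS profile into a reactivity profile
#'
#' Subtracts the paired untreated control's mismatch rate from the DMS-treated
#' sample's rate at every masked position, floors the result at zero, and
#' restricts to A/C reference bases (DMS methylates the Watson-Crick face of
#' unpaired A and C). Pairing is by (condition, replicate): each DMS replicate
#' has its own control.
#'
#' @param dms `tram_profile`, treated sample.
#' @param control `tram_profile`, untreated sample from the same condition and
#'   replicate.
#' @param mask position mask from [coverage_mask()].
#' @param strand_aware complement the ref base on `-` strand before the A/C
#'   test (default `TRUE`).
#' @return a `tram_reactivity`: data.frame with `contig`, `position`, `strand`,
#'   `ref_base`, `reactivity` (>= 0) and source sample ids as attributes.
#' @export
normalize_control <- function(dms, control, mask, strand_aware = TRUE) {
  if (!isTRUE(attr(dms, "treated")) || isTRUE(attr(control, "treated")))
    stop("normalize_control() expects a treated 'dms' and an untreated 'control'")
  if (!identical(attr(dms, "condition"), attr(control, "condition")) ||
      !identical(attr(dms, "replicate"), attr(control, "replicate")))
    stop("replicate pairing mismatch: dms is (", attr(dms, "condition"), ", rep ",
         attr(dms, "replicate"), ") but control is (", attr(control, "condition"),
         ", rep ", attr(control, "replicate"), ")")
  mk <- pos_key(mask$contig, mask$position)
  di <- match(mk, pos_key(dms$contig, dms$position))
  ci <- match(mk, pos_key(control$contig, control$position))
  ok <- !is.na(di) & !is.na(ci)
  di <- di[ok]; ci <- ci[ok]
  ac <- if (strand_aware) is_ac_base(dms$ref_base[di], dms$strand[di])
        else dms$ref_base[di] %in% c("A", "C")
  di2 <- di[ac]; ci2 <- ci[ac]
  out <- data.frame(
    contig = dms$contig[di2], position = dms$position[di2],
    strand = dms$strand[di2], ref_base = dms$ref_base[di2],
    reactivity = pmax(0, dms$mismatch_rate[di2] - control$mismatch_rate[ci2]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("tram_reactivity", "data.frame"),
            sample_id = attr(dms, "sample_id"),
            condition = attr(dms, "condition"),
            replicate = attr(dms, "replicate"),
            source = c(dms = attr(dms, "sample_id"),
                       control = attr(control, "sample_id")))
}

#' Join reactivity profiles into a replicate-aligned matrix
#'
#' All profiles must cover the identical (post-mask) position set; differing
#' sets indicate the intersection filter was not applied consistently and are
#' an error rather than silently intersected again.
#'
#' @param profiles list of `tram_reactivity` objects.
#' @return a numeric matrix, positions x samples, with `contig:position` row
#'   names; position metadata in `attr(, "positions")` and per-column sample
#'   metadata in `attr(, "samples")` (`sample_id`, `condition`, `replicate`).
#' @export
join_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile set")
  keys <- lapply(profiles, function(p) pos_key(p$contig, p$position))
  for (k in keys) if (!identical(k, keys[[1]]))
    stop("reactivity profiles cover different position sets; re-run the coverage filter")
  mat <- do.call(cbind, lapply(profiles, function(p) p$reactivity))
  rownames(mat) <- keys[[1]]
  colnames(mat) <- vapply(profiles, function(p) attr(p, "sample_id"), "")
  attr(mat, "positions") <- profiles[[1]][c("contig", "position", "strand", "ref_base")]
  attr(mat, "samples") <- data.frame(
    sample_id = colnames(mat),
    condition = vapply(profiles, function(p) attr(p, "condition"), ""),
    replicate = vapply(profiles, function(p) attr(p, "replicate"), 1L),
    stringsAsFactors = FALSE)
  mat
}

#' Percentage / per-kilobase reporting helpers
#'
#' Small formatting helpers used when summarizing call tables: `pct_of()`
#' reports `100 * k / n` rounded to `digits`; `per_kilobase()` converts a count
#' observed over `span_nt` nucleotides to a per-kilobase rate.
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal digits to round to.
#' @export
pct_of <- function(k, n, digits = 1) round(100 * k / n, digits)

#' @rdname pct_of
#' @param count events observed.
#' @param span_nt nucleotides over which they were observed.
#' @export
per_kilobase <- function(count, span_nt, digits = 1) round(count * 1000 / span_nt, digits)
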