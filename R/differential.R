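#' Per-window delta statistic: average bidirectional reactivity change
#'
#' `delta = (1 / (N * n_reps)) * sum_i sum_k |r_a[i,k] - r_b[i,k]|` over the
#' `N` A/C positions of a window and the index-matched replicate pairs
#' (replicate k of condition a pairs with replicate k of condition b). The
#' absolute value makes the score bidirectional: it captures local remodeling
#' even when increases and decreases cancel on net.
#'
#' @param ra,rb numeric matrices (positions x replicates) of reactivities for
#'   the two conditions; equal dimensions required.
#' @param pairing `"indexed"` (default, replicate k vs replicate k, as the
#'   shared replicate index in the definition implies) or `"all"` to average
#'   over every cross-condition replicate pair.
#' @return non-negative scalar, symmetric in (a, b).
#' @export
delta_score <- function(ra, rb, pairing = c("indexed", "all")) {
  pairing <- match.arg(pairing)
  ra <- as.matrix(ra); rb <- as.matrix(rb)
  if (nrow(ra) != nrow(rb)) stop("condition matrices must share positions")
  if (pairing == "indexed") {
    if (ncol(ra) != ncol(rb))
      stop("unequal replicate counts: ", ncol(ra), " vs ", ncol(rb),
           " (no implicit pairing)")
    mean(abs(ra - rb))
  } else {
    mean(vapply(seq_len(ncol(ra)), function(i)
      mean(vapply(seq_len(ncol(rb)), function(j)
        mean(abs(ra[, i] - rb[, j])), 0)), 0))
  }
}

#' Signed mean accessibility change
#'
#' Same averaging as [delta_score()] but without the absolute value:
#' `(1 / (N * n_reps)) * sum_i sum_k (r_b[i,k] - r_a[i,k])`. Negative values
#' indicate reduced accessibility (more structure) in condition b. By the
#' triangle inequality `|directional_change| <= delta` always.
#'
#' @inheritParams delta_score
#' @export
directional_change <- function(ra, rb) {
  ra <- as.matrix(ra); rb <- as.matrix(rb)
  if (nrow(ra) != nrow(rb)) stop("condition matrices must share positions")
  if (ncol(ra) != ncol(rb))
    stop("unequal replicate counts: ", ncol(ra), " vs ", ncol(rb))
  mean(rb - ra)
}

#' Remodeling significance test on correlation sets
#'
#' Compares the within-condition pairwise Pearson R values against the
#' between-condition pairwise R values with a two-sided independent two-sample
#' t-test (Student's pooled-variance form by default). A significant p-value
#' indicates that the between-condition disagreement exceeds ordinary
#' replicate-to-replicate variability, i.e. a reproducible, condition-specific
#' change in the accessibility profile.
#'
#' Degenerate zero-variance sets are resolved deterministically: identical
#' constant sets give p = 1, different constant means give p = 0 (both flagged
#' by returning an attribute rather than an error, since planted simulations
#' can produce them).
#'
#' @param mat reactivity matrix (positions x samples) for one window.
#' @param conditions condition label per column (exactly 2 distinct).
#' @param welch use the Welch (unequal-variance) variant.
#' @return p-value in \[0, 1\], or `NA_real_` when either set has fewer than 2
#'   non-missing values.
#' @export
remodeling_test <- function(mat, conditions, welch = FALSE) {
  rc <- replicate_correlations(mat, conditions)
  remodeling_test_sets(rc$r_within, rc$r_between, welch = welch)
}

#' @rdname remodeling_test
#' @param r_within,r_between pairwise Pearson R sets computed elsewhere.
#' @export
remodeling_test_sets <- function(r_within, r_between, welch = FALSE) {
  rw <- r_within[!is.na(r_within)]
  rb <- r_between[!is.na(r_between)]
  if (length(rw) < 2 || length(rb) < 2) return(NA_real_)
  vw <- stats::var(rw); vb <- stats::var(rb)
  if (vw == 0 && vb == 0)
    return(if (isTRUE(all.equal(mean(rw), mean(rb)))) 1 else 0)
  t.test(rw, rb, var.equal = !welch)$p.value
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Standard step-up false-discovery-rate correction; missing p-values are
#' excluded from the ranking (they do not count toward m) and re-inserted as
#' missing.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call remodeled windows
#'
#' Selects windows with `p_adj <= alpha` (boundary inclusive) and
#' `delta >= delta_min`, ranked by decreasing delta; `top_k` optionally keeps
#' only the strongest changes (e.g. a top-100 list for condition-fit
#' comparison).
#'
#' @param stats window table from [window_stats()] with `delta` and `p_adj`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param delta_min minimum delta (default 0).
#' @param top_k optional cap on the number of returned windows.
#' @return the subset of `stats` that is called, ordered by decreasing delta.
#' @export
call_remodeled <- function(stats, alpha = 0.05, delta_min = 0, top_k = NULL) {
  keep <- !is.na(stats$p_adj) & stats$p_adj <= alpha &
    !is.na(stats$delta) & stats$delta >= delta_min
  out <- stats[keep, , drop = FALSE]
  out <- out[order(-out$delta), , drop = FALSE]
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}
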