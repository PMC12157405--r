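#' Segment filtered A/C positions into fixed-count windows
#'
#' Splits the ordered, filtered A/C positions of one transcript into
#' consecutive non-overlapping windows of exactly `w` datapoints; a trailing
#' remainder of fewer than `w` positions is discarded so that every window's
#' Gini and correlation values are computed over the same number of points.
#' Window size is counted in A/C datapoints, not nucleotides, so the
#' nucleotide span of a window varies with local A/C density.
#'
#' @param positions sorted integer vector of filtered A/C coordinates for one
#'   transcript.
#' @param w window size in A/C datapoints (>= 2; 50 for structure discovery,
#'   20 for RBP footprint analysis).
#' @param transcript_id identifier used in the output table.
#' @return list with `windows` (data.frame: `transcript_id`, `window_index`,
#'   `span_start`, `span_end`, `n_ac`) and `membership` (integer vector
#'   parallel to `positions`: the window index of each position, `NA` for the
#'   dropped remainder).
#' @export
segment_windows <- function(positions, w = 50, transcript_id = "tx") {
  if (w < 2) stop("window size must be >= 2 A/C datapoints")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing within a transcript")
  n <- length(positions)
  k <- n %/% w
  membership <- rep(NA_integer_, n)
  if (k > 0) membership[seq_len(k * w)] <- rep(seq_len(k), each = w)
  windows <- data.frame(
    transcript_id = rep(transcript_id, k),
    window_index = seq_len(k),
    span_start = positions[(seq_len(k) - 1) * w + 1],
    span_end = positions[seq_len(k) * w],
    n_ac = rep(as.integer(w), k),
    stringsAsFactors = FALSE)
  list(windows = windows, membership = membership)
}

#' Gini index of a reactivity vector
#'
#' Half the relative mean absolute difference,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the sorted-vector
#' identity in O(n log n). High values indicate a mix of protected and exposed
#' bases, a signature of defined structure; a flat accessibility profile gives
#' 0. The maximum for n points is `(n-1)/n` (all signal at one position).
#'
#' @param x non-negative numeric vector, length >= 2.
#' @param unbiased apply the small-sample `n/(n-1)` correction (default
#'   `FALSE`: the plain population form, which the calling thresholds are
#'   calibrated against).
#' @return the Gini coefficient, or `NA_real_` for an all-zero vector (the
#'   index is undefined; such windows are flagged uninformative downstream).
#' @export
gini <- function(x, unbiased = FALSE) {
  if (length(x) < 2) stop("gini requires at least 2 values")
  if (anyNA(x)) return(NA_real_)
  if (any(x < 0)) stop("gini requires non-negative values")
  n <- length(x)
  s <- sum(x)
  if (s == 0) return(NA_real_)
  xs <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
  if (unbiased) g <- g * n / (n - 1)
  g
}

cor_pairs <- function(mat, idx_a, idx_b = NULL) {
  # pairwise Pearson R; zero-variance columns yield NA (correlation undefined)
  out <- c()
  if (is.null(idx_b)) {
    if (length(idx_a) >= 2) {
      cb <- combn(idx_a, 2)
      out <- vapply(seq_len(ncol(cb)), function(j)
        safe_cor(mat[, cb[1, j]], mat[, cb[2, j]]), 0)
      names(out) <- apply(cb, 2, paste, collapse = "~")
    }
  } else {
    grid <- expand.grid(a = idx_a, b = idx_b)
    out <- vapply(seq_len(nrow(grid)), function(j)
      safe_cor(mat[, grid$a[j]], mat[, grid$b[j]]), 0)
    names(out) <- paste(grid$a, grid$b, sep = "~")
  }
  out
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Pairwise replicate correlations within and between conditions
#'
#' Pearson R for every within-condition replicate pair and every
#' between-condition pair. Zero-variance columns give missing R values, which
#' are excluded from the means; if every pair is missing the means are `NA`
#' and the window should be flagged.
#'
#' @param mat numeric matrix, positions x samples (>= 3 positions).
#' @param conditions character vector of condition labels, one per column.
#' @return list with `r_within`, `r_between` (named numeric vectors),
#'   `mean_r_within`, `mean_r_between`.
#' @export
replicate_correlations <- function(mat, conditions) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (nrow(mat) < 3) stop("need at least 3 positions")
  if (length(conditions) != ncol(mat))
    stop("one condition label per column required")
  conds <- unique(conditions)
  r_within <- c()
  for (cc in conds)
    r_within <- c(r_within, cor_pairs(mat, which(conditions == cc)))
  r_between <- c()
  if (length(conds) == 2)
    r_between <- cor_pairs(mat, which(conditions == conds[1]),
                           which(conditions == conds[2]))
  mw <- if (all(is.na(r_within))) NA_real_ else mean(r_within, na.rm = TRUE)
  mb <- if (length(r_between) == 0 || all(is.na(r_between))) NA_real_
        else mean(r_between, na.rm = TRUE)
  list(r_within = r_within, r_between = r_between,
       mean_r_within = mw, mean_r_between = mb)
}

#' Per-window summary statistics
#'
#' Segments each transcript of a replicate-aligned reactivity matrix into
#' fixed-count A/C windows and computes, per window: the mean reactivity, the
#' Gini index of the replicate-averaged profile (the summary Gini used for
#' structure calls), the mean per-replicate Gini, and the mean pairwise
#' within- and between-condition Pearson correlations. With two conditions the
#' differential columns (`delta`, `dir_change`, `p_value`, `p_adj`) are filled
#' in via [delta_score()], [directional_change()], [remodeling_test()] and
#' [bh_adjust()]; with one condition they are `NA`.
#'
#' @param mat reactivity matrix from [join_profiles()], or any numeric matrix
#'   accompanied by `positions`.
#' @param conditions condition label per column (default: taken from the
#'   matrix's sample metadata).
#' @param w window size in A/C datapoints.
#' @param positions optional data.frame with `contig`, `position` describing
#'   the rows (default: taken from the matrix attributes).
#' @return a `data.frame` of per-window statistics, plus a `membership`
#'   attribute (data.frame `contig`, `position`, `window_id` for every matrix
#'   row; `NA` window for dropped remainders).
#' @export
window_stats <- function(mat, conditions = NULL, w = 50, positions = NULL) {
  if (is.null(positions)) positions <- attr(mat, "positions")
  if (is.null(positions)) stop("position metadata required")
  if (is.null(conditions)) {
    smp <- attr(mat, "samples")
    if (is.null(smp)) stop("condition labels required")
    conditions <- smp$condition
  }
  conds <- unique(conditions)
  two_cond <- length(conds) == 2
  win_list <- list()
  memb_all <- rep(NA_character_, nrow(mat))
  for (tx in unique(positions$contig)) {
    rows <- which(positions$contig == tx)
    seg <- segment_windows(positions$position[rows], w = w, transcript_id = tx)
    if (nrow(seg$windows) == 0) next
    wid <- paste(tx, seg$windows$window_index, sep = "#")
    memb_all[rows] <- ifelse(is.na(seg$membership), NA_character_,
                             paste(tx, seg$membership, sep = "#"))
    for (j in seq_len(nrow(seg$windows))) {
      sub <- mat[rows[which(seg$membership == j)], , drop = FALSE]
      rc <- replicate_correlations(sub, conditions)
      avg_prof <- rowMeans(sub)
      g_sum <- gini(avg_prof)
      g_rep <- vapply(seq_len(ncol(sub)), function(cix) gini(sub[, cix]), 0)
      st <- seg$windows[j, ]
      row <- data.frame(
        window_id = wid[j], transcript_id = tx,
        window_index = st$window_index,
        span_start = st$span_start, span_end = st$span_end, n_ac = st$n_ac,
        mean_rate = mean(sub),
        gini = g_sum, gini_rep_mean = mean(g_rep, na.rm = TRUE),
        mean_r_within = rc$mean_r_within, mean_r_between = rc$mean_r_between,
        delta = NA_real_, dir_change = NA_real_, p_value = NA_real_,
        flag = if (all(avg_prof == 0)) "all_zero"
               else if (all(is.na(rc$r_within))) "no_valid_pairs" else "",
        stringsAsFactors = FALSE)
      if (two_cond) {
        a <- sub[, conditions == conds[1], drop = FALSE]
        b <- sub[, conditions == conds[2], drop = FALSE]
        if (ncol(a) == ncol(b)) {
          row$delta <- delta_score(a, b)
          row$dir_change <- directional_change(a, b)
        }
        row$p_value <- remodeling_test_sets(rc$r_within, rc$r_between)
      }
      win_list[[wid[j]]] <- row
    }
  }
  out <- do.call(rbind, win_list)
  rownames(out) <- NULL
  if (!is.null(out) && two_cond) out$p_adj <- bh_adjust(out$p_value)
  else if (!is.null(out)) out$p_adj <- NA_real_
  attr(out, "membership") <- data.frame(
    contig = positions$contig, position = positions$position,
    window_id = memb_all, stringsAsFactors = FALSE)
  attr(out, "w") <- w
  out
}

#' Per-transcript summary statistics
#'
#' Transcript-level analogue of [window_stats()], computed over all filtered
#' A/C positions of each transcript: mean reactivity, summary Gini (Gini of
#' the replicate-averaged reactivity vector; per-replicate mean also
#' reported), and mean pairwise within-condition Pearson R.
#'
#' @inheritParams window_stats
#' @return data.frame with one row per transcript.
#' @export
transcript_stats <- function(mat, conditions = NULL, positions = NULL) {
  if (is.null(positions)) positions <- attr(mat, "positions")
  if (is.null(conditions)) {
    smp <- attr(mat, "samples")
    if (is.null(smp)) stop("condition labels required")
    conditions <- smp$condition
  }
  res <- lapply(unique(positions$contig), function(tx) {
    sub <- mat[positions$contig == tx, , drop = FALSE]
    if (nrow(sub) < 3) return(NULL)
    rc <- replicate_correlations(sub, conditions)
    g_rep <- vapply(seq_len(ncol(sub)), function(cix) gini(sub[, cix]), 0)
    data.frame(transcript_id = tx, n_ac = nrow(sub), mean_rate = mean(sub),
               gini = gini(rowMeans(sub)), gini_rep_mean = mean(g_rep, na.rm = TRUE),
               mean_r_within = rc$mean_r_within,
               mean_r_between = rc$mean_r_between,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a window statistics table
#'
#' @param stats data.frame from [window_stats()].
#' @param path output TSV path.
#' @export
write_window_stats <- function(stats, path) {
  suppressWarnings(write.table(stats, path, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
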