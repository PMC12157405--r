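DNA <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults chosen to
#' emulate a desk-scale mutational-profiling experiment: a small transcriptome
#' at deep, expression-driven coverage, DMS-selective A/C signal whose
#' strength depends on planted pairing status, untreated-control background,
#' replicate-level noise so within-condition correlations are realistically
#' below 1, and condition-b perturbations (window remodeling, RBP-site
#' release). All randomness is seeded; `seed` is mandatory.
#'
#' Default reactivity regime: unpaired A/C modification probabilities are
#' Beta(2, 38) (mean 0.05), paired A/C Beta(2, 398) (mean 0.005), G/T and
#' control background 0.002 — i.e. mismatch rates well below 1 and on the
#' order of a dozen modifications per kilobase, the regime mutational
#' profiling operates in.
#'
#' @param seed integer seed (required).
#' @param n_transcripts number of transcripts.
#' @param length_mean,length_sd transcript length distribution (nt; minimum
#'   500 enforced).
#' @param gc GC content of generated sequence.
#' @param utr5_frac,cds_frac fractions of each transcript annotated 5UTR /
#'   CDS (remainder is 3UTR).
#' @param coverage_meanlog,coverage_sdlog lognormal read-depth distribution,
#'   drawn once per transcript and constant along it.
#' @param n_replicates replicates per condition.
#' @param p_hairpin probability that a ~`segment_len` segment carries a
#'   planted stem-loop, per region (named vector `5UTR`, `CDS`, `3UTR`).
#' @param segment_len length of the alternating structured/loose segments
#'   (nt).
#' @param loop_len hairpin loop length (nt).
#' @param unpaired_shape,paired_shape Beta shape pairs (length-2 vectors) for
#'   unpaired / paired A/C modification probabilities.
#' @param gu_rate modification probability at G/T reference bases.
#' @param control_error background mismatch probability without treatment.
#' @param rep_noise_sdlog sdlog of the per-position per-replicate lognormal
#'   multiplier on modification probability.
#' @param w window size (A/C datapoints) used for planting and the manifest.
#' @param frac_remodeled fraction of windows remodeled in condition b.
#' @param flip_frac fraction of a remodeled window's A/C positions whose
#'   pairing status flips.
#' @param n_rbps,sites_per_rbp,site_width RBP site planting.
#' @param occlusion fractional reduction of modification probability under a
#'   bound RBP site (0 = no footprint, 1 = fully protected).
#' @param released_rbps number of RBPs whose occlusion is lifted in condition
#'   b (the planted "dissociating" RBPs, taken from the start of the RBP
#'   list).
#' @return a `tram_sim_config` list.
#' @export
sim_config <- function(seed,
                       n_transcripts = 20, length_mean = 1000, length_sd = 150,
                       gc = 0.5, utr5_frac = 0.15, cds_frac = 0.5,
                       coverage_meanlog = log(2000), coverage_sdlog = 0.25,
                       n_replicates = 2,
                       p_hairpin = c("5UTR" = 0.05, "CDS" = 0.05, "3UTR" = 0.45),
                       segment_len = 120, loop_len = 8,
                       unpaired_shape = c(2, 38), paired_shape = c(2, 398),
                       gu_rate = 0.002, control_error = 0.002,
                       rep_noise_sdlog = 0.2,
                       w = 50, frac_remodeled = 0.15, flip_frac = 0.5,
                       n_rbps = 8, sites_per_rbp = 20, site_width = 30,
                       occlusion = 0.9, released_rbps = 1) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  up_mean <- unpaired_shape[1] / sum(unpaired_shape)
  p_mean <- paired_shape[1] / sum(paired_shape)
  if (!(up_mean > p_mean && p_mean > 0))
    stop("unpaired mean rate must exceed paired mean rate, both positive")
  if (occlusion < 0 || occlusion > 1) stop("occlusion factor must be in [0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "tram_sim_config")
}

rand_bases <- function(n, gc) {
  sample(DNA, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

revcomp <- function(bases) rev(unname(DNA_COMP[bases]))

#' Generate ground truth: sequences, planted structures, regions, RBP sites
#'
#' Builds the synthetic transcriptome deterministically from the config seed.
#' Each transcript is partitioned into 5UTR/CDS/3UTR regions and tiled with
#' segments that either carry an explicit stem-loop (complementary arms, so
#' the planted structure is also sequence-foldable) or are unstructured.
#' Filtered-A/C windows are pre-computed so effects can be planted on exactly
#' the windows the pipeline will see; per-position baseline modification
#' probabilities are drawn by pairing status; RBP sites are placed uniformly
#' and annotated with their occlusion.
#'
#' @param config a [sim_config()].
#' @return a `tram_truth` list: per-transcript sequence / pairing / regions /
#'   coverage / A/C positions / baseline probabilities, a window manifest
#'   (with `paired_frac`, `structured`, `unstructured` flags), and the RBP
#'   site table.
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  txs <- list()
  for (t in seq_len(config$n_transcripts)) {
    id <- sprintf("tx%02d", t)
    L <- max(500L, as.integer(round(stats::rnorm(1, config$length_mean,
                                                 config$length_sd))))
    u5 <- as.integer(floor(config$utr5_frac * L))
    cds <- as.integer(floor(config$cds_frac * L))
    regions <- data.frame(
      transcript_id = id,
      start = c(0L, u5, u5 + cds),
      end = c(u5, u5 + cds, L),
      region = c("5UTR", "CDS", "3UTR"),
      stringsAsFactors = FALSE)
    bases <- character(L)
    pairing <- integer(L)
    pos <- 0L
    while (pos < L) {
      seg_len <- min(config$segment_len, L - pos)
      reg <- regions$region[findInterval(pos, regions$start)]
      is_hp <- stats::runif(1) < config$p_hairpin[[reg]] &&
        seg_len >= config$loop_len + 10L
      if (is_hp) {
        stem <- (seg_len - config$loop_len) %/% 2L
        left <- rand_bases(stem, config$gc)
        loop <- rand_bases(config$loop_len, config$gc)
        right <- revcomp(left)
        spare <- seg_len - (2L * stem + config$loop_len)
        block <- c(left, loop, right, rand_bases(spare, config$gc))
        bases[pos + seq_len(seg_len)] <- block
        li <- pos + seq_len(stem)
        ri <- pos + stem + config$loop_len + (stem:1)
        pairing[li] <- ri
        pairing[ri] <- li
      } else {
        bases[pos + seq_len(seg_len)] <- rand_bases(seg_len, config$gc)
      }
      pos <- pos + seg_len
    }
    ac <- which(bases %in% c("A", "C")) - 1L  # 0-based coordinates
    seg <- segment_windows(ac, w = config$w, transcript_id = id)
    paired <- pairing > 0L
    p_base <- numeric(L)
    p_base[bases %in% c("G", "T")] <- config$gu_rate
    is_ac <- bases %in% c("A", "C")
    n_up <- sum(is_ac & !paired); n_p <- sum(is_ac & paired)
    p_base[is_ac & !paired] <- rbeta(n_up, config$unpaired_shape[1],
                                     config$unpaired_shape[2])
    p_base[is_ac & paired] <- rbeta(n_p, config$paired_shape[1],
                                    config$paired_shape[2])
    coverage <- as.integer(round(rlnorm(1, config$coverage_meanlog,
                                        config$coverage_sdlog)))
    txs[[id]] <- list(id = id, length = L, sequence = paste(bases, collapse = ""),
                      bases = bases, pairing = pairing, regions = regions,
                      coverage = coverage, ac_positions = ac,
                      windows = seg$windows, membership = seg$membership,
                      p_mod = p_base)
  }
  # window manifest with planted structure content
  manifest <- do.call(rbind, lapply(txs, function(tx) {
    wdf <- tx$windows
    if (nrow(wdf) == 0) return(NULL)
    wdf$window_id <- paste(tx$id, wdf$window_index, sep = "#")
    wdf$paired_frac <- vapply(seq_len(nrow(wdf)), function(j) {
      memb <- tx$ac_positions[which(tx$membership == j)] + 1L
      mean(tx$pairing[memb] > 0)
    }, 0)
    wdf
  }))
  rownames(manifest) <- NULL
  manifest$structured <- manifest$paired_frac >= 0.5
  manifest$unstructured <- manifest$paired_frac == 0
  # RBP sites: uniform placement; infeasible width is an error
  if (any(config$site_width > vapply(txs, `[[`, 0L, "length")))
    stop("site width exceeds a transcript length")
  n_sites <- config$n_rbps * config$sites_per_rbp
  tx_ids <- names(txs)
  site_tx <- sample(tx_ids, n_sites, replace = TRUE)
  # CLIP compilations are dominated by single-stranded-RNA binders: bias site
  # placement toward accessible stretches (mostly-unpaired footprints)
  starts <- vapply(site_tx, function(id) {
    tx <- txs[[id]]
    for (try in 1:50) {
      s <- sample.int(tx$length - config$site_width, 1L) - 1L
      if (mean(tx$pairing[(s + 1):(s + config$site_width)] > 0) <= 0.3)
        return(s)
    }
    s
  }, 0L)
  sites <- data.frame(
    contig = site_tx,
    start = starts,
    end = starts + config$site_width,
    rbp = rep(sprintf("RBP%02d", seq_len(config$n_rbps)),
              each = config$sites_per_rbp),
    strand = "+",
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(config = config, transcripts = txs, manifest = manifest,
                 sites = sites,
                 released_rbps = sprintf("RBP%02d",
                                         seq_len(config$released_rbps))),
            class = "tram_truth")
}

occlusion_factor <- function(truth, occluded_rbps) {
  # per-transcript multiplicative factor on modification probability
  cfg <- truth$config
  lapply(truth$transcripts, function(tx) {
    fac <- rep(1, tx$length)
    s <- truth$sites[truth$sites$contig == tx$id &
                       truth$sites$rbp %in% occluded_rbps, , drop = FALSE]
    for (i in seq_len(nrow(s)))
      fac[(s$start[i] + 1):s$end[i]] <- 1 - cfg$occlusion
    fac
  })
}

#' Plant the condition-b perturbation
#'
#' Selects a fraction of windows uniformly at random and flips the pairing
#' status (hence the reactivity class) of a fraction of their A/C positions;
#' modification probabilities for flipped positions are re-drawn from the
#' opposite class's distribution. Additionally, the designated released RBPs
#' lose their site occlusion in condition b. With `frac_remodeled = 0` and no
#' released RBPs, condition b is identical to condition a.
#'
#' @param truth a `tram_truth` from [generate_truth()].
#' @param config the same [sim_config()].
#' @return the truth with condition-b fields added: `p_mod_b` per transcript,
#'   `remodeled_windows` (flipped window ids), `flipped` (0-based positions
#'   per transcript), and the manifest gains `remodeled` /
#'   `released_site_overlap` flags.
#' @export
apply_condition_effect <- function(truth, config = truth$config) {
  if (config$frac_remodeled < 0 || config$frac_remodeled > 1)
    stop("frac_remodeled must be in [0, 1]")
  set.seed(config$seed + 1000L)
  man <- truth$manifest
  n_rem <- round(config$frac_remodeled * nrow(man))
  remodeled <- if (n_rem > 0) sample(man$window_id, n_rem) else character(0)
  for (id in names(truth$transcripts)) {
    tx <- truth$transcripts[[id]]
    p_b <- tx$p_mod
    pairing_b <- tx$pairing > 0L
    flipped <- integer(0)
    wids <- paste(id, seq_len(max(0, nrow(tx$windows))), sep = "#")
    for (j in which(wids %in% remodeled)) {
      memb <- tx$ac_positions[which(tx$membership == j)]
      nf <- round(config$flip_frac * length(memb))
      fl <- sort(sample(memb, nf))
      flipped <- c(flipped, fl)
      for (p in fl) {
        now_paired <- !pairing_b[p + 1L]
        pairing_b[p + 1L] <- now_paired
        p_b[p + 1L] <- if (now_paired)
          rbeta(1, config$paired_shape[1], config$paired_shape[2])
        else rbeta(1, config$unpaired_shape[1], config$unpaired_shape[2])
      }
    }
    truth$transcripts[[id]]$p_mod_b <- p_b
    truth$transcripts[[id]]$flipped <- flipped
  }
  man$remodeled <- man$window_id %in% remodeled
  rel_sites <- truth$sites[truth$sites$rbp %in% truth$released_rbps, , drop = FALSE]
  man$released_site_overlap <- vapply(seq_len(nrow(man)), function(i) {
    s <- rel_sites[rel_sites$contig == man$transcript_id[i], , drop = FALSE]
    any(s$start <= man$span_end[i] & s$end > man$span_start[i])
  }, TRUE)
  truth$manifest <- man
  truth$remodeled_windows <- remodeled
  truth
}

#' Simulate per-sample base-call count tables
#'
#' Draws mismatch counts per position as Binomial(coverage, p) where, for a
#' treated sample, p is the control background plus the (possibly
#' RBP-occluded, replicate-noised) modification probability, capped at 1, and
#' for an untreated control p is the background alone. Mismatches are split
#' uniformly among the three non-reference bases.
#'
#' @param truth a `tram_truth` (with condition-b fields when
#'   `condition = "b"`).
#' @param config the [sim_config()].
#' @param condition `"a"` or `"b"`.
#' @param replicate replicate index.
#' @param treated simulate the DMS-treated sample (`TRUE`) or its control.
#' @return a base-call counts data.frame (see [read_basecall_counts()]).
#' @export
simulate_profiles <- function(truth, config = truth$config,
                              condition = c("a", "b"), replicate = 1L,
                              treated = TRUE) {
  condition <- match.arg(condition)
  if (condition == "b" && is.null(truth$transcripts[[1]]$p_mod_b))
    stop("condition b requested but apply_condition_effect() has not run")
  offset <- (match(condition, c("a", "b")) - 1L) * 100L +
    as.integer(replicate) * 10L + as.integer(isTRUE(treated))
  set.seed(config$seed + 2000L + offset)
  occl <- if (condition == "a")
    occlusion_factor(truth, unique(truth$sites$rbp))
  else
    occlusion_factor(truth, setdiff(unique(truth$sites$rbp),
                                    truth$released_rbps))
  out <- lapply(names(truth$transcripts), function(id) {
    tx <- truth$transcripts[[id]]
    p_mod <- if (condition == "a") tx$p_mod else tx$p_mod_b
    p <- if (treated) {
      noise <- rlnorm(tx$length, 0, config$rep_noise_sdlog)
      pmin(1, config$control_error + p_mod * occl[[id]] * noise)
    } else rep(config$control_error, tx$length)
    mis <- rbinom(tx$length, tx$coverage, p)
    a1 <- rbinom(tx$length, mis, 1 / 3)
    a2 <- rbinom(tx$length, mis - a1, 1 / 2)
    a3 <- mis - a1 - a2
    cnt <- matrix(0L, tx$length, 4, dimnames = list(NULL, DNA))
    ref_idx <- match(tx$bases, DNA)
    cnt[cbind(seq_len(tx$length), ref_idx)] <- tx$coverage - mis
    alt <- t(vapply(ref_idx, function(r) setdiff(1:4, r), integer(3)))
    cnt[cbind(seq_len(tx$length), alt[, 1])] <-
      cnt[cbind(seq_len(tx$length), alt[, 1])] + a1
    cnt[cbind(seq_len(tx$length), alt[, 2])] <-
      cnt[cbind(seq_len(tx$length), alt[, 2])] + a2
    cnt[cbind(seq_len(tx$length), alt[, 3])] <-
      cnt[cbind(seq_len(tx$length), alt[, 3])] + a3
    data.frame(contig = id, position = seq_len(tx$length) - 1L, strand = "+",
               ref_base = tx$bases, A = cnt[, 1], C = cnt[, 2], G = cnt[, 3],
               T = cnt[, 4], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the full synthetic experiment in memory
#'
#' Generates truth, applies the condition-b effect, and simulates base-call
#' tables for every (condition, replicate, treated/control) combination.
#'
#' @param config a [sim_config()].
#' @param conditions simulate condition `"a"` only or both.
#' @return list `truth`, `counts` (named list of count tables,
#'   `dms_a1`, `ctl_a1`, ...), `samples` (metadata data.frame).
#' @export
simulate_experiment <- function(config, conditions = c("a", "b")) {
  truth <- generate_truth(config)
  if ("b" %in% conditions) truth <- apply_condition_effect(truth, config)
  counts <- list()
  samples <- NULL
  for (cond in conditions) {
    for (k in seq_len(config$n_replicates)) {
      for (tr in c(TRUE, FALSE)) {
        nm <- sprintf("%s_%s%d", if (tr) "dms" else "ctl", cond, k)
        counts[[nm]] <- simulate_profiles(truth, config, condition = cond,
                                          replicate = k, treated = tr)
        samples <- rbind(samples, data.frame(
          sample_id = nm, condition = cond, replicate = k, treated = tr,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(truth = truth, counts = counts, samples = samples)
}

#' Write a complete CLI-ready input bundle plus truth manifest
#'
#' Materializes [simulate_experiment()] to disk: transcript FASTA, region and
#' RBP-site BEDs, one base-call TSV per sample, and a machine-readable JSON
#' manifest of the planted truths (window table with structured / remodeled
#' flags, released RBPs, seed) for downstream validation.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created).
#' @param conditions conditions to simulate.
#' @return invisibly, a list with `dir`, file paths, and the `truth`.
#' @export
end_to_end_fixture <- function(config, dir, conditions = c("a", "b")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config, conditions)
  truth <- sim$truth
  seqs <- Biostrings::DNAStringSet(vapply(truth$transcripts, `[[`, "", "sequence"))
  names(seqs) <- names(truth$transcripts)
  fa <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(seqs, fa)
  regions <- do.call(rbind, lapply(truth$transcripts, `[[`, "regions"))
  reg_bed <- file.path(dir, "regions.bed")
  rtracklayer::export(GenomicRanges::GRanges(
    regions$transcript_id,
    IRanges::IRanges(regions$start + 1L, regions$end),
    name = regions$region), reg_bed, format = "BED")
  site_bed <- file.path(dir, "sites.bed")
  rtracklayer::export(GenomicRanges::GRanges(
    truth$sites$contig,
    IRanges::IRanges(truth$sites$start + 1L, truth$sites$end),
    strand = truth$sites$strand, name = truth$sites$rbp), site_bed,
    format = "BED")
  count_paths <- character(0)
  for (nm in names(sim$counts)) {
    p <- file.path(dir, paste0(nm, ".counts.tsv"))
    write_basecall_counts(sim$counts[[nm]], p)
    count_paths[nm] <- p
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    seed = config$seed, w = config$w,
    windows = truth$manifest,
    released_rbps = truth$released_rbps,
    samples = sim$samples), manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, fasta = fa, regions = reg_bed, sites = site_bed,
                 counts = count_paths, manifest = manifest_path,
                 truth = truth, sim = sim))
}

#' Run the profile-to-window pipeline on a simulated experiment
#'
#' Convenience wrapper tying the modules together: computes mismatch rates for
#' every sample, applies the intersection coverage filter, control-subtracts
#' each DMS replicate, joins the reactivity profiles, and computes window
#' statistics for the DMS samples.
#'
#' @param sim output of [simulate_experiment()] (or the `sim` element of
#'   [end_to_end_fixture()]).
#' @param w window size in A/C datapoints.
#' @param min_coverage coverage filter threshold.
#' @return list `stats` (window table), `mat` (reactivity matrix),
#'   `transcripts` (transcript-level table).
#' @export
run_pipeline <- function(sim, w = 50, min_coverage = 100) {
  profs <- lapply(seq_len(nrow(sim$samples)), function(i) {
    s <- sim$samples[i, ]
    compute_mismatch_rates(sim$counts[[s$sample_id]], s$sample_id,
                           condition = s$condition, replicate = s$replicate,
                           treated = s$treated)
  })
  names(profs) <- sim$samples$sample_id
  mask <- coverage_mask(profs, min_coverage = min_coverage)
  dms <- sim$samples[sim$samples$treated, ]
  rx <- lapply(seq_len(nrow(dms)), function(i) {
    s <- dms[i, ]
    ctl_id <- sim$samples$sample_id[!sim$samples$treated &
                                      sim$samples$condition == s$condition &
                                      sim$samples$replicate == s$replicate]
    normalize_control(profs[[s$sample_id]], profs[[ctl_id]], mask)
  })
  mat <- join_profiles(rx)
  stats <- window_stats(mat, w = w)
  list(stats = stats, mat = mat,
       transcripts = transcript_stats(mat))
}

#' Direct window-level simulator for calibration studies
#'
#' Bypasses sequences and sampling depth bookkeeping to generate reactivity
#' matrices for a set of independent windows: per-position baseline
#' modification probabilities (a paired/unpaired mixture), per-replicate
#' lognormal noise, and binomial counting noise at fixed coverage. Under
#' `effect = 0` both conditions share one generative profile (the null);
#' `effect > 0` re-draws the class of that fraction of positions in condition
#' b for the first `n_effect` windows.
#'
#' @param n_windows number of windows.
#' @param n_reps replicates per condition.
#' @param n_pos A/C datapoints per window.
#' @param coverage read depth.
#' @param paired_frac fraction of positions drawn from the paired class.
#' @param effect fraction of positions whose class flips in condition b.
#' @param n_effect number of leading windows carrying the effect.
#' @param seed integer seed (required).
#' @param config optional [sim_config()] supplying the reactivity
#'   distributions (defaults used otherwise).
#' @return list `mats` (list of n_pos x (2 n_reps) matrices), `conditions`,
#'   `truth` (logical: window carries a planted effect).
#' @export
simulate_window_set <- function(n_windows, n_reps = 2, n_pos = 50,
                                coverage = 2000, paired_frac = 0.3,
                                effect = 0, n_effect = 0, seed,
                                config = sim_config(seed = seed)) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  draw_class <- function(paired) ifelse(
    paired,
    rbeta(length(paired), config$paired_shape[1], config$paired_shape[2]),
    rbeta(length(paired), config$unpaired_shape[1], config$unpaired_shape[2]))
  conditions <- rep(c("a", "b"), each = n_reps)
  mats <- vector("list", n_windows)
  truth <- rep(FALSE, n_windows)
  for (wn in seq_len(n_windows)) {
    paired_a <- runif(n_pos) < paired_frac
    p_a <- draw_class(paired_a)
    p_b <- p_a
    if (effect > 0 && wn <= n_effect) {
      fl <- sample.int(n_pos, round(effect * n_pos))
      p_b[fl] <- draw_class(!paired_a[fl])
      truth[wn] <- TRUE
    }
    sample_col <- function(p) {
      noise <- rlnorm(n_pos, 0, config$rep_noise_sdlog)
      pr <- pmin(1, config$control_error + p * noise)
      pmax(0, rbinom(n_pos, coverage, pr) / coverage - config$control_error)
    }
    mats[[wn]] <- cbind(
      vapply(seq_len(n_reps), function(k) sample_col(p_a), numeric(n_pos)),
      vapply(seq_len(n_reps), function(k) sample_col(p_b), numeric(n_pos)))
  }
  list(mats = mats, conditions = conditions, truth = truth)
}
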