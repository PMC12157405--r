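small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_transcripts = 4, length_mean = 800,
             length_sd = 50, sites_per_rbp = 8, n_rbps = 3, ...)
}

test_that("a seed is mandatory and drives full determinism", {
  expect_error(sim_config(), "seed")
  expect_error(simulate_window_set(10, seed = ), "seed")
  cfg <- small_cfg(seed = 77)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$manifest, t2$manifest)
  expect_identical(t1$transcripts[[1]]$sequence, t2$transcripts[[1]]$sequence)
  c1 <- simulate_profiles(t1, cfg, condition = "a", replicate = 1, treated = TRUE)
  c2 <- simulate_profiles(t2, cfg, condition = "a", replicate = 1, treated = TRUE)
  expect_identical(c1, c2)
})

test_that("config validation enforces the reactivity ordering and occlusion range", {
  expect_error(sim_config(seed = 1, unpaired_shape = c(2, 398),
                          paired_shape = c(2, 38)), "exceed")
  expect_error(sim_config(seed = 1, occlusion = 1.5), "occlusion")
})

test_that("planted structures are valid involutions with legal loops; regions tile", {
  cfg <- small_cfg(seed = 31)
  truth <- generate_truth(cfg)
  for (tx in truth$transcripts) {
    p <- tx$pairing
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))            # involution
    stems <- which(p > 0 & seq_along(p) < p)
    if (length(stems) > 0)
      expect_true(all(p[stems] - stems - 1 >= cfg$loop_len))  # loop size
    # complementary arms: planted pairs obey Watson-Crick/GU pairing
    pairs <- paste0(tx$bases[stems], tx$bases[p[stems]])
    expect_true(all(pairs %in% c("AT", "TA", "GC", "CG", "GT", "TG")))
    # regions tile [0, L) without overlap
    r <- tx$regions[order(tx$regions$start), ]
    expect_equal(r$start, c(0L, r$end[-3]))
    expect_equal(r$end[3], tx$length)
  }
})

test_that("simulated rates converge to the configured probabilities at deep coverage", {
  cfg <- sim_config(seed = 19, n_transcripts = 1, length_mean = 600,
                    length_sd = 1, coverage_meanlog = log(1e5),
                    coverage_sdlog = 0, rep_noise_sdlog = 0,
                    n_rbps = 1, sites_per_rbp = 1)
  truth <- generate_truth(cfg)
  tx <- truth$transcripts[[1]]
  counts <- simulate_profiles(truth, cfg, condition = "a", treated = TRUE)
  prof <- compute_mismatch_rates(counts, "dms")
  occl <- rep(1, tx$length)
  s <- truth$sites
  for (i in seq_len(nrow(s))) occl[(s$start[i] + 1):s$end[i]] <- 1 - cfg$occlusion
  expected <- pmin(1, cfg$control_error + tx$p_mod * occl)
  got <- prof$mismatch_rate[match(0:(tx$length - 1), prof$position)]
  se <- sqrt(expected * (1 - expected) / tx$coverage)
  expect_gt(mean(abs(got - expected) <= 3 * se + 1e-9), 0.99)
  expect_lt(mean(abs(got - expected)), 3 * mean(se))
  # control subtraction recovers the modification probability +- sampling noise
  ctl <- compute_mismatch_rates(
    simulate_profiles(truth, cfg, condition = "a", treated = FALSE), "ctl",
    treated = FALSE)
  corrected <- prof$mismatch_rate - ctl$mismatch_rate[match(prof$position, ctl$position)]
  expect_true(mean(abs(corrected - (expected - cfg$control_error))) < 3e-3)
})

test_that("full occlusion makes bound sites look like paired baseline", {
  cfg <- sim_config(seed = 23, n_transcripts = 2, length_mean = 900,
                    length_sd = 1, occlusion = 1, coverage_meanlog = log(5e4),
                    coverage_sdlog = 0, rep_noise_sdlog = 0, n_rbps = 1,
                    sites_per_rbp = 10, p_hairpin = c("5UTR" = 0, "CDS" = 0, "3UTR" = 0))
  truth <- generate_truth(cfg)
  counts <- simulate_profiles(truth, cfg, condition = "a", treated = TRUE)
  tx <- truth$transcripts[[1]]
  s <- truth$sites[truth$sites$contig == tx$id, ]
  occl_pos <- unique(unlist(lapply(seq_len(nrow(s)), function(i)
    s$start[i]:(s$end[i] - 1))))
  sub <- counts[counts$contig == tx$id, ]
  m <- as.matrix(sub[c("A", "C", "G", "T")])
  ref_calls <- m[cbind(seq_len(nrow(m)), match(sub$ref_base, c("A", "C", "G", "T")))]
  rate <- (rowSums(m) - ref_calls) / rowSums(m)
  ac <- sub$ref_base %in% c("A", "C")
  in_site <- sub$position %in% occl_pos
  # fully occluded unpaired A/C indistinguishable from background
  expect_lt(mean(rate[ac & in_site]), cfg$control_error * 2.5)
  expect_gt(mean(rate[ac & !in_site]), 10 * cfg$control_error)
})

test_that("zero remodeling fraction leaves condition b identical to a", {
  cfg <- small_cfg(seed = 41, frac_remodeled = 0, released_rbps = 0)
  truth <- apply_condition_effect(generate_truth(cfg))
  for (tx in truth$transcripts)
    expect_identical(tx$p_mod_b, tx$p_mod)
  expect_equal(length(truth$remodeled_windows), 0)
})

test_that("remodeled windows show elevated delta; released sites gain reactivity", {
  cfg <- small_cfg(seed = 43)
  sim <- simulate_experiment(cfg)
  pl <- run_pipeline(sim, w = cfg$w)
  man <- sim$truth$manifest
  idx <- match(pl$stats$window_id, man$window_id)
  rem <- man$remodeled[idx]
  clean <- !man$released_site_overlap[idx]
  expect_gt(mean(pl$stats$delta[rem & clean]),
            2 * mean(pl$stats$delta[!rem & clean]))
  # released-RBP sites: mean reactivity rises in condition b
  rel <- sim$truth$sites[sim$truth$sites$rbp %in% sim$truth$released_rbps, ]
  pos <- attr(pl$mat, "positions")
  in_rel <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(rel)))
    in_rel <- in_rel | (pos$contig == rel$contig[i] &
                          pos$position >= rel$start[i] &
                          pos$position < rel$end[i])
  conds <- attr(pl$mat, "samples")$condition
  flipped_pos <- unlist(lapply(sim$truth$transcripts, function(tx)
    paste(tx$id, tx$flipped, sep = ":")))
  untouched <- in_rel & !(rownames(pl$mat) %in% flipped_pos)
  mean_a <- mean(pl$mat[untouched, conds == "a"])
  mean_b <- mean(pl$mat[untouched, conds == "b"])
  expect_gt(mean_b, mean_a * 1.5)
})

test_that("the fixture bundle is byte-stable, complete, and matches the pipeline", {
  cfg <- small_cfg(seed = 47)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- end_to_end_fixture(cfg, d1)
  fx2 <- end_to_end_fixture(cfg, d2)
  expect_identical(readLines(fx1$manifest), readLines(fx2$manifest))
  expect_identical(readLines(fx1$fasta), readLines(fx2$fasta))
  expect_true(all(file.exists(unlist(fx1$counts))))
  # manifest window ids are a subset of the pipeline's window table
  pl <- run_pipeline(fx1$sim, w = cfg$w)
  man <- jsonlite::read_json(fx1$manifest, simplifyVector = TRUE)
  expect_true(all(man$windows$window_id %in% pl$stats$window_id))
  # on-disk inputs re-read into the same profiles
  counts <- read_basecall_counts(fx1$counts[["dms_a1"]])
  expect_equal(counts, fx1$sim$counts[["dms_a1"]], ignore_attr = TRUE)
  regions <- read_regions_bed(fx1$regions)
  expect_setequal(unique(regions$region), c("5UTR", "CDS", "3UTR"))
  sites <- read_sites_bed(fx1$sites)
  expect_equal(nrow(sites), nrow(fx1$sim$truth$sites))
})
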