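make_counts <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig = r[[1]], position = as.integer(r[[2]]), strand = r[[3]],
               ref_base = r[[4]], A = r[[5]], C = r[[6]], G = r[[7]], T = r[[8]],
               stringsAsFactors = FALSE)))
}

test_that("mismatch rates are substitutions over informative depth", {
  counts <- make_counts(
    list("tx1", 10, "+", "A", 180, 10, 5, 5),   # rate (200-180)/200
    list("tx1", 11, "+", "C", 0, 50, 0, 0),     # no mismatches
    list("tx1", 12, "+", "A", 0, 0, 0, 0))      # zero depth -> absent
  p <- compute_mismatch_rates(counts, "s1")
  expect_equal(nrow(p), 2)
  expect_equal(p$mismatch_rate, c(0.10, 0.0))
  expect_equal(p$coverage, c(200L, 50L))
  expect_false(12 %in% p$position)
})

test_that("malformed rows are rejected with row identification", {
  bad_base <- make_counts(list("tx1", 5, "+", "N", 1, 1, 1, 1))
  expect_error(compute_mismatch_rates(bad_base, "s1"), "ref_base")
  neg <- make_counts(list("tx1", 7, "+", "A", -1, 1, 1, 1))
  expect_error(compute_mismatch_rates(neg, "s1"), "negative")
})

test_that("profile TSV round-trips exactly, metadata included", {
  set.seed(11)
  counts <- data.frame(contig = "tx1", position = 0:99, strand = "+",
                       ref_base = sample(c("A", "C", "G", "T"), 100, TRUE),
                       A = rpois(100, 50), C = rpois(100, 50),
                       G = rpois(100, 50), T = rpois(100, 50))
  p <- compute_mismatch_rates(counts, "s1", condition = "ctrl",
                              replicate = 2L, treated = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_identical(as.data.frame(p), as.data.frame(p2))
  expect_identical(attributes(p)[c("sample_id", "condition", "replicate", "treated")],
                   attributes(p2)[c("sample_id", "condition", "replicate", "treated")])
})

prof_from_cov <- function(coverages, id, ref = "A", rate_mis = 0) {
  counts <- data.frame(contig = "tx1",
                       position = seq_along(coverages) - 1L, strand = "+",
                       ref_base = ref,
                       A = 0L, C = 0L, G = 0L, T = 0L)
  counts[[ref]] <- as.integer(round(coverages * (1 - rate_mis)))
  counts$G <- as.integer(coverages) - counts[[ref]]
  if (ref == "G") { counts$G <- as.integer(round(coverages * (1 - rate_mis))); counts$T <- as.integer(coverages) - counts$G }
  compute_mismatch_rates(counts, id)
}

test_that("coverage filter keeps the across-sample intersection, inclusive at the bound", {
  p1 <- prof_from_cov(c(150, 100, 300), "s1")
  p2 <- prof_from_cov(c(99, 100, 250), "s2")
  mask <- coverage_mask(list(p1, p2), min_coverage = 100)
  expect_equal(mask$position, c(1L, 2L))   # (150,99) excluded; (100,100) kept
  expect_equal(coverage_mask(list(p1), 100)$position, 0:2)  # identity mask
  expect_error(coverage_mask(list()), "empty")
})

test_that("coverage filter is monotone in the threshold", {
  set.seed(21)
  profs <- lapply(1:3, function(i) prof_from_cov(sample(50:300, 200, TRUE),
                                                 paste0("s", i)))
  prev <- NULL
  for (thr in c(50, 120, 200, 280)) {
    cur <- coverage_mask(profs, thr)$position
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

make_pair <- function(dms_rates, ctl_rates, refs, strand = "+") {
  n <- length(dms_rates)
  cov <- 1000L
  mk <- function(rates, treated) {
    counts <- data.frame(contig = "tx1", position = seq_len(n) - 1L,
                         strand = strand, ref_base = refs,
                         A = 0L, C = 0L, G = 0L, T = 0L)
    for (i in seq_len(n)) {
      counts[i, refs[i]] <- as.integer(round(cov * (1 - rates[i])))
      other <- setdiff(c("A", "C", "G", "T"), refs[i])[1]
      counts[i, other] <- cov - counts[i, refs[i]]
    }
    compute_mismatch_rates(counts, if (treated) "dms" else "ctl",
                           condition = "c1", replicate = 1L, treated = treated)
  }
  list(dms = mk(dms_rates, TRUE), ctl = mk(ctl_rates, FALSE))
}

test_that("control subtraction floors at zero and keeps only A/C bases", {
  pr <- make_pair(c(0.10, 0.05, 0.30), c(0.02, 0.08, 0.00),
                  refs = c("A", "C", "G"))
  mask <- coverage_mask(pr, 100)
  rx <- normalize_control(pr$dms, pr$ctl, mask)
  expect_equal(rx$reactivity, c(0.08, 0.0))     # subtraction; floor
  expect_false("G" %in% rx$ref_base)            # non-A/C dropped
})

test_that("minus-strand bases are complemented before the A/C selection", {
  pr <- make_pair(c(0.1, 0.1, 0.1, 0.1), rep(0, 4),
                  refs = c("T", "G", "A", "C"), strand = "-")
  rx <- normalize_control(pr$dms, pr$ctl, coverage_mask(pr, 100))
  expect_equal(rx$ref_base, c("T", "G"))  # genomic T/G = transcribed A/C
})

test_that("replicate pairing is validated", {
  pr <- make_pair(c(0.1, 0.2), c(0, 0), refs = c("A", "C"))
  attr(pr$ctl, "replicate") <- 2L
  expect_error(normalize_control(pr$dms, pr$ctl, coverage_mask(pr, 100)),
               "pairing mismatch")
  attr(pr$ctl, "replicate") <- 1L
  expect_error(normalize_control(pr$ctl, pr$dms, coverage_mask(pr, 100)),
               "treated")
})

test_that("constant shifts cancel in subtraction exactly when no floor is hit", {
  set.seed(31)
  for (rep_i in 1:20) {
    n <- 20
    dms <- runif(n, 0, 0.3)
    ctl <- runif(n, 0, 0.3)
    shift <- runif(1, 0, 0.2)
    base <- make_pair(round(dms, 3), round(ctl, 3), refs = rep("A", n))
    shifted <- make_pair(round(dms, 3) + shift, round(ctl, 3) + shift,
                         refs = rep("A", n))
    r0 <- normalize_control(base$dms, base$ctl, coverage_mask(base, 100))
    r1 <- normalize_control(shifted$dms, shifted$ctl, coverage_mask(shifted, 100))
    floor_hit <- round(dms, 3) < round(ctl, 3)
    expect_equal(r1$reactivity[!floor_hit], r0$reactivity[!floor_hit],
                 tolerance = 1e-12)
    expect_true(all(r0$reactivity[floor_hit] == 0))
  }
})

test_that("join aligns identical position sets and rejects divergent ones", {
  pr <- make_pair(c(0.1, 0.2, 0.3), c(0, 0, 0), refs = rep("A", 3))
  mask <- coverage_mask(pr, 100)
  rx1 <- normalize_control(pr$dms, pr$ctl, mask)
  mat1 <- join_profiles(list(rx1))
  expect_equal(dim(mat1), c(3L, 1L))                 # single profile
  mat2 <- join_profiles(list(rx1, rx1))
  expect_equal(mat2[, 1], mat2[, 2])                 # identical columns
  rx_short <- rx1[-1, ]
  attr(rx_short, "sample_id") <- "other"
  expect_error(join_profiles(list(rx1, rx_short)), "position sets")
})
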