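test_that("constraint normalization winsorizes the top tail and scales to 1", {
  x <- c(rep(0.01, 90), seq(0.02, 0.1, length.out = 9), 10)
  y <- normalize_for_folding(x)
  expect_equal(max(y), 1)
  # the outlier was clipped to the 95th-percentile data value before scaling
  expect_equal(y[100], y[99])
  # ratios among untouched small values preserved
  expect_equal(y[2] / y[1], x[2] / x[1], tolerance = 1e-12)
  # constant positive vector -> all 1
  expect_equal(unclass(normalize_for_folding(rep(0.3, 5)))[1:5], rep(1, 5),
               ignore_attr = TRUE)
  z <- normalize_for_folding(rep(0, 4))
  expect_true(all(z == 0) && attr(z, "flag") == "all_zero")
  expect_error(normalize_for_folding(0.5), "at least 2")
})

test_that("constraint normalization is idempotent", {
  set.seed(71)
  for (i in 1:20) {
    x <- rgamma(sample(4:200, 1), shape = 0.7)
    y1 <- normalize_for_folding(x)
    y2 <- normalize_for_folding(as.numeric(y1))
    expect_equal(as.numeric(y2), as.numeric(y1), tolerance = 1e-12)
  }
})

test_that("SHAPE constraint files use 1-based indices with the -999 sentinel", {
  path <- withr::local_tempfile(fileext = ".shape")
  write_shape(c(NA, 0.7, NA), path)
  expect_equal(readLines(path), c("1 -999", "2 0.69999999999999996", "3 -999"))
  expect_equal(read_shape(path), c(NA, 0.7, NA))
  # empty constraint set -> all sentinel
  write_shape(rep(NA_real_, 4), path)
  expect_true(all(is.na(read_shape(path))))
  set.seed(72)
  v <- ifelse(runif(50) < 0.3, NA, runif(50))
  write_shape(v, path)
  expect_equal(read_shape(path), v)
})

test_that("dot-bracket and CT files round-trip", {
  st <- secondary_structure("GGGAAACCC", c(9, 8, 7, 0, 0, 0, 3, 2, 1))
  expect_equal(dotbracket(st), "(((...)))")
  expect_equal(pairing_from_dotbracket("(((...)))"), st$pairing)
  ct <- withr::local_tempfile(fileext = ".ct")
  write_ct(st, ct)
  st2 <- read_ct(ct)
  expect_equal(st2$pairing, st$pairing)
  expect_equal(st2$sequence, st$sequence)
  dbn <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">hp", "GGGAAACCC", "(((...)))"), dbn)
  expect_equal(read_dotbracket(dbn)$pairing, st$pairing)
  expect_error(pairing_from_dotbracket("(()"), "unbalanced")
  expect_error(secondary_structure("AAAA", c(2, 3, 1, 0)), "involution")
})

test_that("the built-in folder solves canonical hairpins and respects penalties", {
  st <- fold_constrained("GGGAAACCC", min_loop = 3)
  expect_equal(st$pairing, c(9, 8, 7, 0, 0, 0, 3, 2, 1))  # 3 nested pairs
  expect_equal(sum(fold_constrained("AAAAAA")$pairing > 0), 0)
  # reactivity 1 on all stem bases with a large penalty forbids pairing
  cons <- c(1, 1, 1, 0, 0, 0, 1, 1, 1)
  st2 <- fold_constrained("GGGAAACCC", cons, penalty = 10)
  expect_equal(sum(st2$pairing > 0), 0)
  expect_error(fold_constrained("GGXAAACCC"), "A/C/G/U")
})

test_that("the folder's score equals exhaustive non-crossing enumeration up to L = 12", {
  set.seed(73)
  for (i in 1:25) {
    L <- sample(5:12, 1)
    seq_ <- random_rna(L)
    bases <- strsplit(seq_, "")[[1]]
    cvec <- ifelse(runif(L) < 0.5, 0, runif(L))
    pen <- sample(c(0.5, 1, 2), 1)
    st <- fold_constrained(seq_, cvec, penalty = pen)
    got <- structure_score(st, cvec, penalty = pen)
    best <- enumerate_best_score(bases, cvec, min_loop = 3, penalty = pen)
    expect_equal(got, best, tolerance = 1e-9)
    # output is a valid non-crossing structure over allowed pairs
    p <- st$pairing
    for (a in which(p > 0 & seq_len(L) < p)) {
      b <- p[a]
      expect_true(paste0(bases[a], bases[b]) %in%
                    c("AU", "UA", "GC", "CG", "GU", "UG"))
      expect_gte(b - a - 1, 3)
      crossing <- any(p > 0 & seq_len(L) > a & seq_len(L) < b & (p[seq_len(L)] < a | p[seq_len(L)] > b) & seq_len(L) != b)
      expect_false(crossing)
    }
  }
})

test_that("the external-folder adapter reproduces an unambiguous hairpin", {
  st <- fold_external("GGGGGAAAAACCCCC")
  expect_equal(sum(st$pairing > 0) / 2, 5)
  expect_equal(st$pairing[1], 15)
  # constraints are honored: fully reactive stem suppresses pairing
  cons <- c(rep(1, 5), rep(NA, 5), rep(1, 5))
  st2 <- fold_external("GGGGGAAAAACCCCC", cons)
  expect_lt(sum(st2$pairing > 0), 10)
})

test_that("auroc matches pair counting, handles ties, and ignores class-free input", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_true(is.na(auroc(c(1, 2), c(TRUE, TRUE))))
  set.seed(74)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    cls <- runif(n) < 0.5
    if (length(unique(cls)) < 2) next
    expect_equal(auroc(s, cls), auroc_oracle(s, cls), tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent ROC implementation and is rank invariant", {
  skip_if_not_installed("pROC")
  set.seed(75)
  for (i in 1:10) {
    n <- 60
    cls <- runif(n) < 0.4
    if (length(unique(cls)) < 2) next
    s <- rnorm(n) + cls
    ref <- as.numeric(pROC::auc(pROC::roc(response = cls, predictor = s,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auroc(s, cls), ref, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auroc(exp(3 * s), cls), auroc(s, cls), tolerance = 1e-12)
    # complement symmetry on tie-free scores
    expect_equal(auroc(-s, cls) + auroc(s, cls), 1, tolerance = 1e-12)
  }
})

test_that("auroc_structure restricts scoring to A/C bases with data", {
  st <- secondary_structure("GACGU", c(5, 0, 0, 0, 1))
  # A (unpaired, high) vs C (unpaired, low): only A/C enter; G/U ignored
  r <- c(0.9, 0.8, 0.1, 0.9, 0.0)
  expect_equal(auroc_structure(r, st), auroc(c(0.8, 0.1), c(TRUE, TRUE)))
  st2 <- secondary_structure("AACC", c(3, 4, 1, 2))
  r2 <- c(0.9, 0.2, 0.3, 0.1)
  expect_true(is.na(auroc_structure(r2, st2)))  # single class
})

test_that("condition fits: structure-consistent reactivities outscore scrambled ones", {
  set.seed(76)
  wins <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    L <- 60
    pairing <- integer(L)
    pairing[1:20] <- 60:41; pairing[41:60] <- 20:1
    seq_ <- random_rna(L)
    st <- secondary_structure(seq_, pairing)
    unpaired <- st$pairing == 0
    rb <- ifelse(unpaired, rbeta(L, 2, 38), rbeta(L, 2, 398))  # consistent
    ra <- sample(rb)                                           # scrambled
    fits <- compare_condition_fits(
      sequences = c(rg = seq_),
      react_a = list(rg = ra), react_b = list(rg = rb),
      structures = list(rg = st))
    if (nrow(fits) == 1 && fits$auroc_b > fits$auroc_a) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.95 * n_seeds) - 2)
  # identical inputs give identical fits; pair-free regions are excluded
  st_free <- secondary_structure("ACAC", integer(4))
  out <- compare_condition_fits(c(x = "ACAC"), list(x = runif(4)),
                                list(x = runif(4)),
                                structures = list(x = st_free))
  expect_equal(nrow(out), 0)
})
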