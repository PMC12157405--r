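# Independent brute-force oracles used to verify the package's statistics.
# These deliberately use the naive O(n^2) / enumerative definitions rather
# than any code path from the package.

gini_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

# textbook pooled-variance two-sample t-test
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

# step-up BH recursion: p_adj(i) = min over j >= i of m * p(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive hypergeometric tail by summing the combinatorial pmf
hyper_tail_oracle <- function(k, K, n, M, upper = TRUE) {
  pmf <- function(x) choose(K, x) * choose(M - K, n - x) / choose(M, n)
  xs <- if (upper) k:min(K, n) else 0:k
  sum(vapply(xs, pmf, 0))
}

# AUROC by counting wins over every (positive, negative) pair; ties half
auroc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# enumerate all non-crossing structures over allowed pairs with a hairpin
# constraint, returning the maximum achievable folding score
enumerate_best_score <- function(bases, cvec, min_loop = 3, penalty = 1) {
  pairable <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    b <- best(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (!pairable(bases[i], bases[k])) next
      sc <- 1 - penalty * (cvec[i] + cvec[k])
      inner <- if (k - 1 >= i + 1) best(i + 1, k - 1) else 0
      rest <- if (k + 1 <= j) best(k + 1, j) else 0
      b <- max(b, sc + inner + rest)
    }
    b
  }
  best(1, length(bases))
}

# naive exhaustive enumeration of every non-crossing pairing (small L only):
# used to double-check enumerate_best_score itself on tiny cases
all_structures <- function(L, min_loop = 3) {
  rec <- function(i, j) {
    if (j - i < min_loop + 1)
      return(list(integer(0)))
    out <- lapply(rec(i + 1, j), identity)
    for (k in (i + min_loop + 1):j) {
      inner <- rec(i + 1, k - 1)
      rest <- rec(k + 1, j)
      for (s1 in inner) for (s2 in rest)
        out[[length(out) + 1]] <- rbind(c(i, k), s1, s2)
    }
    out
  }
  rec(1, L)
}

random_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                                collapse = "")
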