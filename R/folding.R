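#' Normalize reactivities into folding constraints
#'
#' Winsorizes at the 95th-percentile order statistic (upper limit only; the
#' largest values are set to the 95th-percentile data value, no lower
#' clipping) and then scales the vector to a maximum of 1. Using the order
#' statistic rather than an interpolated quantile makes the operation
#' idempotent and matches standard one-sided winsorization. An all-zero input
#' returns all zeros with a flag attribute.
#'
#' @param x non-negative numeric vector, length >= 2 (NAs allowed; they are
#'   preserved and ignored by the percentile and maximum).
#' @return numeric vector in \[0, 1\] with `attr(, "flag")` equal to
#'   `"all_zero"` when no signal was present.
#' @export
normalize_for_folding <- function(x) {
  if (length(x) < 2) stop("need at least 2 reactivity values")
  if (any(x < 0, na.rm = TRUE)) stop("reactivities must be non-negative")
  ok <- !is.na(x)
  if (all(x[ok] == 0))
    return(structure(x, flag = "all_zero"))
  q <- unname(quantile(x[ok], 0.95, type = 1))  # order statistic, no interpolation
  y <- pmin(x, q)
  y <- y / max(y, na.rm = TRUE)
  structure(y, flag = "")
}

#' Write / read a SHAPE-style constraint file
#'
#' Two-column whitespace-separated text: 1-based position index and the
#' normalized reactivity; positions without data carry the `-999` sentinel.
#' Every position 1..length is written so the file round-trips exactly.
#'
#' @param values numeric vector of normalized reactivities on a contiguous
#'   1..length frame; `NA` marks missing data.
#' @param path file path.
#' @return `write_shape` returns the path invisibly; `read_shape` a numeric
#'   vector with `NA` at sentinel positions.
#' @export
write_shape <- function(values, path) {
  idx <- seq_along(values)
  if (anyDuplicated(idx)) stop("duplicate indices")
  out <- ifelse(is.na(values), "-999", sprintf("%.17g", values))
  writeLines(paste(idx, out), path)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path) {
  df <- read.table(path, col.names = c("pos", "value"))
  if (anyDuplicated(df$pos)) stop("duplicate indices in SHAPE file: ", path)
  values <- rep(NA_real_, max(df$pos))
  v <- df$value
  v[v <= -500] <- NA
  values[df$pos] <- v
  values
}

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

can_pair <- function(a, b) paste0(a, b) %in% ALLOWED_PAIRS

#' Secondary structure object
#'
#' @param sequence RNA string (T is converted to U).
#' @param pairing integer vector, partner index per position (0 = unpaired).
#' @param source `"reference"` or `"predicted"`.
#' @return a `tram_structure` list with elements `sequence`, `pairing`,
#'   `source`.
#' @export
secondary_structure <- function(sequence, pairing, source = "reference") {
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  if (length(pairing) != n) stop("pairing length must equal sequence length")
  p <- which(pairing > 0)
  if (any(pairing[pairing[p]] != p))
    stop("pairing must be an involution: partner(partner(i)) = i")
  structure(list(sequence = sequence, pairing = as.integer(pairing),
                 source = source),
            class = "tram_structure")
}

#' @export
print.tram_structure <- function(x, ...) {
  cat(sprintf("<tram_structure> %d nt, %d pairs (%s)\n%s\n%s\n",
              nchar(x$sequence), sum(x$pairing > 0) / 2, x$source,
              x$sequence, dotbracket(x)))
  invisible(x)
}

#' Dot-bracket rendering and parsing
#'
#' `dotbracket()` renders a non-crossing structure as a dot-bracket string;
#' `pairing_from_dotbracket()` parses one (round-trip inverse).
#'
#' @param structure a `tram_structure`.
#' @export
dotbracket <- function(structure) {
  p <- structure$pairing
  ch <- rep(".", length(p))
  ch[p > 0 & seq_along(p) < p] <- "("
  ch[p > 0 & seq_along(p) > p] <- ")"
  paste(ch, collapse = "")
}

#' @rdname dotbracket
#' @param db dot-bracket string.
#' @export
pairing_from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pairing <- integer(length(ch))
  open_stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open_stack <- c(open_stack, i)
    else if (ch[i] == ")") {
      if (length(open_stack) == 0) stop("unbalanced dot-bracket string")
      j <- open_stack[length(open_stack)]
      open_stack <- open_stack[-length(open_stack)]
      pairing[i] <- j; pairing[j] <- i
    }
  }
  if (length(open_stack) > 0) stop("unbalanced dot-bracket string")
  pairing
}

#' Read / write CT files
#'
#' Connectivity-table format: a header line with the length and a title, then
#' one line per base with index, base, i-1, i+1, partner (0 = unpaired),
#' index.
#'
#' @param structure a `tram_structure`.
#' @param path file path.
#' @param title optional CT title.
#' @export
write_ct <- function(structure, path, title = "structure") {
  n <- nchar(structure$sequence)
  base <- strsplit(structure$sequence, "")[[1]]
  lines <- c(sprintf("%d %s", n, title),
             sprintf("%d %s %d %d %d %d", seq_len(n), base,
                     seq_len(n) - 1L, c(seq_len(n - 1) + 1L, 0L),
                     structure$pairing, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  rec <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  base <- vapply(rec, `[`, "", 2)
  pairing <- as.integer(vapply(rec, `[`, "", 5))
  secondary_structure(paste(base, collapse = ""), pairing, source = "reference")
}

#' Read a dot-bracket (.dbn) file
#'
#' Expects an optional `>`-header line, a sequence line and a dot-bracket
#' line.
#' @param path file path.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (startsWith(lines[1], ">")) lines <- lines[-1]
  secondary_structure(lines[1], pairing_from_dotbracket(lines[2]),
                      source = "reference")
}

#' Fold with a reactivity-penalized base-pair maximization dynamic program
#'
#' Nussinov-style non-crossing folding that maximizes
#' `sum over pairs (1 - penalty * (c_i + c_j))` where `c` is the normalized
#' reactivity constraint (0 where missing): pairs are rewarded, but pairing a
#' base the probing data says is accessible costs reactivity-weighted penalty,
#' so high-reactivity bases end up unpaired. This is a combinatorial test
#' folder, deliberately not a thermodynamic nearest-neighbor model; the
#' external adapter ([fold_external()]) plugs in a thermodynamic engine when
#' one is available. Traceback is deterministic: at each subinterval, pairing
#' the left end is preferred over leaving it unpaired, with the smallest
#' admissible partner/split chosen first.
#'
#' @param sequence RNA string over A/C/G/U (T accepted and converted).
#' @param constraints optional numeric vector of normalized reactivities
#'   aligned to the sequence (`NA` = no data).
#' @param min_loop minimum hairpin loop length (unpaired positions enclosed by
#'   a pair; default 3).
#' @param penalty weight of the reactivity term (default 1).
#' @return a `tram_structure` with `source = "predicted"`.
#' @export
fold_constrained <- function(sequence, constraints = NULL, min_loop = 3,
                             penalty = 1) {
  sequence <- toupper(gsub("T", "U", sequence))
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must be over A/C/G/U, got: ",
         paste(unique(setdiff(bases, c("A", "C", "G", "U"))), collapse = ","))
  n <- length(bases)
  cvec <- if (is.null(constraints)) numeric(n) else {
    if (length(constraints) != n) stop("constraints must align to the sequence")
    ifelse(is.na(constraints), 0, constraints)
  }
  pair_score <- function(i, j)
    if (can_pair(bases[i], bases[j])) 1 - penalty * (cvec[i] + cvec[j]) else -Inf
  M <- matrix(0, n, n)
  if (n - 1 >= min_loop + 1) {
    for (span in seq(min_loop + 1, n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1, j]                     # i unpaired
        for (k in seq(i + min_loop + 1, j)) {   # i paired with k
          ps <- pair_score(i, k)
          if (is.finite(ps)) {
            inner <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0
            rest <- if (k + 1 <= j) M[k + 1, j] else 0
            cand <- ps + inner + rest
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  pairing <- integer(n)
  stack <- if (n >= 2) list(c(1, n)) else list()
  eps <- 1e-9
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < min_loop + 1) next
    done <- FALSE
    for (k in seq(i + min_loop + 1, j)) {       # prefer pairing i, smallest k
      ps <- pair_score(i, k)
      if (!is.finite(ps)) next
      inner <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0
      rest <- if (k + 1 <= j) M[k + 1, j] else 0
      if (abs(ps + inner + rest - M[i, j]) < eps) {
        pairing[i] <- k; pairing[k] <- i
        if (k - 1 >= i + 1) stack[[length(stack) + 1]] <- c(i + 1, k - 1)
        if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1, j)
        done <- TRUE
        break
      }
    }
    if (!done) stack[[length(stack) + 1]] <- c(i + 1, j)
  }
  secondary_structure(sequence, pairing, source = "predicted")
}

#' Score of a structure under the folding objective
#'
#' `sum over pairs (1 - penalty * (c_i + c_j))`; used by tests to compare the
#' dynamic program against exhaustive enumeration.
#' @inheritParams fold_constrained
#' @param structure a `tram_structure`.
#' @export
structure_score <- function(structure, constraints = NULL, penalty = 1) {
  p <- structure$pairing
  n <- length(p)
  cvec <- if (is.null(constraints)) numeric(n) else ifelse(is.na(constraints), 0, constraints)
  idx <- which(p > 0 & seq_len(n) < p)
  sum(1 - penalty * (cvec[idx] + cvec[p[idx]]))
}

#' External-folder adapter (RNAfold contract)
#'
#' Writes the sequence (FASTA) and constraints (SHAPE file) to a temporary
#' directory, invokes an external thermodynamic folder, and parses the
#' returned dot-bracket. The default command is ViennaRNA's `RNAfold
#' --shape=<file>`; any tool honoring the write-FASTA+SHAPE / read-structure
#' contract can be substituted via `command`/`args`. Conversion of SHAPE
#' values to pseudo-energies uses the external tool's defaults, which are
#' recorded on the returned object.
#'
#' @inheritParams fold_constrained
#' @param command external folder executable (default `"RNAfold"`).
#' @param args extra command-line arguments.
#' @return a `tram_structure` with `source = "predicted"` and attribute
#'   `engine` describing the call.
#' @export
fold_external <- function(sequence, constraints = NULL, command = "RNAfold",
                          args = character()) {
  if (Sys.which(command) == "")
    stop("external folder not found on PATH: ", command)
  sequence <- toupper(gsub("T", "U", sequence))
  dir <- tempfile("fold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "region.fa")
  writeLines(c(">region", sequence), fa)
  full_args <- c("--noPS", args)
  if (!is.null(constraints)) {
    shp <- file.path(dir, "region.shape")
    write_shape(constraints, shp)
    full_args <- c(full_args, paste0("--shape=", shp))
  }
  out <- system2(command, c(full_args, fa), stdout = TRUE, stderr = FALSE)
  db_line <- grep("^[.()]+", out, value = TRUE)
  if (length(db_line) == 0) stop("could not parse external folder output")
  db <- sub("^([.()]+).*$", "\\1", db_line[1])
  st <- secondary_structure(sequence, pairing_from_dotbracket(db),
                            source = "predicted")
  attr(st, "engine") <- paste(command, paste(full_args, collapse = " "))
  st
}

#' Area under the ROC curve for reactivity vs pairing status
#'
#' Treats predicted-unpaired bases as the positive class and the reactivity as
#' the score: a high AUROC means accessible (reactive) bases are the ones the
#' structure leaves unpaired. Ties contribute half (Mann-Whitney convention).
#' Evaluation should be restricted to A/C positions carrying reactivity data,
#' since G/U bases carry no DMS signal; [auroc_structure()] applies that
#' restriction for you.
#'
#' @param scores numeric reactivities.
#' @param unpaired logical, `TRUE` for unpaired (positive-class) positions.
#' @return AUROC in \[0, 1\], or `NA_real_` if only one class is present.
#' @export
auroc <- function(scores, unpaired) {
  ok <- !is.na(scores) & !is.na(unpaired)
  scores <- scores[ok]; unpaired <- as.logical(unpaired[ok])
  n_pos <- sum(unpaired); n_neg <- sum(!unpaired)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[unpaired]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname auroc
#' @param reactivity numeric vector aligned to the structure's sequence (`NA`
#'   where no data).
#' @param structure a `tram_structure`.
#' @export
auroc_structure <- function(reactivity, structure) {
  bases <- strsplit(structure$sequence, "")[[1]]
  keep <- bases %in% c("A", "C") & !is.na(reactivity)
  auroc(reactivity[keep], structure$pairing[keep] == 0)
}

#' Compare structure/data agreement between two conditions
#'
#' For each region, scores the agreement (AUROC) of each condition's
#' reactivities against a structure: either a supplied per-region structure
#' (e.g. the planted or reference one) or, when `fold = TRUE`, a structure
#' predicted per condition from that condition's constraint-normalized
#' reactivities with the built-in folder. Supports top-K improvement analyses
#' of remodeled regions.
#'
#' @param sequences named character vector of region sequences.
#' @param react_a,react_b named lists of reactivity vectors per region
#'   (aligned to the sequences, `NA` = no data).
#' @param structures optional named list of `tram_structure` per region; used
#'   for both conditions when `fold = FALSE`.
#' @param fold predict a structure per condition with [fold_constrained()].
#' @param min_loop,penalty folding parameters when `fold = TRUE`.
#' @return data.frame `region`, `auroc_a`, `auroc_b` (NA rows excluded when a
#'   region has a single class).
#' @export
compare_condition_fits <- function(sequences, react_a, react_b,
                                   structures = NULL, fold = FALSE,
                                   min_loop = 3, penalty = 1) {
  res <- lapply(names(sequences), function(rg) {
    ra <- react_a[[rg]]; rb <- react_b[[rg]]
    if (fold) {
      sa <- fold_constrained(sequences[[rg]], normalize_for_folding(ra),
                             min_loop = min_loop, penalty = penalty)
      sb <- fold_constrained(sequences[[rg]], normalize_for_folding(rb),
                             min_loop = min_loop, penalty = penalty)
    } else {
      sa <- sb <- structures[[rg]]
    }
    data.frame(region = rg,
               auroc_a = auroc_structure(ra, sa),
               auroc_b = auroc_structure(rb, sb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[!is.na(out$auroc_a) & !is.na(out$auroc_b), , drop = FALSE]
}
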