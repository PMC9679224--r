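# Independent oracles used to check the package implementations. These are
# deliberately written with different algorithms/data structures than the
# package code paths they verify.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# walk forward from every ATG position in one orientation
.oracle_scan_one <- function(s, min_len, max_len) {
  L <- nchar(s)
  hits <- list()
  for (i in seq_len(max(L - 2L, 0L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= L && (j - i) + 3L <= max_len) {
      codon <- substr(s, j, j + 2L)
      if (codon %in% ORACLE_STOPS) {
        span <- j + 2L - i + 1L
        if (span >= min_len && span <= max_len)
          hits[[length(hits) + 1L]] <- c(i, j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  hits
}

.oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# brute-force six-frame ORF enumeration on one contig sequence; returns
# forward-strand coordinates sorted like find_orfs()
oracle_orf_scan <- function(seq_char, min_len = 30L, max_len = 300L) {
  L <- nchar(seq_char)
  rows <- list()
  for (h in .oracle_scan_one(seq_char, min_len, max_len))
    rows[[length(rows) + 1L]] <- data.frame(start = h[1], end = h[2],
                                            strand = "+")
  rc <- .oracle_revcomp(seq_char)
  for (h in .oracle_scan_one(rc, min_len, max_len))
    rows[[length(rows) + 1L]] <- data.frame(start = L - h[2] + 1L,
                                            end = L - h[1] + 1L,
                                            strand = "-")
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Exhaustive affine-gap (Gotoh) dynamic programming; returns the optimal
# score only. mode "global" = Needleman-Wunsch, "local" = Smith-Waterman.
oracle_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5,
                               mode = c("global", "local")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (moving along a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
  go <- gap_open + gap_extend        # cost of opening a 1-long gap
  ge <- gap_extend
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -(go + (i - 1) * ge)
    if (mode == "local") M[i + 1, 1] <- 0
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -(go + (j - 1) * ge)
    if (mode == "local") M[1, j + 1] <- 0
  }
  if (mode == "local") {
    X[, 1] <- NEG; Y[1, ] <- NEG
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      diag_best <- max(M[i, j], X[i, j], Y[i, j]) + s
      if (mode == "local") diag_best <- max(diag_best, s, 0)
      M[i + 1, j + 1] <- diag_best
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - ge)
    }
  }
  if (mode == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else max(M, 0)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

dna_assembly <- function(seqs) {
  a <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(a) <- paste0("c", seq_along(seqs))
  a
}

orf_key <- function(d) paste(d$start, d$end, d$strand)

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# quick logistic curve helper
logistic_curve <- function(t, r, K, A0 = 0.1) {
  K / (1 + ((K - A0) / A0) * exp(-r * t))
}
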