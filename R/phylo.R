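# Fetch a Biostrings substitution matrix by name (e.g. "BLOSUM62").
get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

align_stats <- function(aligned_a, aligned_b, query_len, type) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  gapfree <- ca != "-" & cb != "-"
  identity <- if (any(gapfree)) 100 * sum(ca[gapfree] == cb[gapfree]) / sum(gapfree)
              else NA_real_
  coverage <- if (type == "global") 100
              else 100 * sum(ca != "-") / query_len
  list(identity = identity, coverage = coverage)
}

align_pair <- function(a, b, type, substitution = "BLOSUM62",
                       gap_open = 10, gap_extend = 0.5,
                       alphabet = c("aa", "nt"), match = 1, mismatch = -1) {
  alphabet <- match.arg(alphabet)
  stopifnot(nzchar(a), nzchar(b))
  mat <- if (alphabet == "nt")
    Biostrings::nucleotideSubstitutionMatrix(match, mismatch, baseOnly = TRUE)
  else if (is.character(substitution)) get_submat(substitution)
  else substitution
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type, substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  if (type == "global") {
    # alignedPattern/alignedSubject retain terminal gaps
    aligned_a <- as.character(Biostrings::alignedPattern(pa))
    aligned_b <- as.character(Biostrings::alignedSubject(pa))
  } else {
    aligned_a <- as.character(Biostrings::pattern(pa))
    aligned_b <- as.character(Biostrings::subject(pa))
  }
  st <- align_stats(aligned_a, aligned_b, nchar(a), type)
  out <- list(seq_a = a, seq_b = b, aligned_a = aligned_a,
              aligned_b = aligned_b, mode = type,
              score = Biostrings::score(pa),
              identity_percent = st$identity,
              coverage_percent = st$coverage)
  class(out) <- "pairwise_alignment"
  out
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Residue strings (amino acids by default).
#' @param substitution Substitution matrix or its Biostrings name
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (magnitudes; defaults 10, 0.5).
#' @param alphabet `"aa"` (uses `substitution`) or `"nt"` (uses
#'   `match`/`mismatch` scores).
#' @param match,mismatch Nucleotide scores used when `alphabet = "nt"`
#'   (defaults 1, -1).
#' @return A `"pairwise_alignment"`: aligned strings, `score`,
#'   `identity_percent` (over gap-free columns) and `coverage_percent`
#'   (100 for global alignments).
#' @export
global_align <- function(a, b, substitution = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, alphabet = c("aa", "nt"),
                         match = 1, mismatch = -1) {
  align_pair(a, b, "global", substitution, gap_open, gap_extend,
             match.arg(alphabet), match, mismatch)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams global_align
#' @return A `"pairwise_alignment"`; `coverage_percent` is the fraction of
#'   the query (`a`) covered by the aligned region, in percent.
#' @export
local_align <- function(a, b, substitution = "BLOSUM62", gap_open = 10,
                        gap_extend = 0.5, alphabet = c("aa", "nt"),
                        match = 1, mismatch = -1) {
  align_pair(a, b, "local", substitution, gap_open, gap_extend,
             match.arg(alphabet), match, mismatch)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s alignment, score %.1f, identity %.1f%%, coverage %.1f%%\n",
              x$mode, x$score, x$identity_percent, x$coverage_percent))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Observed proportion of differing sites (p-distance)
#'
#' Computed over gap-free columns only (pairwise deletion). Accepts either a
#' `"pairwise_alignment"` or two aligned strings of equal length.
#'
#' @param a A `"pairwise_alignment"` or an aligned string.
#' @param b Second aligned string when `a` is a string.
#' @return The proportion in `[0, 1]`, or `NA` (with a warning) when no
#'   gap-free column exists.
#' @export
p_distance <- function(a, b = NULL) {
  if (inherits(a, "pairwise_alignment")) {
    b <- a$aligned_b
    a <- a$aligned_a
  }
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) {
    warning("no gap-free columns; p-distance undefined")
    return(NA_real_)
  }
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Generalized Jukes-Cantor distance
#'
#' Multiple-hit corrected evolutionary distance for a k-state alphabet:
#' `d = -((k-1)/k) * ln(1 - k*p/(k-1))` (k = 4 for nucleotides, 20 for
#' amino acids). Saturated inputs (`p >= (k-1)/k`) yield `Inf` with a
#' warning.
#'
#' @param p Observed difference proportion(s) in `[0, 1)`.
#' @param k Alphabet size, 4 or 20 (default 4).
#' @return Numeric vector of corrected distances.
#' @export
jukes_cantor <- function(p, k = 4) {
  stopifnot(k %in% c(4, 20), all(p >= 0 | is.na(p)))
  cap <- (k - 1) / k
  d <- ifelse(p >= cap, Inf, -cap * log(1 - p / cap))
  if (any(is.finite(p) & p >= cap))
    warning("saturated p-distance(s) >= ", cap, "; distance set to Inf")
  d
}

# Normalize an MSA given as a named character vector of equal-length strings
# (or a character matrix of residues) to a residue matrix.
msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  stopifnot(!is.null(names(msa)), length(unique(nchar(msa))) == 1L)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Jukes-Cantor distance matrix from a multiple alignment
#'
#' Pairwise p-distances with pairwise deletion of gap columns, corrected by
#' [jukes_cantor()].
#'
#' @param msa Named character vector of equal-length aligned sequences, or a
#'   residue matrix with row names.
#' @param k Alphabet size (default 20 for proteins).
#' @return Symmetric labeled distance matrix (may contain `Inf`/`NA`).
#' @export
jc_distance_matrix <- function(msa, k = 20) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      p <- if (!any(ok)) NA_real_ else sum(m[i, ok] != m[j, ok]) / sum(ok)
      d[i, j] <- d[j, i] <- suppressWarnings(jukes_cantor(p, k))
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler Q
#' criterion. Ties in Q are broken by the lexicographically smallest label
#' index pair; negative branch lengths are clamped to zero with the deficit
#' moved to the sister edge. The result is an unrooted [ape::phylo] tree
#' with a trifurcating root. On additive distance matrices the tree
#' reproduces the generating topology and branch lengths exactly.
#'
#' @param dm Symmetric numeric matrix with labels (or a [stats::dist]).
#' @return An `ape` `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (!all(is.finite(dm))) stop("distance matrix contains non-finite entries")
  D <- dm
  node <- labs
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lexicographically smallest (i, j), i < j, among minima
    qmin <- min(Q)
    best <- NULL
    for (i in 1:(m - 1L)) {
      j_hits <- which(Q[i, (i + 1L):m] == qmin)
      if (length(j_hits) > 0L) {
        best <- c(i, i + j_hits[1L])
        break
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", node[i], ":", fmt(li), ",", node[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
                c(newdist[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
  }
  # final three-point formulas
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- paste0("(", node[1], ":", fmt(l1), ",", node[2], ":", fmt(l2),
                ",", node[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of leaves.
#'
#' @param tree An `ape` `phylo` with branch lengths.
#' @return Symmetric labeled matrix.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  stats::cophenetic(tree)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data tree (pairwise-deletion p-distance, generalized
#' Jukes-Cantor correction, neighbor joining), then resamples alignment
#' columns with replacement `n_reps` times, rebuilds a tree per replicate,
#' and annotates each internal edge of the full tree with the percentage of
#' replicates containing the same bipartition. Replicates producing a
#' saturated or undefined distance are dropped and counted; more than 10%
#' dropped triggers a warning. Deterministic for a fixed `seed`.
#'
#' @param msa Named character vector of aligned sequences (>= 4 rows,
#'   >= 10 columns), or a residue matrix.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param k Alphabet size for the distance correction (default 20).
#' @return A `phylo` with integer `node.label` supports in `[0, 100]`;
#'   attributes `n_used` and `n_dropped`.
#' @export
bootstrap_tree <- function(msa, n_reps = 1000L, seed = 1L, k = 20) {
  m <- msa_matrix(msa)
  stopifnot(nrow(m) >= 4L, ncol(m) >= 10L)
  full_dm <- jc_distance_matrix(m, k)
  if (!all(is.finite(full_dm))) stop("full-data distance matrix is saturated")
  full <- neighbor_joining(full_dm)
  set.seed(seed)
  btrees <- vector("list", n_reps)
  used <- 0L
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    dmb <- jc_distance_matrix(m[, cols, drop = FALSE], k)
    if (!all(is.finite(dmb))) next
    used <- used + 1L
    btrees[[used]] <- neighbor_joining(dmb)
  }
  dropped <- n_reps - used
  if (dropped > 0.1 * n_reps)
    warning(dropped, " of ", n_reps,
            " replicates dropped (saturated/undefined distances)")
  if (used == 0L) stop("all bootstrap replicates dropped")
  btrees <- btrees[seq_len(used)]
  cnt <- ape::prop.clades(full, btrees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  full$node.label <- as.character(as.integer(round(100 * cnt / used)))
  attr(full, "n_used") <- used
  attr(full, "n_dropped") <- dropped
  full
}

#' Select proteins common to a minimum number of species
#'
#' Groups CDSs by identical annotation label and keeps the labels present in
#' at least `min_species` species and in every species of
#' `required_species`. One representative peptide per species per group is
#' chosen (the longest; ties broken by smallest `cds_id`).
#'
#' @param tables Named list (species -> `data.frame` with `cds_id`,
#'   `annotation_label`, `peptide`).
#' @param min_species Minimum number of species carrying the label
#'   (default 8).
#' @param required_species Labels must be present in all of these species
#'   (default none).
#' @return Named list: annotation label -> named character vector
#'   (species -> representative peptide), sorted by label.
#' @export
select_common_proteins <- function(tables, min_species = 8L,
                                   required_species = character(0)) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  presence <- list()
  for (sp in names(tables)) {
    t <- tables[[sp]]
    for (lab in unique(t$annotation_label[nzchar(t$annotation_label)]))
      presence[[lab]] <- union(presence[[lab]], sp)
  }
  keep <- names(presence)[vapply(presence, function(sps)
    length(sps) >= min_species && all(required_species %in% sps),
    logical(1))]
  out <- lapply(sort(keep), function(lab) {
    sps <- sort(presence[[lab]])
    reps <- vapply(sps, function(sp) {
      t <- tables[[sp]]
      cand <- t[t$annotation_label == lab, , drop = FALSE]
      cand <- cand[order(-nchar(cand$peptide), cand$cds_id), , drop = FALSE]
      cand$peptide[1L]
    }, character(1))
    reps
  })
  stats::setNames(out, sort(keep))
}

#' Star multiple alignment
#'
#' Progressive multiple alignment of a protein family: every member is
#' globally aligned to the longest member (ties broken by name), and each
#' pairwise alignment is projected onto the reference columns (positions
#' where the reference takes a gap, i.e. insertions relative to the
#' reference, are discarded). The result is rectangular with width equal to
#' the reference length.
#'
#' @param peptides Named character vector (>= 2 sequences).
#' @param ... Passed to [global_align()].
#' @return Named character vector of equal-length aligned rows.
#' @export
star_align <- function(peptides, ...) {
  stopifnot(length(peptides) >= 2L, !is.null(names(peptides)))
  lens <- nchar(peptides)
  ref_name <- sort(names(peptides)[lens == max(lens)])[1L]
  ref <- peptides[[ref_name]]
  out <- stats::setNames(character(length(peptides)), names(peptides))
  out[ref_name] <- ref
  for (nm in setdiff(names(peptides), ref_name)) {
    al <- global_align(ref, peptides[[nm]], ...)
    ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    out[nm] <- paste(cb[ca != "-"], collapse = "")
  }
  out
}

#' Concatenate per-group alignments
#'
#' Row-wise concatenation of rectangular alignments over an identical
#' species set, in sorted group-label order.
#'
#' @param alignments Named list of named character vectors (each an MSA over
#'   the same species).
#' @return Named character vector; width = sum of group widths.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  species <- sort(names(alignments[[1L]]))
  for (g in names(alignments)) {
    if (!identical(sort(names(alignments[[g]])), species))
      stop("species set mismatch in group: ", g)
    if (length(unique(nchar(alignments[[g]]))) != 1L)
      stop("alignment not rectangular in group: ", g)
  }
  out <- stats::setNames(rep("", length(species)), species)
  for (g in sort(names(alignments)))
    out <- paste0(out, alignments[[g]][species])
  stats::setNames(out, species)
}
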