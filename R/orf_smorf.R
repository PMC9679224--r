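STOP_CODONS <- c("TAA", "TAG", "TGA")

# Scan one sequence (already in the orientation to be read) for ATG..stop
# spans in frames 0..2. Returns local 1-based start/end (including the stop
# codon) and the frame.
scan_frames <- function(seq_char, min_len, max_len) {
  L <- nchar(seq_char)
  out <- list()
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3L
    if (n_codon * 3L < min_len) next
    cs <- seq.int(f + 1L, by = 3L, length.out = n_codon)
    codons <- substring(seq_char, cs, cs + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (length(atg) == 0L || length(stp) == 0L) next
    # first in-frame stop at or after each ATG
    k <- findInterval(atg - 1L, stp) + 1L
    ok <- k <= length(stp)
    atg <- atg[ok]; k <- k[ok]
    if (length(atg) == 0L) next
    span <- (stp[k] - atg + 1L) * 3L
    keep <- span >= min_len & span <= max_len
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      lstart = f + (atg[keep] - 1L) * 3L + 1L,
      lend = f + stp[k[keep]] * 3L,
      frame = f
    )
  }
  if (length(out) == 0L)
    data.frame(lstart = integer(0), lend = integer(0), frame = integer(0))
  else do.call(rbind, out)
}

#' Find small open reading frames in all six frames
#'
#' An ORF is an in-frame `ATG` followed by the first in-frame stop codon
#' (`TAA`/`TAG`/`TGA`), with total span (stop included) within
#' `[min_len, max_len]`. Every qualifying ATG is reported, including ATGs
#' nested inside a longer ORF of the same frame (report-all policy). Both
#' strands are scanned; coordinates are always reported on the forward
#' strand, `frame` is the offset (0-2) in the strand actually read, and
#' `nt_seq`/`peptide` are in the sense of the ORF.
#'
#' @param assembly A named `DNAStringSet`.
#' @param min_len,max_len Inclusive span bounds in nucleotides, both
#'   divisible by 3. Defaults 30 and 300 nt.
#' @return A `data.frame` with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `nt_seq`, `peptide` (stop stripped) and `position_class`
#'   (`NA` until [classify_smorfs()] is applied).
#' @export
find_orfs <- function(assembly, min_len = 30L, max_len = 300L) {
  stopifnot(min_len <= max_len, min_len %% 3L == 0L, max_len %% 3L == 0L,
            min_len >= 6L)
  rows <- list()
  for (i in seq_along(assembly)) {
    cid <- names(assembly)[i]
    fwd <- as.character(assembly[[i]])
    L <- nchar(fwd)
    if (L < min_len) next
    rev <- as.character(Biostrings::reverseComplement(assembly[[i]]))

    hf <- scan_frames(fwd, min_len, max_len)
    if (nrow(hf) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, start = hf$lstart, end = hf$lend, strand = "+",
        frame = hf$frame, nt_seq = substring(fwd, hf$lstart, hf$lend),
        stringsAsFactors = FALSE
      )
    }
    hr <- scan_frames(rev, min_len, max_len)
    if (nrow(hr) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, start = L - hr$lend + 1L, end = L - hr$lstart + 1L,
        strand = "-", frame = hr$frame,
        nt_seq = substring(rev, hr$lstart, hr$lend),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), nt_seq = character(0),
                      peptide = character(0), position_class = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$start, out$end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$peptide <- strip_stop(translate_many(out$nt_seq))
  out$position_class <- NA_character_
  out
}

# strand-aware flanking windows of a CDS table; rows with zero width dropped
flank_windows <- function(cds, window, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  left_of_start <- (cds$strand == "+") == (side == "upstream")
  start <- ifelse(left_of_start, pmax(1L, cds$start - window), cds$end + 1L)
  end <- ifelse(left_of_start, cds$start - 1L, cds$end + window)
  keep <- end >= start
  data.frame(contig_id = cds$contig_id[keep], start = start[keep],
             end = end[keep], cds_id = cds$cds_id[keep],
             stringsAsFactors = FALSE)
}

# indices of orfs fully contained in any interval of tbl (same contig);
# returns the containing interval's cds_id chosen by smallest gap to the
# interval's nearest boundary
contained_in <- function(orfs, tbl) {
  hit_cds <- rep(NA_character_, nrow(orfs))
  if (nrow(tbl) == 0L || nrow(orfs) == 0L) return(hit_cds)
  for (ctg in intersect(unique(orfs$contig_id), unique(tbl$contig_id))) {
    oi <- which(orfs$contig_id == ctg)
    ti <- which(tbl$contig_id == ctg)
    q <- IRanges::IRanges(orfs$start[oi], orfs$end[oi])
    s <- IRanges::IRanges(tbl$start[ti], tbl$end[ti])
    ov <- IRanges::findOverlaps(q, s, type = "within")
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    # nearest-boundary tie-break among multiple containing intervals
    dist <- pmin(orfs$start[oi][qh] - tbl$start[ti][sh],
                 tbl$end[ti][sh] - orfs$end[oi][qh])
    ord <- order(qh, dist, tbl$cds_id[ti][sh])
    first <- !duplicated(qh[ord])
    hit_cds[oi[qh[ord][first]]] <- tbl$cds_id[ti][sh[ord][first]]
  }
  hit_cds
}

#' Classify smORFs by position relative to CDSs
#'
#' Assigns each ORF exactly one positional class: `CDSSmORF` if the ORF
#' interval is fully contained in a CDS interval on the same contig
#' (strand-agnostic), else `5'SmORF` if fully within `window` nt upstream of
#' a CDS (upstream defined by the CDS strand), else `3'SmORF` if fully
#' within `window` nt downstream, else `intergenic`. Precedence is
#' CDS > 5' > 3'; when several CDSs qualify the one with the nearest
#' boundary is recorded in `cds_id`.
#'
#' @param orfs Output of [find_orfs()].
#' @param cds A CDS `data.frame` (see [read_cds_gff3()]).
#' @param window Flanking window size in nt (default 1000).
#' @return `orfs` with `position_class` filled in and a `cds_id` column
#'   naming the associated CDS (`NA` for intergenic).
#' @export
classify_smorfs <- function(orfs, cds, window = 1000L) {
  orfs$position_class <- rep("intergenic", nrow(orfs))
  orfs$cds_id <- rep(NA_character_, nrow(orfs))
  if (nrow(orfs) == 0L || is.null(cds) || nrow(cds) == 0L) return(orfs)

  inside <- contained_in(orfs, cds[, c("contig_id", "start", "end", "cds_id")])
  hit <- !is.na(inside)
  orfs$position_class[hit] <- "CDSSmORF"
  orfs$cds_id[hit] <- inside[hit]

  todo <- is.na(orfs$cds_id)
  up <- contained_in(orfs[todo, , drop = FALSE],
                     flank_windows(cds, window, "upstream"))
  orfs$position_class[todo][!is.na(up)] <- "5'SmORF"
  orfs$cds_id[todo][!is.na(up)] <- up[!is.na(up)]

  todo <- is.na(orfs$cds_id)
  down <- contained_in(orfs[todo, , drop = FALSE],
                       flank_windows(cds, window, "downstream"))
  orfs$position_class[todo][!is.na(down)] <- "3'SmORF"
  orfs$cds_id[todo][!is.na(down)] <- down[!is.na(down)]
  orfs
}

#' Count sequences shared between two smORF sets
#'
#' Number of distinct sequences (nucleotide or translated) present in both
#' sets; multiplicity within a set is ignored.
#'
#' @param set_a,set_b smORF `data.frame`s (see [find_orfs()]).
#' @param level `"peptide"` or `"nucleotide"`.
#' @return Integer count.
#' @export
count_shared_smorfs <- function(set_a, set_b,
                                level = c("peptide", "nucleotide")) {
  level <- match.arg(level)
  col <- if (level == "peptide") "peptide" else "nt_seq"
  length(intersect(unique(set_a[[col]]), unique(set_b[[col]])))
}

#' Match smORF peptides against a reference set
#'
#' Each query peptide is locally aligned (Smith-Waterman, see
#' [local_align()]) against every reference peptide; matches are reported
#' when percent identity over aligned columns and query coverage both meet
#' their thresholds. The highest-scoring match per query is flagged.
#'
#' @param queries smORF `data.frame` with a `peptide` column; row identity is
#'   taken from a `query_id` column if present, else `contig:start-end`.
#' @param reference `data.frame` with columns `id` and `peptide`.
#' @param min_identity,min_coverage Thresholds in percent (defaults 50).
#' @param ... Passed to [local_align()] (substitution matrix, gap costs).
#' @return A `data.frame` with columns `query_id`, `reference_id`,
#'   `identity_percent`, `coverage_percent`, `score`, `best_hit`.
#' @export
match_smorfs <- function(queries, reference, min_identity = 50,
                         min_coverage = 50, ...) {
  stopifnot(nrow(reference) > 0L)
  qid <- if ("query_id" %in% names(queries)) queries$query_id
         else paste0(queries$contig_id, ":", queries$start, "-", queries$end)
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    qpep <- queries$peptide[i]
    if (!nzchar(qpep)) {
      warning("empty query peptide skipped: ", qid[i])
      next
    }
    hits <- lapply(seq_len(nrow(reference)), function(j) {
      al <- local_align(qpep, reference$peptide[j], ...)
      data.frame(query_id = qid[i], reference_id = reference$id[j],
                 identity_percent = al$identity_percent,
                 coverage_percent = al$coverage_percent, score = al$score,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    hits <- hits[hits$identity_percent >= min_identity &
                 hits$coverage_percent >= min_coverage, , drop = FALSE]
    if (nrow(hits) > 0L) {
      hits$best_hit <- seq_len(nrow(hits)) == which.max(hits$score)
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(0), reference_id = character(0),
                      identity_percent = numeric(0),
                      coverage_percent = numeric(0), score = numeric(0),
                      best_hit = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
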