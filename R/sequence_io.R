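#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are upper-cased and any symbol outside `{A,C,G,T,N}` is replaced
#' by `N` (with a warning reporting how many symbols were masked). Contig
#' identifiers are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` whose names are the contig identifiers.
#' @export
read_genome_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA contains no records: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate contig identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs))) stop("FASTA contains empty sequences")
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN symbol(s) replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A named `DNAStringSet` (see [read_genome_fasta()]).
#' @param path Output file path. Sequences are wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly, path, width = 80L)
  invisible(path)
}

#' Assembly-level genome statistics
#'
#' Computes contig count, total length and GC content. GC is computed as
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from both the
#' numerator and the denominator. An assembly with no informative (ACGT)
#' bases gets `NA` GC.
#'
#' @param assembly A named `DNAStringSet`.
#' @return A one-row `data.frame` with columns `n_contigs`, `total_length_bp`
#'   and `gc_percent`.
#' @export
genome_stats <- function(assembly) {
  if (length(assembly) == 0L) stop("empty assembly")
  freq <- Biostrings::letterFrequency(assembly, letters = c("A", "C", "G", "T"))
  tot <- colSums(freq)
  informative <- sum(tot)
  gc <- if (informative == 0) NA_real_ else
    100 * (tot[["G"]] + tot[["C"]]) / informative
  if (is.na(gc)) warning("assembly contains no ACGT bases; GC undefined")
  data.frame(
    n_contigs = length(assembly),
    total_length_bp = sum(Biostrings::width(assembly)),
    gc_percent = gc,
    row.names = NULL
  )
}

#' Translate a nucleotide string
#'
#' Standard genetic code. A trailing partial codon is dropped, stop codons
#' are rendered as `*` (no read-through) and any codon containing `N`
#' translates to `X`.
#'
#' @param nt A nucleotide string over `{A,C,G,T,N}`.
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return The translated amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt, frame = 0L) {
  stopifnot(length(nt) == 1L, frame %in% 0:2)
  s <- substr(nt, frame + 1L, nchar(nt))
  len <- (nchar(s) %/% 3L) * 3L
  if (len == 0L) return("")
  s <- substr(s, 1L, len)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# Vectorized translation used by the ORF scanner; input lengths must be
# multiples of 3.
translate_many <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

# Strip one terminal stop symbol, if present.
strip_stop <- function(pep) sub("\\*$", "", pep)

#' Read CDS records from GFF3
#'
#' Imports `CDS` features from a GFF3 file and derives each peptide from the
#' assembly (reverse-complementing minus-strand features before translation).
#' Records whose coordinates extend past the contig end, whose length is not
#' divisible by 3, or whose contig is absent from the assembly are rejected
#' with a warning. The attribute keys `product` and `pathway` populate
#' `annotation_label` and `pathway_labels` (the latter a list column; GFF3
#' multi-values separated by commas are split).
#'
#' @param path Path to a GFF3 file.
#' @param assembly A named `DNAStringSet` covering the annotated contigs.
#' @return A `data.frame` with columns `cds_id`, `contig_id`, `start`, `end`,
#'   `strand`, `peptide`, `annotation_label` and the list column
#'   `pathway_labels`. Coordinates are 1-based inclusive on the forward
#'   strand; peptides have the terminal stop stripped.
#' @export
read_cds_gff3 <- function(path, assembly) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  empty <- data.frame(
    cds_id = character(0), contig_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    peptide = character(0), annotation_label = character(0),
    stringsAsFactors = FALSE
  )
  empty$pathway_labels <- list()
  if (length(gr) == 0L) return(empty)

  mc <- GenomicRanges::mcols(gr)
  ids <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
         else paste0("cds_", seq_along(gr))
  ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))
  contig <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"

  clen <- stats::setNames(Biostrings::width(assembly), names(assembly))
  ok <- rep(TRUE, length(gr))
  bad_contig <- !(contig %in% names(clen))
  bad_coord <- !bad_contig & (start < 1L | end > clen[contig])
  bad_len <- (end - start + 1L) %% 3L != 0L
  drop <- bad_contig | bad_coord | bad_len
  if (any(drop)) {
    warning(sum(drop), " CDS record(s) rejected (",
            sum(bad_contig), " unknown contig, ",
            sum(bad_coord, na.rm = TRUE), " out of bounds, ",
            sum(bad_len & !bad_contig & !bad_coord), " length not divisible by 3)")
  }
  keep <- which(!drop)
  if (length(keep) == 0L) return(empty)

  nt <- vapply(keep, function(i) {
    s <- Biostrings::subseq(assembly[[contig[i]]], start[i], end[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  pep <- strip_stop(translate_many(nt))

  label <- if ("product" %in% names(mc)) {
    x <- as.character(mc$product)[keep]; x[is.na(x)] <- ""; x
  } else rep("", length(keep))
  pw <- if ("pathway" %in% names(mc)) {
    raw <- mc$pathway[keep]
    lapply(seq_along(raw), function(i) {
      v <- raw[[i]]
      if (length(v) == 0L || all(is.na(v))) character(0)
      else unlist(strsplit(as.character(v), ",", fixed = TRUE), use.names = FALSE)
    })
  } else rep(list(character(0)), length(keep))

  out <- data.frame(
    cds_id = ids[keep], contig_id = contig[keep],
    start = start[keep], end = end[keep], strand = strand[keep],
    peptide = pep, annotation_label = label,
    stringsAsFactors = FALSE
  )
  out$pathway_labels <- pw
  out
}

#' Write CDS records to GFF3
#'
#' Inverse of [read_cds_gff3()] for the columns this pipeline uses. Commas in
#' annotation labels are percent-encoded; pathway labels are written as a
#' comma-separated multi-value `pathway` attribute.
#'
#' @param cds A CDS `data.frame` (see [read_cds_gff3()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_gff3 <- function(cds, path) {
  enc <- function(x) gsub(";", "%3B", gsub(",", "%2C", gsub("=", "%3D", x)))
  attrs <- vapply(seq_len(nrow(cds)), function(i) {
    a <- paste0("ID=", enc(cds$cds_id[i]))
    if (nzchar(cds$annotation_label[i]))
      a <- paste0(a, ";product=", enc(cds$annotation_label[i]))
    pw <- cds$pathway_labels[[i]]
    if (length(pw) > 0L)
      a <- paste0(a, ";pathway=", paste(enc(pw), collapse = ","))
    a
  }, character(1))
  lines <- c("##gff-version 3",
             paste(cds$contig_id, "coldadapt", "CDS", cds$start, cds$end,
                   ".", cds$strand, "0", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
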