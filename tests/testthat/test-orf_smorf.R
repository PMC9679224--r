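test_that("a minimal 30-nt ORF is found, and on both strands", {
  s <- paste0("ATG", strrep("GCT", 8), "TAA")
  expect_equal(nchar(s), 30L)
  orfs <- find_orfs(dna_assembly(c(c1 = s)))
  fwd <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(c(fwd$start, fwd$end), c(1L, 30L))
  expect_equal(fwd$peptide, paste0("M", strrep("A", 8)))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  orfs_rc <- find_orfs(dna_assembly(c(c1 = rc)))
  rev <- orfs_rc[orfs_rc$strand == "-", ]
  expect_equal(nrow(rev), 1L)
  expect_equal(c(rev$start, rev$end), c(1L, 30L))
  expect_equal(rev$nt_seq, s)
})

test_that("contigs shorter than min_len yield no ORFs without error", {
  expect_equal(nrow(find_orfs(dna_assembly(c(c1 = "ATGTAA")))), 0L)
})

test_that("length bounds include the stop codon and are respected", {
  long <- paste0("ATG", strrep("GCT", 99), "TAA")  # 303 nt: too long
  expect_equal(nrow(find_orfs(dna_assembly(c(c1 = long)))[
    find_orfs(dna_assembly(c(c1 = long)))$strand == "+", ]), 0L)
  expect_equal(nrow(find_orfs(dna_assembly(c(c1 = long)),
                              max_len = 303)[1, ]), 1L)
})

test_that("scanner equals brute-force six-frame enumeration on random contigs", {
  set.seed(21)
  for (i in 1:15) {
    s <- random_dna(5000, gc = runif(1, 0.4, 0.6))
    imp <- find_orfs(dna_assembly(c(c1 = s)))
    ora <- oracle_orf_scan(s)
    expect_identical(orf_key(imp), orf_key(ora))
  }
})

make_cds <- function(contig, start, end, strand, id = "cdsA") {
  d <- data.frame(cds_id = id, contig_id = contig, start = start, end = end,
                  strand = strand, peptide = "M", annotation_label = "x",
                  stringsAsFactors = FALSE)
  d$pathway_labels <- list(character(0))
  d
}

make_orf <- function(start, end, contig = "c1") {
  data.frame(contig_id = contig, start = start, end = end, strand = "+",
             frame = 0L, nt_seq = "", peptide = "",
             position_class = NA_character_, stringsAsFactors = FALSE)
}

test_that("positional classes follow containment, windows and precedence", {
  cds <- make_cds("c1", 2000, 3000, "+")
  cl <- function(orf) classify_smorfs(orf, cds)$position_class
  expect_equal(cl(make_orf(2100, 2189)), "CDSSmORF")
  expect_equal(cl(make_orf(1500, 1559)), "5'SmORF")
  expect_equal(cl(make_orf(3200, 3259)), "3'SmORF")
  expect_equal(cl(make_orf(500, 559)), "intergenic")
  # straddling a boundary is not containment
  expect_equal(cl(make_orf(1990, 2049)), "intergenic")

  # upstream is rightward on the minus strand
  cds_m <- make_cds("c1", 2000, 3000, "-")
  expect_equal(classify_smorfs(make_orf(3200, 3259), cds_m)$position_class,
               "5'SmORF")
  expect_equal(classify_smorfs(make_orf(1500, 1559), cds_m)$position_class,
               "3'SmORF")

  # empty CDS table: everything intergenic
  expect_equal(classify_smorfs(make_orf(10, 39), cds[0, ])$position_class,
               "intergenic")
})

test_that("classification assigns exactly one class per ORF", {
  set.seed(31)
  spec <- synthetic_spec(seed = 31)
  g <- generate_genome(spec, "G_martinii")
  orfs <- find_orfs(g$assembly)
  cls <- classify_smorfs(orfs, g$cds)
  expect_true(all(cls$position_class %in%
                  c("CDSSmORF", "5'SmORF", "3'SmORF", "intergenic")))
  expect_equal(nrow(cls), nrow(orfs))
})

test_that("shared-smORF counts are distinct-sequence based and symmetric", {
  a <- data.frame(peptide = c("MAA", "MCC", "MCC"), nt_seq = "x")
  b <- data.frame(peptide = c("MDD", "MEE"), nt_seq = "x")
  expect_equal(count_shared_smorfs(a, b), 0L)
  expect_equal(count_shared_smorfs(a, a), 2L)
  b2 <- data.frame(peptide = c("MCC", "MAA", "MAA", "MFF"), nt_seq = "y")
  expect_equal(count_shared_smorfs(a, b2), 2L)
  expect_equal(count_shared_smorfs(b2, a), count_shared_smorfs(a, b2))
  # nucleotide level uses nt_seq
  expect_equal(count_shared_smorfs(a, b2, level = "nucleotide"), 0L)
})

test_that("smORF matching applies identity and coverage thresholds", {
  q <- data.frame(contig_id = "c1", start = 1, end = 30, strand = "+",
                  frame = 0, nt_seq = "", peptide = "MARNDCEQGH",
                  stringsAsFactors = FALSE)
  ref <- data.frame(id = c("hit", "far"),
                    peptide = c("MARNDCEQGH", "WWWWYYYYFF"),
                    stringsAsFactors = FALSE)
  m <- match_smorfs(q, ref)
  expect_equal(m$reference_id, "hit")
  expect_equal(m$identity_percent, 100)
  expect_equal(m$coverage_percent, 100)
  expect_true(m$best_hit)

  # raising thresholds never increases the number of matches
  set.seed(41)
  qs <- data.frame(contig_id = "c1", start = 1:5, end = 2:6, strand = "+",
                   frame = 0, nt_seq = "",
                   peptide = vapply(1:5, function(i)
                     paste(sample(c("A", "R", "N", "D", "C"), 12, TRUE),
                           collapse = ""), character(1)),
                   stringsAsFactors = FALSE)
  refs <- data.frame(id = paste0("r", 1:4),
                     peptide = vapply(1:4, function(i)
                       paste(sample(c("A", "R", "N", "D", "C"), 12, TRUE),
                             collapse = ""), character(1)),
                     stringsAsFactors = FALSE)
  n50 <- nrow(match_smorfs(qs, refs, min_identity = 50))
  n70 <- nrow(match_smorfs(qs, refs, min_identity = 70))
  n90 <- nrow(match_smorfs(qs, refs, min_identity = 90))
  expect_true(n70 <= n50)
  expect_true(n90 <= n70)

  # empty query peptides are skipped with a warning
  q_empty <- q
  q_empty$peptide <- ""
  expect_warning(m2 <- match_smorfs(q_empty, ref), "empty query")
  expect_equal(nrow(m2), 0L)
})
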