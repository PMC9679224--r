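test_that("pairwise alignments match their exhaustive DP oracle", {
  bl <- blosum62()
  al <- global_align("MA", "MA")
  expect_equal(al$identity_percent, 100)
  expect_equal(al$aligned_a, "MA")

  # nucleotide mode with linear gap cost 2
  al_nt <- global_align("ACGT", "AGT", alphabet = "nt", gap_open = 0,
                        gap_extend = 2)
  nt_mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  expect_equal(al_nt$score,
               oracle_align_score("ACGT", "AGT", nt_mat, 0, 2, "global"))
  expect_equal(nchar(al_nt$aligned_a), 4L)

  set.seed(17)
  aa <- rownames(bl)[1:20]
  for (i in 1:40) {
    a <- paste(sample(aa, 8, TRUE), collapse = "")
    b <- paste(sample(aa, 8, TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 oracle_align_score(a, b, bl, 10, 0.5, "global"))
    expect_equal(local_align(a, b)$score,
                 oracle_align_score(a, b, bl, 10, 0.5, "local"))
    # score symmetry
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("local alignment of an embedded query has full coverage", {
  al <- local_align("CDEFWY", "AAAAACDEFWYGGGGG")
  expect_equal(al$identity_percent, 100)
  expect_equal(al$coverage_percent, 100)
})

test_that("p-distance uses pairwise deletion of gap columns", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("A-CT", "AGCT"), 0)        # 3 usable columns
  expect_equal(p_distance("A-CT", "AGCA"), 1 / 3)
  expect_warning(expect_true(is.na(p_distance("--", "AA"))), "gap-free")
})

test_that("generalized Jukes-Cantor matches its closed form", {
  expect_equal(jukes_cantor(0, 4), 0)
  expect_equal(jukes_cantor(0.3, 4), -0.75 * log(1 - 0.3 / 0.75))
  expect_equal(jukes_cantor(0.3, 4), 0.3831, tolerance = 1e-4)
  expect_equal(jukes_cantor(0.05, 20), -0.95 * log(1 - 0.05 / 0.95))
  expect_equal(jukes_cantor(0.05, 20), 0.0514, tolerance = 1e-3)
  expect_warning(expect_equal(jukes_cantor(0.8, 4), Inf), "saturated")
  # strictly increasing, and d ~ p for small p
  p <- seq(0.001, 0.7, by = 0.01)
  d <- jukes_cantor(p, 4)
  expect_true(all(diff(d) > 0))
  expect_equal(jukes_cantor(1e-6, 20) / 1e-6, 1, tolerance = 1e-4)
})

test_that("neighbor joining solves the three-taxon case exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pm <- patristic_matrix(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(pm), unname(d), tolerance = 1e-12)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive matrices exactly", {
  for (i in 1:25) {
    n <- 5 + (i %% 4)
    t0 <- random_tree(n, c(0.05, 0.4), seed = 1000 + i)
    dm <- patristic_matrix(t0)
    t1 <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(t0), t1), 0, ignore_attr = TRUE)
    pm <- patristic_matrix(t1)[rownames(dm), colnames(dm)]
    expect_equal(pm, dm, tolerance = 1e-9)
    # independent cross-check against ape's implementation
    expect_equal(ape::dist.topo(t1, ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining is invariant to label order", {
  t0 <- random_tree(6, c(0.05, 0.3), seed = 5)
  dm <- patristic_matrix(t0)
  perm <- sample(rownames(dm))
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("patristic distances invert the tree construction", {
  # star tree with unit branches: all leaves at distance 2
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  pm <- patristic_matrix(star)
  expect_true(all(pm[upper.tri(pm)] == 2))
  expect_error(patristic_matrix(ape::read.tree(text = "(a,b,c);")),
               "branch lengths")
})

test_that("bootstrap supports are deterministic and bounded", {
  tr0 <- random_tree(6, c(0.05, 0.2), seed = 3)
  ev <- evolve_proteins(tr0, random_peptide(150, seed = 4), rate = 1,
                        seed = 5)
  b1 <- bootstrap_tree(ev$peptides, n_reps = 50, seed = 9)
  b2 <- bootstrap_tree(ev$peptides, n_reps = 50, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
  sup <- as.integer(b1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  # a single replicate can only give 0 or 100
  b3 <- bootstrap_tree(ev$peptides, n_reps = 1, seed = 2)
  expect_true(all(as.integer(b3$node.label) %in% c(0L, 100L)))
})

test_that("a strongly supported split gets high bootstrap support", {
  # two clades separated by many exclusive conserved columns (kept below
  # the Jukes-Cantor saturation threshold)
  left <- paste(rep("A", 60), collapse = "")
  right <- paste(c(rep("A", 30), rep("W", 30)), collapse = "")
  jitter <- function(s, k, seed) {
    set.seed(seed)
    x <- strsplit(s, "")[[1]]
    idx <- sample(length(x), k)
    x[idx] <- sample(c("C", "D", "E", "F", "G"), k, TRUE)
    paste(x, collapse = "")
  }
  msa <- c(l1 = jitter(left, 3, 1), l2 = jitter(left, 3, 2),
           l3 = jitter(left, 3, 3), r1 = jitter(right, 3, 4),
           r2 = jitter(right, 3, 5), r3 = jitter(right, 3, 6))
  bt <- bootstrap_tree(msa, n_reps = 100, seed = 11)
  split_leaves <- function(tree, node) {
    tips <- ape::extract.clade(tree, node)$tip.label
    sort(tips)
  }
  # find the internal edge separating l* from r*
  sup <- NA
  for (nd in (length(msa) + 1):(length(msa) + bt$Nnode)) {
    tips <- tryCatch(split_leaves(bt, nd), error = function(e) NULL)
    if (!is.null(tips) &&
        (identical(tips, c("l1", "l2", "l3")) ||
         identical(tips, c("r1", "r2", "r3"))))
      sup <- as.integer(bt$node.label[nd - length(msa)])
  }
  expect_false(is.na(sup))
  expect_true(sup >= 95)
})

test_that("common-protein selection honors presence and required species", {
  tabs <- list()
  for (i in 1:10) {
    labs <- c("ubiquitous", if (i <= 8) "common8", if (i <= 5) "rare")
    tabs[[paste0("sp", i)]] <- data.frame(
      cds_id = paste0("c", seq_along(labs)),
      annotation_label = labs,
      peptide = strrep("MA", 5 + i),
      stringsAsFactors = FALSE)
  }
  sel <- select_common_proteins(tabs, min_species = 8)
  expect_equal(names(sel), c("common8", "ubiquitous"))
  expect_equal(length(sel$ubiquitous), 10L)
  # required species missing from the label's carriers
  sel2 <- select_common_proteins(tabs, min_species = 8,
                                 required_species = "sp9")
  expect_equal(names(sel2), "ubiquitous")
  # longest peptide is the representative
  expect_equal(sel$ubiquitous[["sp10"]], strrep("MA", 15))
})

test_that("star alignment is rectangular and concatenation is additive", {
  peps <- c(s1 = "MARNDCEQGH", s2 = "MARNDEQGH", s3 = "MARNDCEQG")
  msa <- star_align(peps)
  expect_equal(unique(nchar(msa)), 10L)
  expect_equal(msa[["s1"]], peps[["s1"]])

  cc <- concatenate_alignments(list(g2 = msa, g1 = msa))
  expect_equal(unique(nchar(cc)), 20L)
  # sorted group order: g1 first
  expect_equal(substr(cc[["s2"]], 1, 10), msa[["s2"]])
  bad <- list(g1 = msa, g2 = msa[c("s1", "s2")])
  expect_error(concatenate_alignments(bad), "g2")

  # concatenation order does not change the NJ topology
  t0 <- random_tree(6, c(0.05, 0.2), seed = 21)
  ev <- evolve_proteins(t0, random_peptide(120, seed = 22), seed = 23)
  msa6 <- ev$peptides
  c1 <- concatenate_alignments(list(a = msa6, b = msa6))
  n1 <- neighbor_joining(jc_distance_matrix(c1))
  n2 <- neighbor_joining(jc_distance_matrix(msa6))
  expect_equal(ape::dist.topo(n1, n2), 0, ignore_attr = TRUE)
})
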