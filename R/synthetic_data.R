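AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PATHWAY_POOL <- c("glycolysis", "TCA cycle", "MAPK signaling", "cell cycle",
                  "ribosome", "spliceosome", "autophagy",
                  "carbohydrate metabolism", "amino acid metabolism",
                  "transport and catabolism")

SMORF_CLASSES <- c("CDSSmORF", "5'SmORF", "3'SmORF", "intergenic")

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + salt) %% 2147483000L
}

#' Specification of a synthetic comparative-genomics study
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the study conditions of a four-species Alpine-yeast comparison:
#' optimal growth temperatures of 20/10/15/15 degC, peak growth rates of
#' 0.1579/0.0726/0.0736/0.175 per day, GC contents spanning 50.9-61.2%,
#' A600 inoculum 0.1 read daily for 10 days in triplicate at
#' 4-30 degC, and hundreds-of-copies gene redundancy concentrated in a few
#' protein families. Genome scale is reduced (two contigs of 80 kb per
#' species) so that a full run stays interactive.
#'
#' @param seed Integer master seed; all generator output is a deterministic
#'   function of (spec, seed).
#' @param species Character vector of species identifiers.
#' @param contigs_per_species,contig_length_bp Assembly shape.
#' @param gc_target Background GC fraction(s) in (0,1); scalar or one per
#'   species.
#' @param n_cds Background CDS count per species (redundant-family copies
#'   are added on top).
#' @param cds_length_range Min/max CDS length in codons (stop included).
#' @param vf_effect Named additive shift (percentage points / 100) of the
#'   expected very-flexible residue fraction per species; baseline 0.30.
#' @param planted_smorfs Named integer vector of planted smORF counts per
#'   positional class (`CDSSmORF`, `5'SmORF`, `3'SmORF`, `intergenic`).
#' @param redundant_families Named integer vector: annotation label ->
#'   number of CDS copies planted per species.
#' @param growth List: `temps` (degC), `otg_true` and `r_peak` (named per
#'   species), `noise_sd`, `replicates`, `days`, `a0`, `k_range` (logistic
#'   carrying-capacity range), `halfwidth` (viability half-width, degC).
#' @param tree_spec List: `n_taxa`, `bl_range` (branch-length range),
#'   `rate` (substitutions per site per unit branch length).
#' @return Object of class `"synthetic_spec"` (a validated list).
#' @export
synthetic_spec <- function(
    seed = 1L,
    species = c("G_gilvescens", "G_martinii", "N_antarctica", "P_glacialis"),
    contigs_per_species = 2L,
    contig_length_bp = 80000L,
    gc_target = c(G_gilvescens = 0.509, G_martinii = 0.55,
                  N_antarctica = 0.55, P_glacialis = 0.612),
    n_cds = 24L,
    cds_length_range = c(70L, 180L),
    vf_effect = NULL,
    planted_smorfs = c("CDSSmORF" = 4L, "5'SmORF" = 4L, "3'SmORF" = 4L,
                       "intergenic" = 4L),
    redundant_families = c(
      "P-loop containing nucleoside triphosphate hydrolase" = 7L,
      "alpha/beta hydrolase" = 5L,
      "major facilitator superfamily protein" = 4L,
      "armadillo repeat-containing protein" = 3L),
    growth = list(
      temps = c(4, 10, 15, 20, 25, 30),
      otg_true = c(G_gilvescens = 20, G_martinii = 10,
                   N_antarctica = 15, P_glacialis = 15),
      r_peak = c(G_gilvescens = 0.1579, G_martinii = 0.0726,
                 N_antarctica = 0.0736, P_glacialis = 0.175),
      noise_sd = 0.01, replicates = 3L, days = 10L, a0 = 0.1,
      k_range = c(2.5, 3.5), halfwidth = 12),
    tree_spec = list(n_taxa = 8L, bl_range = c(0.02, 0.25), rate = 1)) {
  if (is.null(vf_effect)) vf_effect <- stats::setNames(rep(0, length(species)),
                                                       species)
  if (length(gc_target) == 1L)
    gc_target <- stats::setNames(rep(gc_target, length(species)), species)
  stopifnot(
    length(species) >= 1L, contigs_per_species >= 1L,
    contig_length_bp >= 5000L,
    all(gc_target > 0 & gc_target < 1),
    all(species %in% names(gc_target)),
    n_cds >= 1L, cds_length_range[1] >= 12L,
    cds_length_range[1] <= cds_length_range[2],
    all(names(planted_smorfs) %in% SMORF_CLASSES),
    all(vf_effect > -0.3 & vf_effect < 0.7),
    all(species %in% names(vf_effect)),
    all(species %in% names(growth$otg_true)),
    all(species %in% names(growth$r_peak))
  )
  out <- list(seed = as.integer(seed), species = species,
              contigs_per_species = as.integer(contigs_per_species),
              contig_length_bp = as.integer(contig_length_bp),
              gc_target = gc_target, n_cds = as.integer(n_cds),
              cds_length_range = as.integer(cds_length_range),
              vf_effect = vf_effect, planted_smorfs = planted_smorfs,
              redundant_families = redundant_families, growth = growth,
              tree_spec = tree_spec)
  class(out) <- "synthetic_spec"
  out
}

# residue sampling distribution: uniform 1/20 baseline with extra mass
# `shift` moved onto the very-flexible residues
aa_probs <- function(shift) {
  p <- stats::setNames(rep(0.05, 20), AA20)
  p[VF_RESIDUES] <- (0.30 + shift) / 6
  others <- setdiff(AA20, VF_RESIDUES)
  p[others] <- p[others] * (0.70 - shift) / 0.70
  p
}

# codon table inverted once
aa_to_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

sample_peptide <- function(n_res, probs) {
  paste(c("M", sample(AA20, n_res - 1L, replace = TRUE, prob = probs)),
        collapse = "")
}

# back-translate: ATG + random synonymous codons + random stop
peptide_to_cds <- function(pep, codon_tab) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1]][-1L]  # first is M -> ATG
  body <- vapply(chars, function(a) {
    cs <- codon_tab[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

random_smorf_nt <- function(len_nt, codon_tab) {
  n_codon <- len_nt / 3L
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE),
                     c(STOP_CODONS, "ATG"))
  body <- sample(nonstop, n_codon - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a synthetic genome with planted truth
#'
#' Emits a multi-contig assembly for one species: i.i.d. background bases at
#' the target GC, non-overlapping planted CDSs (valid start/stop, peptides
#' sampled from a composition shifted by the species' `vf_effect`),
#' redundant gene families planted as copies sharing one annotation label
#' and peptide, and smORFs planted at coordinates that satisfy their
#' declared positional class and contain no internal in-frame stop. CDS
#' peptides in the truth table are re-derived from the final sequence, so
#' they match exactly what [read_cds_gff3()] reconstructs.
#'
#' @param spec A [synthetic_spec()].
#' @param species One of `spec$species`.
#' @return List with `assembly` (`DNAStringSet`), `cds` (truth
#'   `data.frame`, same columns as [read_cds_gff3()] plus `species` and
#'   `family`), `smorfs` (truth `data.frame`: `contig_id`, `start`, `end`,
#'   `strand`, `frame`, `class`, `nt_seq`, `peptide`, `host_cds`) and
#'   `families` (label -> copies).
#' @export
generate_genome <- function(spec, species) {
  stopifnot(inherits(spec, "synthetic_spec"), species %in% spec$species)
  sp_idx <- match(species, spec$species)
  set.seed(derive_seed(spec$seed, 101L * sp_idx))
  codon_tab <- aa_to_codons()
  probs <- aa_probs(spec$vf_effect[[species]])
  gc <- spec$gc_target[[species]]
  gap <- 2600L

  # ---- plan CDSs ---------------------------------------------------------
  fam_labels <- rep(names(spec$redundant_families), spec$redundant_families)
  n_total <- spec$n_cds + length(fam_labels)
  len_codons <- sample(seq(spec$cds_length_range[1], spec$cds_length_range[2]),
                       n_total, replace = TRUE)
  strands <- rep(c("+", "-"), length.out = n_total)
  labels <- character(n_total)
  peps <- character(n_total)
  fam_pep <- vapply(names(spec$redundant_families), function(lab)
    sample_peptide(sample(seq(spec$cds_length_range[1],
                              spec$cds_length_range[2]), 1L) - 1L, probs),
    character(1))
  fi <- 0L
  for (k in seq_len(n_total)) {
    if (k <= spec$n_cds) {
      labels[k] <- if (k <= 2L) ""  # a couple of unannotated CDSs
                   else sprintf("hypothetical protein %s-%03d", species, k)
      peps[k] <- sample_peptide(len_codons[k] - 1L, probs)
    } else {
      fi <- fi + 1L
      labels[k] <- fam_labels[fi]
      peps[k] <- fam_pep[[fam_labels[fi]]]
      len_codons[k] <- nchar(peps[k]) + 1L
    }
  }
  len_nt <- 3L * len_codons
  pathways <- lapply(seq_len(n_total), function(k) {
    pw <- PATHWAY_POOL[1L + (k - 1L) %% length(PATHWAY_POOL)]
    if (k %% 5L == 0L)
      pw <- c(pw, PATHWAY_POOL[1L + k %% length(PATHWAY_POOL)])
    pw
  })

  # ---- plan smORFs: class -> host CDS (strand-matched) -------------------
  smorf_class <- rep(names(spec$planted_smorfs), spec$planted_smorfs)
  host_of <- integer(length(smorf_class))
  taken <- logical(n_total)
  pick_host <- function(need_strand, need_len) {
    ok <- !taken & (is.na(need_strand) | strands == need_strand) &
      len_nt >= need_len
    if (!any(ok)) stop("infeasible packing: no host CDS available for smORF")
    which(ok)[1L]
  }
  smorf_len <- integer(length(smorf_class))
  for (s in seq_along(smorf_class)) {
    cl <- smorf_class[s]
    if (cl == "CDSSmORF") {
      h <- pick_host(NA, 30L + 12L)
      smorf_len[s] <- 3L * sample(10:min(100L, (len_nt[h] - 12L) %/% 3L), 1L)
    } else {
      h <- pick_host(switch(cl, "5'SmORF" = "+", "3'SmORF" = "-",
                            "intergenic" = NA), 0L)
      smorf_len[s] <- 3L * sample(10:100, 1L)
    }
    host_of[s] <- h
    taken[h] <- TRUE
  }

  # ---- pack contigs ------------------------------------------------------
  n_ctg <- spec$contigs_per_species
  ctg_of <- 1L + (seq_len(n_total) - 1L) %% n_ctg
  L <- spec$contig_length_bp
  for (c_i in seq_len(n_ctg)) {
    need <- sum(gap + len_nt[ctg_of == c_i]) + 600L
    if (need > L)
      stop("infeasible packing: contig ", c_i, " needs ", need,
           " bp > ", L, " bp")
  }
  starts <- integer(n_total)
  ends <- integer(n_total)
  for (c_i in seq_len(n_ctg)) {
    cursor <- 1L
    for (k in which(ctg_of == c_i)) {
      starts[k] <- cursor + gap
      ends[k] <- starts[k] + len_nt[k] - 1L
      cursor <- ends[k]
    }
  }

  # ---- emit sequence -----------------------------------------------------
  contig_ids <- sprintf("%s_ctg%02d", species, seq_len(n_ctg))
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- lapply(seq_len(n_ctg), function(c_i)
    sample(names(base_p), L, replace = TRUE, prob = base_p))

  write_seq <- function(c_i, at, nt) {
    contigs[[c_i]][at:(at + nchar(nt) - 1L)] <<-
      strsplit(nt, "", fixed = TRUE)[[1]]
  }
  for (k in seq_len(n_total)) {
    nt <- peptide_to_cds(peps[k], codon_tab)
    if (strands[k] == "-") nt <- revcomp_chr(nt)
    write_seq(ctg_of[k], starts[k], nt)
  }

  # smORF placement relative to host (forward coordinates)
  sm_rows <- list()
  for (s in seq_along(smorf_class)) {
    h <- host_of[s]
    cl <- smorf_class[s]
    len <- smorf_len[s]
    prev_in_ctg <- which(ctg_of == ctg_of[h] & ends < starts[h])
    prev_end <- if (length(prev_in_ctg) > 0L) max(ends[prev_in_ctg]) else 0L
    p <- switch(cl,
      "CDSSmORF" = starts[h] + 4L,
      "5'SmORF" = starts[h] - 50L - len,
      "3'SmORF" = starts[h] - 50L - len,   # left of a minus-strand host
      "intergenic" = prev_end + 1050L
    )
    stopifnot(p >= 1L, p + len - 1L <= L)
    orf_strand <- if (s %% 2L == 0L) "-" else "+"
    nt <- random_smorf_nt(len, codon_tab)
    write_seq(ctg_of[h], p, if (orf_strand == "-") revcomp_chr(nt) else nt)
    end <- p + len - 1L
    sm_rows[[s]] <- data.frame(
      contig_id = contig_ids[ctg_of[h]], start = p, end = end,
      strand = orf_strand,
      frame = if (orf_strand == "+") (p - 1L) %% 3L else (L - end) %% 3L,
      class = cl, nt_seq = nt, peptide = strip_stop(translate_many(nt)),
      host_cds = if (cl == "intergenic") NA_character_
                 else sprintf("%s_cds%03d", species, h),
      stringsAsFactors = FALSE
    )
  }
  smorfs <- do.call(rbind, sm_rows)

  assembly <- Biostrings::DNAStringSet(
    vapply(contigs, paste, character(1), collapse = ""))
  names(assembly) <- contig_ids

  # truth peptides re-derived from the final sequence
  final_nt <- vapply(seq_len(n_total), function(k) {
    s <- Biostrings::subseq(assembly[[ctg_of[k]]], starts[k], ends[k])
    if (strands[k] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  cds <- data.frame(
    cds_id = sprintf("%s_cds%03d", species, seq_len(n_total)),
    contig_id = contig_ids[ctg_of], start = starts, end = ends,
    strand = strands, peptide = strip_stop(translate_many(final_nt)),
    annotation_label = labels, species = species,
    family = ifelse(labels %in% names(spec$redundant_families), labels,
                    NA_character_),
    stringsAsFactors = FALSE
  )
  cds$pathway_labels <- pathways

  list(assembly = assembly, cds = cds, smorfs = smorfs,
       families = spec$redundant_families)
}

# temperature-response curve: concave quadratic peaking at otg, zero outside
# the viability range
growth_rate_at <- function(temp, otg, r_peak, halfwidth) {
  pmax(0, r_peak * (1 - ((temp - otg) / halfwidth)^2))
}

#' Generate synthetic growth curves with known truth
#'
#' Logistic curves `A(t) = K / (1 + ((K - A0)/A0) exp(-r(T) t))` with
#' inoculum `A0`, per-species carrying capacity `K` drawn once from
#' `k_range`, rate `r(T)` a concave quadratic peaking at the species' true
#' optimal temperature (zero outside the viability range), additive Gaussian
#' noise and clipping at zero.
#'
#' @param spec A [synthetic_spec()].
#' @param species One of `spec$species`.
#' @param temps Optional temperature override (default `spec$growth$temps`).
#' @param r_peak,otg_true Optional overrides of the species' planted values.
#' @return List with `curves` (`data.frame`: strain, temperature, replicate,
#'   time, a600) and `truth` (`otg_true`, `r_by_temp`, `K`, `noise_sd`).
#' @export
generate_growth_curves <- function(spec, species, temps = NULL,
                                   r_peak = NULL, otg_true = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), species %in% spec$species)
  g <- spec$growth
  sp_idx <- match(species, spec$species)
  set.seed(derive_seed(spec$seed, 211L * sp_idx))
  temps <- temps %||% g$temps
  r_peak <- r_peak %||% g$r_peak[[species]]
  otg <- otg_true %||% g$otg_true[[species]]
  K <- stats::runif(1, g$k_range[1], g$k_range[2])
  times <- seq(0, g$days)
  r_by_temp <- growth_rate_at(temps, otg, r_peak, g$halfwidth)
  rows <- list()
  for (ti in seq_along(temps)) {
    r <- r_by_temp[ti]
    mu <- K / (1 + ((K - g$a0) / g$a0) * exp(-r * times))
    for (rep_i in seq_len(g$replicates)) {
      a <- pmax(mu + stats::rnorm(length(times), 0, g$noise_sd), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = species, temperature = temps[ti], replicate = rep_i,
        time = times, a600 = a, stringsAsFactors = FALSE
      )
    }
  }
  list(curves = do.call(rbind, rows),
       truth = list(otg_true = otg,
                    r_by_temp = stats::setNames(r_by_temp, temps),
                    K = K, noise_sd = g$noise_sd))
}

#' Random unrooted tree with uniform branch lengths
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param bl_range Branch-length range (uniform draw).
#' @param seed Integer RNG seed.
#' @return An `ape` `phylo`.
#' @export
random_tree <- function(n_taxa, bl_range = c(0.02, 0.25), seed = 1L) {
  set.seed(as.integer(seed))
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), bl_range[1], bl_range[2])
  tr
}

#' Evolve a protein along a tree
#'
#' Places substitutions on each branch as
#' `Poisson(rate * branch_length * n_sites)` with uniform replacement over
#' the 19 alternative residues; no indels. The generating tree is the truth
#' for topology-recovery tests.
#'
#' @param tree An `ape` `phylo` with branch lengths.
#' @param root_peptide Ancestral sequence (>= 50 residues recommended).
#' @param rate Substitutions per site per unit branch length (default 1).
#' @param seed Integer RNG seed.
#' @return List with `tree` (the input) and `peptides` (named by tip label).
#' @export
evolve_proteins <- function(tree, root_peptide, rate = 1, seed = 1L) {
  set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", n_tip + tr$Nnode)
  seqs[[root]] <- strsplit(root_peptide, "", fixed = TRUE)[[1]]
  L <- length(seqs[[root]])
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chi <- tr$edge[e, 2L]
    s <- seqs[[par]]
    n_sub <- stats::rpois(1L, rate * tr$edge.length[e] * L)
    if (n_sub > 0L) {
      sites <- sample.int(L, min(n_sub, L))
      for (site in sites) {
        s[site] <- sample(setdiff(AA20, s[site]), 1L)
      }
    }
    seqs[[chi]] <- s
  }
  peps <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                 character(1))
  list(tree = tree, peptides = stats::setNames(peps, tree$tip.label))
}

#' Random peptide
#'
#' @param n_res Number of residues.
#' @param seed Optional integer seed.
#' @return A single amino-acid string starting with `M`.
#' @export
random_peptide <- function(n_res, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  paste(c("M", sample(AA20, n_res - 1L, replace = TRUE)), collapse = "")
}
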