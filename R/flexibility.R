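#' Amino-acid flexibility classes
#'
#' Residue sets of the composition-based flexibility index used throughout
#' the pipeline: very flexible (Vf) = `E G K N Q S`, moderately flexible
#' (Mf) = `A D H I P R T V`; the remaining six standard residues
#' (`C F L M W Y`) form the rigid complement.
#'
#' @format Character vectors of one-letter residue codes.
#' @name flexibility_classes
NULL

#' @rdname flexibility_classes
#' @export
VF_RESIDUES <- c("E", "G", "K", "N", "Q", "S")

#' @rdname flexibility_classes
#' @export
MF_RESIDUES <- c("A", "D", "H", "I", "P", "R", "T", "V")

#' @rdname flexibility_classes
#' @export
RIGID_RESIDUES <- c("C", "F", "L", "M", "W", "Y")

#' Flexibility class of a residue
#'
#' @param aa Character vector of one-letter residue codes (the 20 standard
#'   residues or `X`). `X` maps to `rigid` with a warning.
#' @return Character vector over `{"Vf","Mf","rigid"}`.
#' @export
residue_class <- function(aa) {
  bad <- !aa %in% c(VF_RESIDUES, MF_RESIDUES, RIGID_RESIDUES, "X")
  if (any(bad)) stop("unknown residue symbol(s): ",
                     paste(unique(aa[bad]), collapse = ", "))
  if (any(aa == "X")) warning(sum(aa == "X"), " X residue(s) classified rigid")
  out <- rep("rigid", length(aa))
  out[aa %in% VF_RESIDUES] <- "Vf"
  out[aa %in% MF_RESIDUES] <- "Mf"
  out
}

#' Composition-based flexibility profile of proteins
#'
#' Per-protein percentages of Vf, Mf and rigid residues, plus their
#' aggregate VMf = Vf + Mf. A terminal stop symbol is stripped; `X` residues
#' are excluded from both the numerator and the denominator (they carry no
#' flexibility information).
#'
#' @param protein_id Character vector of identifiers.
#' @param peptide Character vector of amino-acid strings, same length.
#' @return A `data.frame` with columns `protein_id`, `n_residues`,
#'   `vf_percent`, `mf_percent`, `vmf_percent`, `rigid_percent`. For every
#'   row `vf + mf + rigid = 100` up to floating tolerance.
#' @export
flexibility_profile <- function(protein_id, peptide) {
  stopifnot(length(protein_id) == length(peptide))
  pep <- gsub("\\*", "", peptide)
  pep_nox <- gsub("X", "", pep)
  if (any(!nzchar(pep_nox)))
    stop("empty peptide (after stop/X removal) for: ",
         paste(protein_id[!nzchar(pep_nox)], collapse = ", "))
  chars <- strsplit(pep_nox, "", fixed = TRUE)
  bad <- unique(unlist(chars)[!unlist(chars) %in%
                              c(VF_RESIDUES, MF_RESIDUES, RIGID_RESIDUES)])
  if (length(bad) > 0L)
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  n <- lengths(chars)
  vf <- vapply(chars, function(x) sum(x %in% VF_RESIDUES), numeric(1))
  mf <- vapply(chars, function(x) sum(x %in% MF_RESIDUES), numeric(1))
  data.frame(
    protein_id = protein_id,
    n_residues = n,
    vf_percent = 100 * vf / n,
    mf_percent = 100 * mf / n,
    vmf_percent = 100 * (vf + mf) / n,
    rigid_percent = 100 * (n - vf - mf) / n,
    stringsAsFactors = FALSE
  )
}

#' Attach externally predicted flexibility classes (M0/M1/M2)
#'
#' Merges a per-protein table of predicted flexibility-class percentages
#' (three classes from rigid to flexible, e.g. from a deep-learning
#' predictor) onto composition profiles. Rows must satisfy
#' `m0 + m1 + m2 = 100` within ±0.5 (rounding tolerance); accepted rows are
#' renormalized to sum exactly 100 and `m12 = m1 + m2` is computed. Rows
#' violating the sum constraint, and rows whose `protein_id` is not in
#' `profiles`, are dropped with a warning. Proteins absent from the table
#' keep `NA` M fields.
#'
#' @param profiles Output of [flexibility_profile()].
#' @param m_table `data.frame` with columns `protein_id`, `m0`, `m1`, `m2`
#'   (percentages).
#' @return `profiles` with added columns `m0_percent`, `m1_percent`,
#'   `m2_percent`, `m12_percent`.
#' @export
attach_external_classes <- function(profiles, m_table) {
  stopifnot(all(c("protein_id", "m0", "m1", "m2") %in% names(m_table)))
  s <- m_table$m0 + m_table$m1 + m_table$m2
  bad_sum <- abs(s - 100) > 0.5
  if (any(bad_sum))
    warning(sum(bad_sum), " M-class row(s) rejected: percentages do not sum to 100")
  unknown <- !m_table$protein_id %in% profiles$protein_id
  if (any(unknown & !bad_sum))
    warning(sum(unknown & !bad_sum), " M-class row(s) skipped: unknown protein_id")
  keep <- !bad_sum & !unknown
  m <- m_table[keep, , drop = FALSE]
  sc <- 100 / (m$m0 + m$m1 + m$m2)
  idx <- match(profiles$protein_id, m$protein_id)
  profiles$m0_percent <- (m$m0 * sc)[idx]
  profiles$m1_percent <- (m$m1 * sc)[idx]
  profiles$m2_percent <- (m$m2 * sc)[idx]
  profiles$m12_percent <- ((m$m1 + m$m2) * sc)[idx]
  profiles
}

#' Long-format flexibility observations grouped by pathway
#'
#' Joins per-protein flexibility profiles with CDS pathway labels and emits
#' one observation row per (species, pathway, metric, protein). A protein
#' with k pathway labels contributes to all k pathway groups; every protein
#' additionally contributes once to the `"global"` pseudo-pathway. Metrics
#' are `Vf` and `VMf`, plus `M2` and `M1+2` when external classes are
#' attached.
#'
#' @param profiles Output of [flexibility_profile()] (optionally with
#'   M classes attached).
#' @param cds CDS `data.frame` with `cds_id` matching `protein_id` and the
#'   list column `pathway_labels`; may carry a `species` column.
#' @param species Species label used when `cds` has no `species` column.
#' @return Long `data.frame` with columns `species`, `pathway`, `metric`,
#'   `protein_id`, `value`.
#' @export
aggregate_by_pathway <- function(profiles, cds, species = NULL) {
  sp <- if ("species" %in% names(cds)) cds$species
        else rep(species %||% "unknown", nrow(cds))
  idx <- match(cds$cds_id, profiles$protein_id)
  metric_cols <- c(Vf = "vf_percent", VMf = "vmf_percent",
                   M2 = "m2_percent", `M1+2` = "m12_percent")
  metric_cols <- metric_cols[metric_cols %in% names(profiles)]
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    pi <- idx[i]
    if (is.na(pi)) next
    pw <- unique(c("global", cds$pathway_labels[[i]]))
    for (m in names(metric_cols)) {
      v <- profiles[[metric_cols[[m]]]][pi]
      if (is.na(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp[i], pathway = pw, metric = m,
        protein_id = profiles$protein_id[pi], value = v,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L)
    return(data.frame(species = character(0), pathway = character(0),
                      metric = character(0), protein_id = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
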