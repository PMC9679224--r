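#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA across species groups followed by Tukey
#' honestly-significant-difference pairwise tests (studentized-range
#' distribution with the Tukey-Kramer unequal-n adjustment, via
#' [stats::TukeyHSD()]). Groups with fewer than 2 observations are dropped
#' with a warning; if fewer than 2 usable groups remain, or the pooled
#' variance is zero, the test is recorded as untested.
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   per-protein metric values.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return List with `tested` (logical), and when tested: `anova_p`,
#'   `pair_p` (named vector, names `"A-B"`), `significant` (named logical),
#'   `alpha`, `n` (group sizes). When untested, `reason`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning(sum(sizes < 2L), " group(s) with <2 observations excluded")
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L)
    return(list(tested = FALSE, reason = "fewer than 2 usable groups"))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (all(tapply(y, g, stats::var) == 0) && length(unique(y)) == 1L)
    return(list(tested = FALSE, reason = "zero variance in all groups"))
  fit <- stats::aov(y ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  pair_p <- stats::setNames(tk[, "p adj"], rownames(tk))
  list(tested = TRUE, anova_p = anova_p, pair_p = pair_p,
       significant = pair_p < alpha, alpha = alpha,
       n = lengths(groups))
}

#' Run per-(pathway, metric) ANOVA/Tukey comparisons across species
#'
#' Applies [anova_tukey()] to every (pathway, metric) cell of a long-format
#' observation table (see [aggregate_by_pathway()]) and collects all
#' pairwise outcomes.
#'
#' @param long Long `data.frame` with columns `species`, `pathway`,
#'   `metric`, `value`.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with columns `pathway`, `metric`, `entity_a`,
#'   `entity_b`, `p`, `anova_p`, `significant`; untested cells are omitted.
#' @export
compare_flexibility <- function(long, alpha = 0.05) {
  rows <- list()
  for (d in split(long, interaction(long$pathway, long$metric, drop = TRUE))) {
    groups <- split(d$value, d$species)
    res <- suppressWarnings(anova_tukey(groups, alpha))
    if (!isTRUE(res$tested)) next
    pairs <- strsplit(names(res$pair_p), "-", fixed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = d$pathway[1], metric = d$metric[1],
      entity_a = vapply(pairs, `[`, character(1), 1L),
      entity_b = vapply(pairs, `[`, character(1), 2L),
      p = unname(res$pair_p), anova_p = res$anova_p,
      significant = unname(res$significant),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L)
    return(data.frame(pathway = character(0), metric = character(0),
                      entity_a = character(0), entity_b = character(0),
                      p = numeric(0), anova_p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise significance-count matrices
#'
#' Counts, for every pair of entities, the number of (pathway x metric)
#' cells whose Tukey comparison was significant at `alpha`. Optionally the
#' entities are first mapped onto groups (e.g. by OTG or Gr class); pairs
#' falling within one group are then dropped, and each (pathway, metric,
#' group-pair) cell counts once.
#'
#' @param results Output of [compare_flexibility()] (columns `pathway`,
#'   `metric`, `entity_a`, `entity_b`, `p`).
#' @param entities Optional ordered entity labels (default: sorted union).
#' @param alpha Significance level (default 0.05).
#' @param group_map Optional named character vector mapping entity to group
#'   label.
#' @return Object of class `"pairwise_significance"`: list with `counts`
#'   (combined symmetric matrix, zero diagonal), `by_metric` (list of
#'   matrices), `alpha`, `entities`.
#' @export
significance_heatmap <- function(results, entities = NULL, alpha = 0.05,
                                 group_map = NULL) {
  a <- results$entity_a
  b <- results$entity_b
  if (!is.null(group_map)) {
    a <- unname(group_map[a])
    b <- unname(group_map[b])
  }
  keep <- a != b & results$p < alpha
  lo <- pmin(a, b)[keep]
  hi <- pmax(a, b)[keep]
  cells <- data.frame(pathway = results$pathway[keep],
                      metric = results$metric[keep],
                      lo = lo, hi = hi, stringsAsFactors = FALSE)
  cells <- unique(cells)
  if (is.null(entities)) {
    entities <- sort(unique(if (is.null(group_map)) {
      c(results$entity_a, results$entity_b)
    } else unname(group_map)))
  }
  make_mat <- function(d) {
    m <- matrix(0L, length(entities), length(entities),
                dimnames = list(entities, entities))
    if (nrow(d) > 0L) {
      tab <- table(factor(d$lo, levels = entities),
                   factor(d$hi, levels = entities))
      m <- m + unclass(tab) + t(unclass(tab))
    }
    storage.mode(m) <- "integer"
    m
  }
  out <- list(
    counts = make_mat(cells),
    by_metric = lapply(split(cells, factor(cells$metric)), make_mat),
    alpha = alpha, entities = entities
  )
  class(out) <- "pairwise_significance"
  out
}

#' @export
print.pairwise_significance <- function(x, ...) {
  cat("Significant (pathway x metric) cells per entity pair (alpha =",
      x$alpha, ")\n")
  print(x$counts)
  invisible(x)
}

#' Cluster entities by their significance-difference profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance between
#' matrix rows) of the entities of a pairwise significance-count matrix.
#'
#' @param x A `"pairwise_significance"` object or a numeric matrix with row
#'   names.
#' @return An object of class [stats::hclust].
#' @export
cluster_entities <- function(x) {
  m <- if (inherits(x, "pairwise_significance")) x$counts else x
  if (nrow(m) < 2L) stop("need at least 2 entities to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Difference-vs-difference regressions
#'
#' For each (pathway, metric) with significant pairwise differences, the
#' between-species differences in the group-mean flexibility metric are
#' regressed (ordinary least squares, intercept included) on the
#' corresponding differences in each growth parameter (OTG, Gr).
#' Two-point regressions necessarily have R-squared 1 and are flagged.
#'
#' @param group_means `data.frame` with columns `entity`, `pathway`,
#'   `metric`, `mean_value`.
#' @param growth `data.frame` with columns `entity`, `otg`, `gr`.
#' @param cells `data.frame` of selected pairs: columns `pathway`, `metric`,
#'   `entity_a`, `entity_b` (typically the significant rows of
#'   [compare_flexibility()]).
#' @return `data.frame` with columns `pathway`, `metric`, `growth_param`,
#'   `n_pairs`, `slope`, `intercept`, `r2`, `direction`, `two_point`.
#' @export
delta_regression <- function(group_means, growth, cells) {
  rows <- list()
  for (d in split(cells, interaction(cells$pathway, cells$metric,
                                     drop = TRUE))) {
    d <- unique(d[, c("pathway", "metric", "entity_a", "entity_b")])
    gm <- group_means[group_means$pathway == d$pathway[1] &
                      group_means$metric == d$metric[1], , drop = FALSE]
    ya <- gm$mean_value[match(d$entity_a, gm$entity)]
    yb <- gm$mean_value[match(d$entity_b, gm$entity)]
    dy <- ya - yb
    for (gp in c("OTG", "Gr")) {
      gv <- if (gp == "OTG") growth$otg else growth$gr
      xa <- gv[match(d$entity_a, growth$entity)]
      xb <- gv[match(d$entity_b, growth$entity)]
      dx <- xa - xb
      ok <- !is.na(dx) & !is.na(dy)
      if (sum(ok) < 2L || stats::var(dx[ok]) == 0) next
      fit <- stats::lm(dy[ok] ~ dx[ok])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = d$pathway[1], metric = d$metric[1], growth_param = gp,
        n_pairs = sum(ok), slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]), r2 = r2,
        direction = if (stats::coef(fit)[2] >= 0) "positive" else "negative",
        two_point = sum(ok) == 2L, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pathway = character(0), metric = character(0),
                      growth_param = character(0), n_pairs = integer(0),
                      slope = numeric(0), intercept = numeric(0),
                      r2 = numeric(0), direction = character(0),
                      two_point = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-redundancy table
#'
#' Counts, per species, the CDSs sharing an identical annotation label and
#' returns the `top_n` labels ranked by total count across species (ties
#' broken alphabetically). Unannotated CDSs (empty label) are excluded and
#' their number reported in the `n_unannotated` attribute.
#'
#' @param cds CDS `data.frame` with columns `species` and `annotation_label`.
#' @param top_n Number of labels to keep (default 20); `Inf` keeps all.
#' @return `data.frame` with `annotation_label`, one count column per
#'   species, and `total`; attribute `n_unannotated` (named integer vector).
#' @export
redundancy_table <- function(cds, top_n = 20L) {
  stopifnot(all(c("species", "annotation_label") %in% names(cds)))
  unann <- !nzchar(cds$annotation_label)
  ann <- cds[!unann, , drop = FALSE]
  tab <- table(ann$annotation_label, ann$species)
  wide <- as.data.frame.matrix(tab)
  wide <- data.frame(annotation_label = rownames(wide), wide,
                     check.names = FALSE, row.names = NULL,
                     stringsAsFactors = FALSE)
  wide$total <- rowSums(wide[, -1, drop = FALSE])
  wide <- wide[order(-wide$total, wide$annotation_label), , drop = FALSE]
  wide <- utils::head(wide, top_n)
  rownames(wide) <- NULL
  attr(wide, "n_unannotated") <-
    vapply(split(unann, cds$species), sum, integer(1))
  wide
}

#' Gene-redundancy ratio
#'
#' Per species, the number of annotated CDSs divided by the number of
#' distinct annotation labels (a genome with no duplicated gene would score
#' 1).
#'
#' @inheritParams redundancy_table
#' @return Named numeric vector.
#' @export
redundancy_ratio <- function(cds) {
  ann <- cds[nzchar(cds$annotation_label), , drop = FALSE]
  vapply(split(ann$annotation_label, ann$species),
         function(x) length(x) / length(unique(x)), numeric(1))
}
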