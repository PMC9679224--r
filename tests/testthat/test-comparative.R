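test_that("two-group Tukey reduces to the pooled-variance t-test", {
  set.seed(101)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 5))
  res <- anova_tukey(g)
  expect_true(res$tested)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(unname(res$pair_p), tt$p.value, tolerance = 1e-4)
  expect_true(res$significant)
  expect_equal(res$anova_p, tt$p.value, tolerance = 1e-6)
})

test_that("degenerate and undersized groups are handled", {
  res <- anova_tukey(list(a = rep(1, 5), b = rep(1, 5)))
  expect_false(res$tested)
  expect_warning(res2 <- anova_tukey(list(a = 1, b = rnorm(5))), "excluded")
  expect_false(res2$tested)
  expect_warning(res3 <- anova_tukey(list(a = 2, b = rnorm(5, 1),
                                          c = rnorm(5))), "excluded")
  expect_true(res3$tested)
  expect_equal(length(res3$pair_p), 1L)
})

make_results <- function() {
  data.frame(
    pathway = c("p1", "p1", "p2", "p2"),
    metric = c("M1+2", "Vf", "M1+2", "Vf"),
    entity_a = c("A", "A", "A", "C"),
    entity_b = c("B", "B", "B", "D"),
    p = c(0.01, 0.20, 0.04, 0.03),
    stringsAsFactors = FALSE)
}

test_that("significance-count matrices are symmetric and alpha-monotone", {
  res <- make_results()
  h <- significance_heatmap(res, entities = c("A", "B", "C", "D"))
  expect_equal(h$counts["A", "B"], 2L)
  expect_equal(h$counts["B", "A"], 2L)
  expect_equal(h$counts["C", "D"], 1L)
  expect_equal(diag(h$counts), setNames(rep(0L, 4), c("A", "B", "C", "D")))
  expect_equal(h$by_metric[["M1+2"]]["A", "B"], 2L)
  expect_equal(h$by_metric[["Vf"]]["A", "B"], 0L)

  h_strict <- significance_heatmap(res, entities = c("A", "B", "C", "D"),
                                   alpha = 0.02)
  expect_true(all(h_strict$counts <= h$counts))

  h_none <- significance_heatmap(res[res$p > 0.5, , drop = FALSE],
                                 entities = c("A", "B"))
  expect_true(all(h_none$counts == 0L))
})

test_that("entity grouping collapses pairs and drops within-group ones", {
  res <- make_results()
  gm <- c(A = "low", B = "high", C = "low", D = "low")
  h <- significance_heatmap(res, group_map = gm)
  expect_equal(sort(h$entities), c("high", "low"))
  # the C-D pair is within "low" and must vanish
  expect_equal(h$counts["low", "high"], 2L)
  expect_equal(h$counts["low", "low"], 0L)
})

test_that("clustering merges identical rows first and ignores entity order", {
  m <- rbind(A = c(0, 1, 5, 5), B = c(0, 1, 5, 5),
             C = c(5, 5, 0, 1), D = c(5, 5, 0, 1))
  colnames(m) <- c("w", "x", "y", "z")
  hc <- cluster_entities(m)
  # the first two merges join the identical rows, at height 0
  m1 <- sort(hc$labels[-hc$merge[1, ]])
  m2 <- sort(hc$labels[-hc$merge[2, ]])
  expect_true(identical(m1, c("A", "B")) || identical(m1, c("C", "D")))
  expect_true(identical(m2, c("A", "B")) || identical(m2, c("C", "D")))
  expect_false(identical(m1, m2))
  expect_equal(hc$height[1:2], c(0, 0))

  # permuting entity order leaves the 2-group partition unchanged
  hc2 <- cluster_entities(m[c(3, 1, 4, 2), ])
  k1 <- cutree(hc, 2)
  k2 <- cutree(hc2, 2)[names(k1)]
  expect_equal(k1[["A"]] == k1[["B"]], k2[["A"]] == k2[["B"]])
  expect_equal(k1[["C"]] == k1[["D"]], k2[["C"]] == k2[["D"]])
  expect_equal(k1[["A"]] == k1[["C"]], k2[["A"]] == k2[["C"]])
})

test_that("delta regressions report slope, fit and the two-point flag", {
  gm <- data.frame(
    entity = c("A", "B", "C", "D"),
    pathway = "p1", metric = "Vf",
    mean_value = c(30, 34, 38, 42),
    stringsAsFactors = FALSE)
  growth <- data.frame(entity = c("A", "B", "C", "D"),
                       otg = c(10, 12, 14, 16), gr = c(0.1, 0.1, 0.2, 0.3))
  cells <- expand.grid(entity_a = c("A", "B", "C"),
                       entity_b = c("B", "C", "D"),
                       stringsAsFactors = FALSE)
  cells <- cells[cells$entity_a != cells$entity_b, ]
  cells$pathway <- "p1"
  cells$metric <- "Vf"
  out <- delta_regression(gm, growth, cells)
  otg_row <- out[out$growth_param == "OTG", ]
  # mean_value is perfectly linear in otg: slope 2, r2 = 1
  expect_equal(otg_row$slope, 2, tolerance = 1e-9)
  expect_equal(otg_row$r2, 1, tolerance = 1e-9)
  expect_equal(otg_row$direction, "positive")
  expect_false(otg_row$two_point)

  two <- delta_regression(gm, growth,
                          cells[cells$entity_a == "A" &
                                cells$entity_b %in% c("B", "C"), ])
  expect_true(all(two$two_point))
  expect_equal(two$r2, rep(1, nrow(two)), tolerance = 1e-9)
})

test_that("redundancy tables count label copies and exclude unannotated", {
  cds <- data.frame(
    species = c(rep("s1", 4), rep("s2", 3)),
    annotation_label = c("h", "h", "h", "t", "h", "", "t"),
    stringsAsFactors = FALSE)
  tab <- redundancy_table(cds, top_n = 1)
  expect_equal(tab$annotation_label, "h")
  expect_equal(tab$s1, 3L)
  expect_equal(tab$s2, 1L)
  expect_equal(attr(tab, "n_unannotated")[["s2"]], 1L)

  full <- redundancy_table(cds, top_n = Inf)
  expect_equal(sum(full$total), sum(nzchar(cds$annotation_label)))

  r <- redundancy_ratio(cds)
  expect_equal(r[["s1"]], 4 / 2)
  expect_equal(r[["s2"]], 2 / 2)
})

test_that("planted redundant families are counted exactly", {
  spec <- synthetic_spec(seed = 77)
  g <- generate_genome(spec, "G_gilvescens")
  tab <- redundancy_table(g$cds, top_n = length(spec$redundant_families))
  expect_equal(sort(tab$annotation_label),
               sort(names(spec$redundant_families)))
  counts <- setNames(tab$total, tab$annotation_label)
  expect_equal(counts[names(spec$redundant_families)],
               spec$redundant_families + 0L,
               ignore_attr = FALSE)
})
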