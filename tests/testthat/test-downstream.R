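# fitted-surface matrix with two opposite spatial groups
opposite_groups <- function(n_cells = 80, per_group = 10, noise = 0.05, seed = 1) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n_cells)
  f <- sin(2 * pi * x)
  up <- t(replicate(per_group, f + rnorm(n_cells, 0, noise)))
  dn <- t(replicate(per_group, -f + rnorm(n_cells, 0, noise)))
  m <- rbind(up, dn)
  rownames(m) <- c(paste0("up", seq_len(per_group)), paste0("dn", seq_len(per_group)))
  standardize_fits(m)
}

test_that("module discovery finds the planted two-group structure", {
  std <- opposite_groups()
  mods <- cluster_gene_modules(std, k_max = 8, seed = 2)
  expect_identical(attr(mods, "k"), 2L)
  got <- lapply(mods, function(m) sort(m$genes))
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  c(paste(sort(paste0("up", 1:10)), collapse = ","),
                    paste(sort(paste0("dn", 1:10)), collapse = ",")))
  # deterministic under the same seed
  mods2 <- cluster_gene_modules(std, k_max = 8, seed = 2)
  expect_identical(lapply(mods, `[[`, "genes"), lapply(mods2, `[[`, "genes"))
})

test_that("degenerate module inputs collapse to one module", {
  m <- matrix(rep(c(1, -1), each = 6), 4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), NULL))
  m[] <- 1
  expect_identical(attr(cluster_gene_modules(m, seed = 1), "k"), 1L)
  single <- cluster_gene_modules(matrix(rnorm(5), 1,
                                        dimnames = list("g1", NULL)), seed = 1)
  expect_length(single, 1L)
})

test_that("modules partition the genes and metagenes average members", {
  std <- opposite_groups(seed = 3)
  mods <- cluster_gene_modules(std, k_max = 6, seed = 4)
  all_genes <- unlist(lapply(mods, `[[`, "genes"))
  expect_setequal(all_genes, rownames(std))
  expect_identical(anyDuplicated(all_genes), 0L)
  # single-gene module equals that gene's standardized fit
  expect_equal(metagene("up1", std), std["up1", ])
  # opposite surfaces cancel
  expect_equal(unname(metagene(c("up1", "dn1"), rbind(up1 = std["up1", ],
                                                      dn1 = -std["up1", ]))),
               rep(0, ncol(std)))
  # 3-gene hand-computed mean
  toy <- rbind(a = c(1, 2), b = c(3, 4), c = c(5, 0))
  expect_equal(unname(metagene(c("a", "b", "c"), toy)), c(3, 2))
  # grand metagene equals the grand mean of the standardized matrix
  expect_equal(metagene(rownames(std), std), colMeans(std))
})

test_that("marker detection recovers cluster-restricted genes", {
  set.seed(5)
  n <- 120
  labels <- stats::setNames(rep(0:1, each = n / 2), paste0("c", seq_len(n)))
  expr <- matrix(rnorm(30 * n), 30, n,
                 dimnames = list(paste0("g", 1:30), names(labels)))
  expr["g1", labels == 0] <- expr["g1", labels == 0] + 4   # marker of cluster 0
  mk <- find_markers(expr, labels, top_n = 5, seed = 1)
  expect_identical(mk$per_cluster[["0"]]$gene[1], "g1")
  expect_true("g1" %in% mk$union)
  # p-values agree with the base two-sample test (normal approximation)
  p_ref <- wilcox.test(expr["g1", labels == 0], expr["g1", labels == 1],
                       exact = FALSE, correct = TRUE)$p.value
  expect_equal(mk$per_cluster[["0"]]$p[1], p_ref, tolerance = 1e-9)
  # invariance under cluster relabeling
  mk2 <- find_markers(expr, stats::setNames(1 - labels, names(labels)),
                      top_n = 5, seed = 1)
  expect_equal(sort(mk$per_cluster[["0"]]$p), sort(mk2$per_cluster[["1"]]$p))
  # top_n larger than the gene count returns everything
  mk3 <- find_markers(expr, labels, top_n = 100, seed = 1)
  expect_identical(nrow(mk3$per_cluster[["0"]]), 30L)
  expect_error(find_markers(expr, stats::setNames(rep(0L, n), names(labels))),
               "2 clusters")
})

test_that("SVG/marker overlap fraction is plain set arithmetic", {
  ranking <- paste0("g", 1:20)
  expect_equal(svg_marker_overlap(ranking, character(0), top_k = 10), 1)
  expect_equal(svg_marker_overlap(ranking, ranking, top_k = 10), 0)
  markers <- paste0("g", c(1:6))   # 4 of the top 10 are not markers
  expect_equal(svg_marker_overlap(ranking, markers, top_k = 10), 0.4)
  expect_warning(f <- svg_marker_overlap(ranking[1:3], markers, top_k = 10),
                 "clamped")
  expect_equal(f, 0)
})

test_that("gene-set enrichment matches the hypergeometric closed form", {
  universe <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:20), miss = paste0("g", 90:95))
  module <- paste0("g", c(1:8, 50, 60))   # overlap 8 with `hit`
  res <- enrich_gene_sets(module, universe, sets)
  expect_identical(res$set[1], "hit")
  # independent oracle: sum of the hypergeometric pmf over >= 8
  p_oracle <- sum(dhyper(8:10, 20, 80, 10))
  expect_equal(res$p[res$set == "hit"], p_oracle, tolerance = 1e-12)

  # a module that is an entire set, in a 10x larger universe, is extreme
  full <- enrich_gene_sets(paste0("g", 1:10), universe,
                           list(s = paste0("g", 1:10)))
  expect_identical(full$set[1], "s")
  expect_lt(full$p[1], 1e-6)

  # disjoint module -> nothing retained
  none <- enrich_gene_sets(paste0("g", 70:79), universe,
                           list(s = paste0("g", 1:10)))
  expect_identical(nrow(none), 0L)
  expect_error(enrich_gene_sets(module, character(0), sets), "empty")
})

test_that("GMT files round trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g4", "g5"))
})
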