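test_that("rectangular subsetting keeps central cells with their transcripts", {
  tis <- generate_tissue(tissue_spec(arena = c(400, 400), n_cells = 40, seed = 31))
  # frac = 1 keeps everything
  all_in <- subset_rectangle(tis$transcripts, tis$nuclei, tis$cells, frac = 1)
  expect_identical(nrow(all_in$transcripts), nrow(tis$transcripts))
  expect_length(all_in$nuclei, length(tis$nuclei))
  sub <- subset_rectangle(tis$transcripts, tis$nuclei, tis$cells, frac = 0.5)
  expect_lt(length(sub$nuclei), length(tis$nuclei))
  kept_ids <- vapply(sub$nuclei, `[[`, character(1), "nucleus_id")
  expect_true(all(sub$transcripts$cell %in% c(kept_ids, "UNASSIGNED")))
  expect_error(subset_rectangle(tis$transcripts, tis$nuclei, frac = 0), "frac")
})

test_that("uniformly placed cells are retained at about frac^2", {
  set.seed(32)
  n <- 4000
  nuclei <- lapply(seq_len(n), function(i) {
    rect_nucleus(paste0("n", i), runif(1, 0, 1000), runif(1, 0, 1000), 0.5, 0.5)
  })
  tx <- data.frame(x = c(0, 1000), y = c(0, 1000), gene = "g",
                   cell = "UNASSIGNED")
  sub <- subset_rectangle(tx, nuclei, frac = 0.2)
  expected <- n * 0.04
  expect_lt(abs(length(sub$nuclei) - expected),
            3 * sqrt(n * 0.04 * 0.96))
})

test_that("control probes are removed by prefix", {
  tx <- data.frame(x = 1:10, y = 1:10,
                   gene = c("NegControlProbe_00042", "GeneA",
                            "NegControlCodeword_1", "UnassignedCodeword_7",
                            paste0("G", 1:6)),
                   cell = "c1")
  out <- drop_controls(tx)
  expect_identical(nrow(out), 7L)
  expect_false(any(grepl("Control|Codeword", out$gene)))
})

test_that("gridify tiles the bounding box with half-open squares", {
  g <- gridify(c(0, 10, 0, 10), 2)
  expect_identical(nrow(g), 25L)
  expect_identical(nrow(gridify(c(0, 1, 0, 1), 5)), 1L)
  # every transcript lands in exactly one square
  set.seed(33)
  tx <- data.frame(x = runif(200, 0, 10), y = runif(200, 0, 10),
                   gene = "g", cell = "c")
  binned <- bin_transcripts(tx, g)
  expect_true(all(binned$square %in% g$square_id))
  expect_identical(sum(binned$counts), 200)
  expect_error(gridify(c(0, 1, 0, 1), 0), "positive")
})

test_that("the 8-micron baseline assigns cells to the dominant square", {
  g8 <- gridify(c(0, 16, 0, 16), 8)
  inside <- rect_nucleus("in", 1, 1, 5, 5)            # fully inside square 0,0
  straddle <- rect_nucleus("str", 2.4, 0.5, 8, 5)     # 70/30 split across x = 8
  m <- bin8_baseline(list(inside, straddle), g8)
  expect_identical(m$square_id[m$cell_id == "in"], "sq_0_0")
  expect_identical(m$square_id[m$cell_id == "str"], "sq_0_0")
  far <- rect_nucleus("far", 100, 100, 2, 2)          # overlaps nothing
  expect_true(is.na(bin8_baseline(list(far), g8)$square_id))
  # two cells sharing a square both keep it in the map
  twin <- rect_nucleus("twin", 2, 2, 3, 3)
  m2 <- bin8_baseline(list(inside, twin), g8)
  expect_identical(unique(m2$square_id), "sq_0_0")
  # tie resolution makes the map single-valued and is seeded
  own1 <- resolve_bin8_ties(m2, rng_seed = 4)
  own2 <- resolve_bin8_ties(m2, rng_seed = 4)
  expect_identical(own1, own2)
  expect_length(own1, 1L)
})

test_that("mapping accuracy counts matching assignments including unassigned", {
  gold <- c("a", "a", "b", "UNASSIGNED")
  expect_equal(mapping_accuracy(gold, gold), 1)
  half <- c("a", "x", "b", "y")
  expect_equal(mapping_accuracy(half, gold), 0.5)
  expect_equal(mapping_accuracy(rep("UNASSIGNED", 4), c("a", "b", "c", "d")), 0)
})

test_that("expression agreement is the median per-cell correlation", {
  set.seed(34)
  counts <- matrix(rpois(30 * 20, 6), 30, 20,
                   dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
  expect_equal(expression_agreement(counts, counts), 1)
  # small perturbation keeps correlation high
  noisy <- pmax(counts + matrix(rbinom(600, 1, 0.1), 30, 20), 0)
  dimnames(noisy) <- dimnames(counts)
  expect_gt(expression_agreement(noisy, counts), 0.9)
  expect_error(expression_agreement(counts[, 1:2], counts[, 1:2]), "3 shared")
})

test_that("clustering agreement is the adjusted Rand index", {
  a <- rep(1:3, each = 10)
  expect_equal(clustering_agreement(a, a), 1)
  expect_equal(clustering_agreement(a, rep(1, 30)), 0)
  expect_equal(clustering_agreement(seq_len(30), rep(1, 30)), 0)
  # random label permutations are centred at zero
  set.seed(35)
  aris <- replicate(200, clustering_agreement(a, sample(a)))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("nucleus assignment beats 8-micron binning on the nested lattice", {
  tis <- generate_ideal_tissue(n_side = 3, seed = 36)
  ev <- evaluate_assignment(tis$transcripts, tis$nuclei, tis$cells,
                            size_px = 8,
                            cluster_args = list(n_pcs = 5, resolution = 0.8,
                                                seed = 0))
  ct <- ev[ev$method == "ctsvg", ]
  b8 <- ev[ev$method == "bin8", ]
  expect_equal(ct$accuracy, 1.0)
  expect_lt(b8$accuracy, 1.0)
  expect_gte(ct$median_cor, b8$median_cor)
  expect_gte(ct$ari, b8$ari)
})
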