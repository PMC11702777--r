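test_that("nucleus size filter removes only log-area outliers", {
  # all areas equal: sd = 0, cutoff = mean, none strictly exceed
  nuclei <- lapply(1:10, function(i) rect_nucleus(paste0("n", i), i * 10, 0,
                                                  exp(0.5), exp(0.5)))
  expect_length(filter_large_nuclei(nuclei), 10L)

  # log-areas {1 x9, 20}: mean 2.9, sd 6.00833, cutoff 14.9166 -> outlier out
  areas <- c(rep(exp(1), 9), exp(20))
  nuclei <- lapply(seq_along(areas), function(i)
    rect_nucleus(paste0("n", i), i * 1e6, 0, sqrt(areas[i]), sqrt(areas[i])))
  kept <- filter_large_nuclei(nuclei)
  expect_length(kept, 9L)
  expect_false("n10" %in% vapply(kept, `[[`, character(1), "nucleus_id"))

  expect_warning(res <- filter_large_nuclei(nuclei[1]), "single")
  expect_length(res, 1L)
  expect_error(filter_large_nuclei(list()), "no nuclei")
})

test_that("squares go to the nucleus with the largest subsquare overlap", {
  grid <- toy_grid(1, 1, size = 1)
  # single nucleus
  a <- rect_nucleus("a", -1, -1, 2, 4)
  asg <- assign_squares(grid, list(a))
  expect_identical(asg$cell_id, "a")
  expect_identical(asg$stage, "NUCLEUS")

  # 60 vs 40 subsquare centroids
  a <- rect_nucleus("a", -1, -1, 1.6, 3)   # covers x < 0.6 -> 60 centroids
  b <- rect_nucleus("b", 0.6, -1, 2, 3)    # covers x > 0.6 -> 40 centroids
  asg <- assign_squares(grid, list(a, b))
  expect_identical(asg$cell_id, "a")
  expect_equal(asg$overlap, 0.6)
  # order of polygons does not matter
  expect_identical(assign_squares(grid, list(b, a))$cell_id, "a")

  # exact tie 50/50 -> smallest nucleus id wins, numerically aware
  a <- rect_nucleus("10", -1, -1, 1.5, 3)
  b <- rect_nucleus("9", 0.5, -1, 2, 3)
  asg <- assign_squares(grid, list(a, b))
  expect_identical(asg$cell_id, "9")

  # zero overlap stays unassigned
  far <- rect_nucleus("far", 10, 10, 1, 1)
  asg <- assign_squares(grid, list(far))
  expect_true(is.na(asg$cell_id))
})

test_that("the expanded pass never reassigns nucleus-pass squares", {
  tis <- generate_tissue(tissue_spec(arena = c(300, 300), n_cells = 20, seed = 11))
  nuclei <- filter_large_nuclei(tis$nuclei)
  pass1 <- assign_squares(tis$grid, nuclei, stage = "NUCLEUS")
  expanded <- lapply(nuclei, expand_nucleus, area_ratio = 2)
  pass2 <- assign_squares(tis$grid, expanded, existing = pass1, stage = "EXPANDED")
  fixed <- !is.na(pass1$cell_id)
  expect_true(any(fixed))
  expect_identical(pass2$cell_id[fixed], pass1$cell_id[fixed])
  expect_identical(pass2$stage[fixed], pass1$stage[fixed])
  # and it only adds assignments
  expect_true(all(fixed <= !is.na(pass2$cell_id)))
})

test_that("abnormal cells are removed by the three stated rules", {
  grid <- toy_grid(3, 4, size = 2)   # square area 4
  mk_assign <- function(cells) {
    df <- data.frame(square_id = grid$square_id, cell_id = NA_character_,
                     stage = NA_character_, overlap = 0)
    for (nm in names(cells)) {
      df$cell_id[match(cells[[nm]], grid$square_id)] <- nm
      df$stage[match(cells[[nm]], grid$square_id)] <- "NUCLEUS"
    }
    df
  }
  nuc <- list(rect_nucleus("a", 0, 0, 5, 4),       # area 20
              rect_nucleus("b", 50, 0, 5, 4))
  expd <- lapply(nuc, expand_nucleus, area_ratio = 2)  # expanded area 40

  # rule (a): cell b has no squares; a (6 squares, 24 >= 20) survives
  asg <- mk_assign(list(a = c("s0_0", "s0_1", "s0_2", "s0_3", "s1_0", "s1_1")))
  expect_identical(remove_abnormal_cells(asg, grid, nuc, expd), "a")

  # rule (b): 4 squares (16) < 0.5 * 40 -> removed; 6 squares (24) -> kept
  asg4 <- mk_assign(list(a = c("s0_0", "s0_1", "s0_2", "s0_3")))
  expect_identical(remove_abnormal_cells(asg4, grid, nuc, expd), character(0))
  asg6 <- mk_assign(list(a = c("s0_0", "s0_1", "s0_2", "s0_3", "s1_0", "s1_1")))
  expect_identical(remove_abnormal_cells(asg6, grid, nuc, expd), "a")

  # rule (b) with the nucleus-area reference: 4 squares (16) >= 0.5 * 20
  expect_identical(remove_abnormal_cells(asg4, grid, nuc, expd,
                                         area_reference = "nucleus"), "a")

  # rule (c): gap at (0, 1) disconnects; adjacency retains
  nuc_small <- list(rect_nucleus("a", 0, 0, 4, 1))
  expd_small <- lapply(nuc_small, expand_nucleus, area_ratio = 2)
  gap <- mk_assign(list(a = c("s0_0", "s0_2")))
  expect_identical(remove_abnormal_cells(gap, grid, nuc_small, expd_small),
                   character(0))
  adj <- mk_assign(list(a = c("s0_0", "s0_1")))
  expect_identical(remove_abnormal_cells(adj, grid, nuc_small, expd_small), "a")
  # diagonal contact is not 4-connected
  diag <- mk_assign(list(a = c("s0_0", "s1_1")))
  expect_identical(remove_abnormal_cells(diag, grid, nuc_small, expd_small),
                   character(0))
})

test_that("aggregation sums square counts per cell with centroid coordinates", {
  grid <- toy_grid(1, 3, size = 1)
  counts <- Matrix::Matrix(rbind(g1 = c(1, 2, 9), g2 = c(5, 0, 7)), sparse = TRUE)
  colnames(counts) <- grid$square_id
  asg <- data.frame(square_id = grid$square_id,
                    cell_id = c("a", "a", NA), stage = c("NUCLEUS", "EXPANDED", NA),
                    overlap = c(1, 0.5, 0))
  nuc <- list(rect_nucleus("a", 0, 0, 2, 1))
  expd <- lapply(nuc, expand_nucleus, area_ratio = 2)
  cells <- aggregate_counts(asg, counts, "a", nuc, expd)
  expect_equal(as.matrix(cells$counts), matrix(c(3, 5), 2, 1,
               dimnames = list(c("g1", "g2"), "a")))
  expect_equal(unname(cells$coords["a", ]), nuc[[1]]$centroid)
  expect_equal(cells$meta["a", "n_squares"], 2L)

  # nothing assigned -> empty matrix with zero cells
  empty <- aggregate_counts(
    data.frame(square_id = grid$square_id, cell_id = NA_character_,
               stage = NA_character_, overlap = 0),
    counts, character(0), nuc, expd)
  expect_equal(dim(empty), c(2L, 0L))
})

test_that("total counts are conserved between squares and cells", {
  tis <- generate_tissue(tissue_spec(arena = c(350, 350), n_cells = 30, seed = 21))
  asg <- assign_cells(tis$grid, tis$counts, tis$nuclei)
  unassigned <- is.na(asg$assignment$cell_id) |
    !(asg$assignment$cell_id %in% colnames(asg$cells$counts))
  expect_equal(sum(asg$cells$counts) + sum(tis$counts[, unassigned]),
               sum(tis$counts))
})

test_that("argmax assignment agrees with the exact-clipping oracle", {
  set.seed(13)
  agree <- 0; total <- 0
  for (i in 1:120) {
    size <- 2
    p1 <- ellipse_poly(runif(1, -1, 3), runif(1, -1, 3), runif(1, 1.5, 3),
                       runif(1, 1.5, 3), runif(1, 0, pi))
    p2 <- ellipse_poly(runif(1, -1, 3), runif(1, -1, 3), runif(1, 1.5, 3),
                       runif(1, 1.5, 3), runif(1, 0, pi))
    ap <- c(approximate_overlap(0, 0, size, p1), approximate_overlap(0, 0, size, p2))
    ex <- c(exact_overlap(0, 0, size, p1), exact_overlap(0, 0, size, p2))
    if (max(ex) == 0) next
    total <- total + 1
    agree <- agree + (which.max(ap) == which.max(ex))
  }
  expect_gte(agree / total, 0.95)
})
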