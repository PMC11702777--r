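test_that("Jaccard index matches set arithmetic", {
  expect_equal(jaccard(1:3, 1:3), 1)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(integer(0), integer(0)), 0)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "a")), 1)  # duplicates ignored
})

test_that("reassignment matching retains top-Jaccard clusters per seed", {
  d <- blob_dataset(n = 150, effect = 4, seed = 6)
  cl <- cluster_cells(d$expr, n_pcs = 8, resolution = 0.5, seed = 0,
                      normalized = TRUE)
  expect_error(build_reassignments(cl, n_seeds = 3, keep = 5), "exceed")
  re <- build_reassignments(cl, n_seeds = 5, keep = 3)
  expect_length(re, length(unique(cl$labels)))
  for (cl_id in names(re)) {
    expect_length(re[[cl_id]], 3L)
    jc <- vapply(re[[cl_id]], `[[`, numeric(1), "jaccard")
    # perfectly separated blobs: every reseed reproduces the partition
    expect_equal(jc, rep(1, 3))
    # ties resolved toward smaller seeds
    expect_identical(vapply(re[[cl_id]], `[[`, numeric(1), "seed"), c(1, 2, 3))
  }
  # keep = n_seeds retains every match regardless of Jaccard
  re_all <- build_reassignments(cl, n_seeds = 3, keep = 3)
  expect_length(re_all[[1]], 3L)
})

test_that("null statistics are reproducible and sized genes x reassignments", {
  d <- blob_dataset(n = 260, effect = 4, seed = 7)
  cl <- cluster_cells(d$expr, n_pcs = 8, resolution = 0.5, seed = 0,
                      normalized = TRUE)
  re <- build_reassignments(cl, n_seeds = 6, keep = 5)
  genes <- rownames(d$expr)[1:10]
  n1 <- null_statistics(d$expr, d$coords, re[["0"]], genes, K = 0,
                        rng_seed = 3, min_nulls = 5)
  n2 <- null_statistics(d$expr, d$coords, re[["0"]], genes, K = 0,
                        rng_seed = 3, min_nulls = 5)
  expect_identical(n1, n2)
  expect_identical(dim(n1), c(10L, 5L))
  expect_true(all(n1 >= 0))
  # a different permutation seed changes the nulls
  n3 <- null_statistics(d$expr, d$coords, re[["0"]], genes, K = 0,
                        rng_seed = 4, min_nulls = 5)
  expect_false(identical(n1, n3))
})

test_that("Gamma tail p-values match the closed-form oracle", {
  set.seed(8)
  nulls <- rgamma(100, shape = 3, rate = 1)
  # far-left observation: clearly not significant
  expect_gt(gamma_pvalue(min(nulls) / 10, nulls), 0.5)
  # far-right observation: oracle tail of the true Gamma is < 1e-10; the
  # fitted Gamma must agree on the order of magnitude
  p60 <- gamma_pvalue(60, nulls)
  expect_lt(p60, 1e-10)
  expect_lt(pgamma(60, 3, 1, lower.tail = FALSE), 1e-10)
  # strictly decreasing in the observed statistic
  obs <- seq(0.5, 12, length.out = 30)
  pv <- vapply(obs, gamma_pvalue, numeric(1), nulls = nulls)
  expect_true(all(diff(pv) < 0))
  expect_error(gamma_pvalue(1, rgamma(10, 2)), "at least 30")
})

test_that("Gamma shape recovery from 100 nulls is within 35% (median)", {
  set.seed(9)
  err <- replicate(120, {
    x <- rgamma(100, shape = 3, rate = 1)
    f <- fitdistrplus::fitdist(x, "gamma", method = "mle")
    abs(f$estimate[["shape"]] - 3) / 3
  })
  expect_lt(median(err), 0.35)
})

test_that("zero nulls are nudged and the empirical fallback is available", {
  nulls <- c(rep(0, 5), rgamma(95, 2, 1))
  p <- gamma_pvalue(1, nulls)
  expect_true(p > 0 && p < 1)
  # degenerate nulls force the empirical permutation fallback
  p_emp <- gamma_pvalue(5, rep(1, 50))
  expect_equal(p_emp, 1 / 51)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  fdr <- adjust_bh(p)
  expect_true(all(fdr >= p))
  ord <- sample(5)
  expect_equal(adjust_bh(p[ord]), fdr[ord])
})

test_that("the parametric baseline is the F(p-1, n-p) upper tail", {
  expect_equal(parametric_pvalue_baseline(0, 300, 36), 1)
  q95 <- qf(0.95, 35, 264)
  expect_equal(parametric_pvalue_baseline(q95, 300, 36), 0.05)
  expect_equal(parametric_pvalue_baseline(1, 1e5, 36),
               pf(1, 35, 1e5 - 36, lower.tail = FALSE))
})

test_that("the full test is deterministic and flags planted genes", {
  d <- blob_dataset(n = 360, effect = 4, seed = 10)
  sim <- generate_svg_expression(d$coords, n_svg = 6, n_null = 30,
                                 effect = 4, noise_sd = 1, rng_seed = 11)
  expr <- rbind(d$expr, sim$expr)
  cl <- cluster_cells(expr, n_pcs = 8, resolution = 0.5, seed = 0,
                      normalized = TRUE)
  svg1 <- suppressWarnings(
    test_svgs(expr, d$coords, cl, K = 0, n_seeds = 12, keep = 10, rng_seed = 1))
  svg2 <- suppressWarnings(
    test_svgs(expr, d$coords, cl, K = 0, n_seeds = 12, keep = 10, rng_seed = 1))
  expect_identical(svg1$results, svg2$results)
  r <- svg1$results[["0"]]
  expect_true(all(c("gene", "F", "p", "fdr", "rank", "significant") %in% names(r)))
  # ranking is by p then descending F
  expect_identical(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$p) >= 0))
  # planted spatial genes dominate the significant set
  sig <- r$gene[r$significant]
  expect_gte(sum(grepl("^svg", sig)), 5)
  expect_lte(sum(!grepl("^svg", sig)), 2)
  # FDR >= p always
  expect_true(all(r$fdr >= r$p - 1e-15))
})
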