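test_that("isolation neighborhood size follows the 1%/[10,50] clamp", {
  expect_identical(isolation_k(1000), 10L)
  expect_identical(isolation_k(10000), 50L)
  expect_identical(isolation_k(500), 10L)
  expect_identical(isolation_k(3000), 30L)
  expect_identical(isolation_k(3050), 31L)   # round half-up: 30.5 -> 31
  expect_identical(isolation_k(5), 4L)       # capped at n - 1
})

test_that("regular grids lose no cells; a displaced cell is the only removal", {
  # zero-variance scores: nothing removed
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10)) * 1.0
  rownames(g) <- paste0("c", seq_len(nrow(g)))
  keep <- remove_isolated_cells(g)
  expect_true(all(keep))

  # 200 clustered cells plus one displaced by 1000 units
  set.seed(5)
  xy <- cbind(rnorm(201, 0, 5), rnorm(201, 0, 5))
  xy[201, ] <- c(1000, 1000)
  rownames(xy) <- paste0("c", 1:201)
  keep <- remove_isolated_cells(xy)
  expect_identical(names(keep)[!keep], "c201")

  # brute-force oracle for the scores themselves
  k <- isolation_k(201)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  oracle <- apply(d, 1, function(r) mean(sort(r)[seq_len(k)]))
  expect_equal(unname(attr(keep, "scores")), unname(oracle), tolerance = 1e-9)

  expect_warning(remove_isolated_cells(xy[1, , drop = FALSE]), "at least 2")
})

test_that("cluster gene filter applies the positive-fraction threshold", {
  m <- matrix(0, 3, 300, dimnames = list(c("keep3", "drop2", "all"), NULL))
  m["keep3", 1:3] <- 1    # 3 = 1% of 300
  m["drop2", 1:2] <- 1
  m["all", ] <- 1
  expect_identical(filter_cluster_genes(m, 0.01), c("keep3", "all"))
})

test_that("design dimensions follow p = 1 + 2(K+3) + (K+3)^2", {
  set.seed(1)
  xy <- cbind(runif(100), runif(100))
  d2 <- build_design(xy, K = 2)
  expect_identical(d2$p, 36L)
  expect_identical(ncol(d2$X), 36L)
  d0 <- build_design(xy, K = 0)
  expect_identical(d0$p, 16L)
  # full rank designs
  expect_identical(qr(d2$X)$rank, 36L)
  # basis values stay in [0, 1] and the full (K+4)-function basis they come
  # from sums to one, so each row's main-effect sum is at most 1
  mains <- d2$X[, 2:6]
  expect_true(all(mains >= 0 & mains <= 1))
  expect_true(all(rowSums(mains) <= 1 + 1e-9))
  expect_error(build_design(xy[1:30, ], K = 2), "reduce K")
  expect_error(build_design(cbind(rep(1, 100), runif(100)), K = 0), "constant")
})

test_that("batch F statistics equal independent per-gene OLS", {
  set.seed(2)
  n <- 300
  xy <- cbind(runif(n), runif(n))
  rownames(xy) <- paste0("c", 1:n)
  design <- build_design(xy, K = 2)
  Y <- matrix(rnorm(20 * n), 20, n, dimnames = list(paste0("g", 1:20), rownames(xy)))
  Y[1, ] <- Y[1, ] + 3 * xy[, 1]^2
  fit <- fit_genes(design, Y)
  for (i in 1:20) {
    lmfit <- lm(Y[i, ] ~ design$X - 1)
    f_oracle <- summary(lm(Y[i, ] ~ design$X[, -1]))$fstatistic[["value"]]
    expect_equal(fit$F[[i]], f_oracle, tolerance = 1e-8)
    expect_equal(unname(fit$fitted[i, ]), unname(fitted(lmfit)), tolerance = 1e-8)
  }
})

test_that("degenerate genes and exact surfaces behave at the conventions", {
  set.seed(3)
  n <- 120
  xy <- cbind(runif(n), runif(n))
  design <- build_design(xy, K = 0)
  # constant gene -> F = 0
  Y <- rbind(const = rep(2, n),
             exact = as.numeric(design$X %*% rnorm(design$p)))
  fit <- fit_genes(design, Y)
  expect_identical(fit$F[["const"]], 0)
  # noiseless X beta -> essentially perfect fit
  expect_gt(fit$F[["exact"]], 1e6)
  expect_error(fit_genes(design, matrix(NA_real_, 1, n)), "finite")
})

test_that("F statistics are invariant under cell reordering", {
  set.seed(4)
  n <- 150
  xy <- cbind(runif(n), runif(n))
  Y <- matrix(rnorm(5 * n), 5, n)
  f1 <- fit_genes(build_design(xy, K = 2), Y)$F
  perm <- sample.int(n)
  f2 <- fit_genes(build_design(xy[perm, ], K = 2), Y[, perm])$F
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("standardized fits have mean zero and unit sd per gene", {
  expect_equal(unname(standardize_fits(matrix(c(1, 2, 3), 1))[1, ]),
               c(-1, 0, 1))
  v <- matrix(rnorm(50), 2)
  s1 <- standardize_fits(v)
  expect_equal(unname(standardize_fits(s1)), unname(s1), tolerance = 1e-12)
  expect_warning(z <- standardize_fits(matrix(5, 1, 4)), "constant")
  expect_equal(unname(z[1, ]), rep(0, 4))
})
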