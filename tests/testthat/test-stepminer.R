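test_that("a perfect step is recovered exactly", {
  fit <- fit_step(c(1, 1, 1, 5, 5, 5))
  expect_equal(fit$k, 3L)
  expect_equal(fit$mu_left, 1)
  expect_equal(fit$mu_right, 5)
  expect_equal(fit$sse, 0)
  expect_equal(fit$sthr, 3)
  expect_false(fit$no_step)
  expect_equal(fit$fitted, rep(c(1, 5), each = 3))
})

test_that("constant series are flagged as having no step", {
  fit <- fit_step(c(2, 2, 2, 2))
  expect_true(fit$no_step)
  expect_equal(fit$sthr, 2)
  expect_true(is.na(fit$fstat))
  expect_error(fit_step(3), "at least 2")
  expect_error(fit_step(c(1, NA)), "finite")
})

test_that("fit_step matches exhaustive split search on random series", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    x <- rnorm(n)
    fit <- fit_step(x)
    oracle <- brute_step(x)
    expect_identical(fit$k, as.integer(oracle$k))
    expect_equal(fit$sse, oracle$sse, tolerance = 1e-9)
    # optimality: no split beats the chosen one
    expect_true(all(fit$sse <= oracle$all_sse + 1e-9))
  }
})

test_that("equal-SSE ties resolve to the smallest split index", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- sample(1:3, n, replace = TRUE) # coarse values force ties
    if (all(x == x[1])) next
    fit <- fit_step(x)
    oracle <- brute_step(x)
    near_min <- which(oracle$all_sse <= min(oracle$all_sse) + 1e-9)
    expect_equal(fit$k, min(near_min))
  }
})

test_that("the F statistic follows the regression-test definition", {
  x <- c(0.2, 0.5, 0.1, 3.9, 4.2, 4.1, 4.0)
  fit <- fit_step(x)
  m <- 3
  n <- length(x)
  fitted <- c(rep(mean(x[1:fit$k]), fit$k),
              rep(mean(x[(fit$k + 1):n]), n - fit$k))
  expected <- (sum((fitted - mean(x))^2) / (m - 1)) /
    (sum((x - fitted)^2) / (n - m))
  expect_equal(fit$fstat, expected)
  # zero-residual fits have an infinite statistic
  expect_equal(fit_step(c(1, 1, 5, 5))$fstat, Inf)
})

test_that("gene_threshold is order-invariant and handles degenerate genes", {
  v <- matrix(c(5, 1, 5, 1), nrow = 1, dimnames = list("g1", paste0("s", 1:4)))
  m1 <- toy_matrix(v)
  m2 <- toy_matrix(v[, c(2, 4, 1, 3), drop = FALSE])
  expect_equal(gene_threshold(m1, "g1"), 3)
  expect_equal(gene_threshold(m2, "g1"), 3)
  expect_error(gene_threshold(m1, "nope"), "gene not in matrix: nope")

  const <- toy_matrix(matrix(7, nrow = 1, ncol = 3,
                             dimnames = list("g1", paste0("s", 1:3))))
  expect_warning(thr <- gene_threshold(const, "g1"), "no step")
  expect_equal(thr, 7)
})

test_that("the threshold is affine-equivariant", {
  set.seed(9)
  x <- simulate_bimodal_gene(10, 10)
  base <- fit_step(sort(x))$sthr
  expect_equal(fit_step(sort(x + 2.5))$sthr, base + 2.5)
  expect_equal(fit_step(sort(x * 3))$sthr, base * 3)
})

test_that("binarize applies the threshold, tie, and margin rules", {
  v <- matrix(c(1, 1, 5, 5), nrow = 1, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(unname(binarize(toy_matrix(v))[1, ]), c(0L, 0L, 1L, 1L))

  # value exactly at the threshold classifies low at margin 0
  thr3 <- tibble::tibble(gene = "g1", sthr = 3)
  v2 <- matrix(c(1, 1, 3, 5, 5), nrow = 1,
               dimnames = list("g1", paste0("s", 1:5)))
  m2 <- toy_matrix(v2)
  expect_equal(unname(binarize(m2, thresholds = thr3)[1, ]),
               c(0L, 0L, 0L, 1L, 1L))

  # a positive margin opens an intermediate NA band around the threshold
  v3 <- matrix(c(2.8, 3.2, 5), nrow = 1,
               dimnames = list("g1", paste0("s", 1:3)))
  m3 <- toy_matrix(v3)
  b <- binarize(m3, margin = 0.5, thresholds = thr3)
  expect_true(is.na(b[1, 1]) && is.na(b[1, 2]))
  expect_equal(b[1, 3], 1L)
  expect_error(binarize(m3, margin = -1), "nonnegative")
  expect_error(binarize(m3, thresholds = tibble::tibble(gene = "gX", sthr = 1)),
               "cover every gene")
})

test_that("gene_thresholds tabulates every gene", {
  set.seed(5)
  v <- rbind(
    g1 = simulate_bimodal_gene(5, 5),
    g2 = rep(1, 10)
  )
  colnames(v) <- paste0("s", 1:10)
  thr <- gene_thresholds(toy_matrix(v))
  expect_identical(thr$gene, c("g1", "g2"))
  expect_false(thr$no_step[1])
  expect_true(thr$no_step[2])
  expect_equal(thr$sthr[2], 1)
})
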