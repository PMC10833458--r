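test_that("modified_zscore centers on the threshold and scales by 3 sd", {
  expect_equal(modified_zscore(3, 3, 1), 0)
  expect_equal(modified_zscore(3 + 3 * 2, 3, 2), 1)
  expect_equal(modified_zscore(5, 3, 1), 2 / 3)
  expect_error(modified_zscore(1, 0, 0), "positive")
})

test_that("a single-gene signature's composite score is that gene's z", {
  set.seed(11)
  v <- rbind(g1 = simulate_bimodal_gene(6, 6))
  colnames(v) <- paste0("s", 1:12)
  m <- toy_matrix(v)
  sig <- gene_signature("g1", 1)
  got <- composite_score(m, sig)
  sthr <- gene_threshold(m, "g1")
  expect_equal(got$score, unname((v[1, ] - sthr) / (3 * sd(v[1, ]))))
  # flipping the one direction negates the score
  flipped <- composite_score(m, gene_signature("g1", -1))
  expect_equal(flipped$score, -got$score)
})

test_that("signed mode subtracts down genes; sum_all adds everything", {
  set.seed(12)
  v <- rbind(
    up1 = simulate_bimodal_gene(6, 6),
    dn1 = simulate_bimodal_gene(6, 6)
  )
  colnames(v) <- paste0("s", 1:12)
  m <- toy_matrix(v)
  z <- function(g) {
    (v[g, ] - gene_threshold(m, g)) / (3 * sd(v[g, ]))
  }
  sig <- gene_signature(c("up1", "dn1"), c(1, -1))
  expect_equal(composite_score(m, sig, mode = "signed")$score,
               unname(z("up1") - z("dn1")))
  expect_equal(composite_score(m, sig, mode = "sum_all")$score,
               unname(z("up1") + z("dn1")))
})

test_that("missing and constant signature genes are dropped, not imputed", {
  set.seed(13)
  v <- rbind(g1 = simulate_bimodal_gene(5, 5),
             flat = rep(2, 10))
  colnames(v) <- paste0("s", 1:10)
  m <- toy_matrix(v)
  sig <- gene_signature(c("g1", "absent"), c(1, 1))
  expect_message(got <- composite_score(m, sig), "absent")
  expect_equal(nrow(got), 10L)
  expect_warning(composite_score(m, gene_signature(c("g1", "flat"), c(1, 1))),
                 "zero-variance gene 'flat'")
  expect_error(
    suppressMessages(composite_score(m, gene_signature("nope", 1))),
    "no signature gene found"
  )
})

test_that("modified z is invariant to shifting a gene's values", {
  set.seed(14)
  x <- simulate_bimodal_gene(8, 8)
  v1 <- rbind(g1 = x); v2 <- rbind(g1 = x + 4.2)
  colnames(v1) <- colnames(v2) <- paste0("s", 1:16)
  s1 <- composite_score(toy_matrix(v1), gene_signature("g1", 1))
  s2 <- composite_score(toy_matrix(v2), gene_signature("g1", 1))
  expect_equal(s1$score, s2$score)
})

test_that("roc_auc equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(1, 1, 2), c(0, 1, 1)),
               pair_auc(c(1, 1, 2), c(0, 1, 1)))
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE)) # both classes
    scores <- sample(1:5, n, replace = TRUE) # ties likely
    expect_equal(roc_auc(scores, labels), pair_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "non-empty")
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(22)
  scores <- rnorm(30)
  labels <- rep(0:1, 15)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
})

test_that("welch_t matches the textbook formula and its symmetries", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- welch_t(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_ref <- (mean(x) - mean(y)) / se
  df_ref <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(got$t, t_ref)
  expect_equal(got$df, df_ref)
  expect_equal(got$p, 2 * pt(abs(t_ref), df_ref, lower.tail = FALSE))

  rev <- welch_t(y, x)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  expect_error(welch_t(1, c(2, 3)), "at least 2")
})

test_that("score_and_classify assembles a coherent report", {
  set.seed(31)
  sim <- simulate_expression(sim_config(n_genes = 100, seed = 31))
  rep1 <- score_and_classify(sim$matrix, sim$signature, "condition",
                             positive = "autonomous")
  expect_s3_class(rep1, "score_report")
  expect_gte(rep1$auc, 0.95)
  expect_lt(rep1$p, 1e-6)
  expect_identical(rep1$direction, "up")
  g <- glance(rep1)
  expect_identical(g$positive, "autonomous")
  expect_equal(g$n_positive, 20L)
  expect_equal(nrow(tidy(rep1)), 40L)
  expect_true(!is.unsorted(tidy(rep1)$score))

  # permuting samples changes nothing
  perm <- sample(ncol(sim$matrix$values))
  m2 <- expression_matrix(
    sim$matrix$values[, perm],
    annotations = sim$matrix$annotations[perm, ]
  )
  rep2 <- score_and_classify(m2, sim$signature, "condition",
                             positive = "autonomous")
  expect_equal(rep2$auc, rep1$auc)
  expect_equal(rep2$t, rep1$t)
  expect_equal(rep2$p, rep1$p)

  expect_error(
    score_and_classify(sim$matrix, sim$signature, "missing_field"),
    "annotation column not found"
  )
})

test_that("flipping every signature direction negates signed scores", {
  set.seed(32)
  sim <- simulate_expression(sim_config(n_genes = 50, n_per_group = 8,
                                        seed = 32))
  sig <- sim$signature
  flipped <- gene_signature(sig$gene, -sig$direction)
  s1 <- composite_score(sim$matrix, sig)
  s2 <- composite_score(sim$matrix, flipped)
  expect_equal(s2$score, -s1$score)
})

test_that("score reports render as plot and TSV", {
  set.seed(33)
  sim <- simulate_expression(sim_config(n_genes = 60, n_per_group = 6,
                                        seed = 33))
  rep1 <- score_and_classify(sim$matrix, sim$signature, "condition",
                             positive = "autonomous")
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_report(rep1, path)
  expect_match(readLines(path, n = 1), "^# signature=planted auc=")
  back <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(back), 12L)
})
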