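make_two_group <- function(values) {
  n <- ncol(values)
  toy_matrix(values, groups = rep(c("A", "B"), each = n / 2))
}

test_that("per_gene_test recovers planted mean differences", {
  set.seed(41)
  v <- rbind(
    null = rnorm(12, 5, 0.1),
    shifted = c(rnorm(6, 10, 1e-4), rnorm(6, 4, 1e-4))
  )
  v <- rbind(v, flat = rep(1, 12))
  colnames(v) <- paste0("s", 1:12)
  deg <- per_gene_test(make_two_group(v), "condition")
  expect_identical(deg$gene, c("null", "shifted", "flat"))
  expect_equal(deg$logFC[2], 6, tolerance = 1e-3)
  expect_lt(deg$p[2], 1e-10)
  # identical distributions: flat gene gives exactly logFC 0, p 1
  expect_equal(deg$logFC[3], 0)
  expect_equal(deg$p[3], 1)
  expect_true(all(deg$padj >= deg$p))
})

test_that("swapping group order negates logFC and preserves p", {
  set.seed(42)
  v <- matrix(rnorm(80), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  m <- toy_matrix(v, groups = rep(c("A", "B"), each = 5))
  d1 <- per_gene_test(m, "condition", groups = c("A", "B"))
  d2 <- per_gene_test(m, "condition", groups = c("B", "A"))
  expect_equal(d2$logFC, -d1$logFC)
  expect_equal(d2$p, d1$p)
  expect_error(per_gene_test(toy_matrix(v[, 1:3, drop = FALSE],
                                        groups = c("A", "A", "B")),
                             "condition"),
               "at least 2 samples")
})

test_that("bh_adjust equals direct step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 4)), rep(0.5, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(43)
  for (i in 1:200) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("re-adjusting adjusted p-values never lowers them", {
  set.seed(44)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(bh_adjust(adj) >= adj - 1e-12))
  o <- order(p)
  expect_true(!is.unsorted(adj[o]))
})

test_that("filter_degs applies strict cuts in both directions", {
  tab <- tibble::tibble(
    gene = c("up", "down", "weak"),
    logFC = c(6, -6, 2),
    padj = c(0.001, 0.001, 0.001)
  )
  sig <- filter_degs(tab, lfc_cut = 5, padj_cut = 0.01)
  expect_identical(sig$gene, c("up", "down"))
  expect_identical(sig$direction, c(1L, -1L))

  tab2 <- tibble::tibble(gene = "g", logFC = 6, padj = 0.02)
  expect_warning(sig2 <- filter_degs(tab2, 5, 0.01), "empty")
  expect_equal(nrow(sig2), 0L)
})

test_that("filter_degs is monotone in its cutoffs", {
  set.seed(45)
  tab <- tibble::tibble(
    gene = paste0("g", 1:100),
    logFC = rnorm(100, sd = 4),
    padj = runif(100)
  )
  base <- filter_degs(tab, 2, 0.2)$gene
  expect_true(all(filter_degs(tab, 3, 0.2)$gene %in% base))
  expect_true(all(suppressWarnings(filter_degs(tab, 2, 0.05))$gene %in% base))
})

test_that("overrepresentation matches combinatorial enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(target = paste0("g", 1:5))
  res <- overrepresentation(paste0("g", 1:5), universe, sets)
  expect_equal(res$p, 1 / choose(10, 5))
  expect_equal(res$overlap, 5L)

  res0 <- overrepresentation(paste0("g", 6:10), universe, sets)
  expect_equal(res0$p, 1)
  expect_equal(res0$overlap, 0L)

  # random draws against brute-force enumeration in a small universe
  set.seed(46)
  for (i in 1:20) {
    N <- sample(8:14, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    universe <- paste0("u", seq_len(N))
    set_genes <- universe[seq_len(K)]
    hits <- sample(universe, n)
    res <- overrepresentation(hits, universe, list(s = set_genes))
    expect_equal(res$p, hyper_enum(N, K, n, res$overlap), tolerance = 1e-12)
  }

  expect_error(overrepresentation("g1", character(0), sets), "empty universe")
  expect_error(overrepresentation("zzz", universe, sets), "outside the universe")
})

test_that("GMT collections plug into overrepresentation", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathway1\tdesc\tg1\tg2\tg3", "pathway2\tdesc\tg8\tg9"), path)
  gmt <- read_gmt(path)
  res <- overrepresentation(c("g1", "g2"), paste0("g", 1:10), gmt)
  expect_identical(res$set[1], "pathway1")
  expect_lt(res$p[1], res$p[2])
  expect_equal(res$padj, bh_stepup(res$p))
})
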