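#' Per-gene two-group differential expression test
#'
#' For every gene: log2 fold change as the mean difference of log2 values
#' (first-listed group minus second) and a Welch t-test p-value, with
#' Benjamini-Hochberg adjusted p-values across genes. This is a plain
#' per-gene location test on log-scale values, not a count model.
#'
#' @param matrix An `expr_mat` on log2 scale.
#' @param group_field Annotation column with exactly two levels.
#' @param groups Optional length-2 character vector fixing which group is
#'   subtracted from which (`logFC = mean(groups[1]) - mean(groups[2])`);
#'   defaults to the sorted unique labels.
#' @return A tibble (one row per gene): `gene`, `logFC`, `t`, `df`, `p`,
#'   `padj`.
#' @export
per_gene_test <- function(matrix, group_field, groups = NULL) {
  stopifnot(inherits(matrix, "expr_mat"))
  if (!group_field %in% names(matrix$annotations)) {
    stop("annotation column not found: ", group_field)
  }
  lab <- as.character(matrix$annotations[[group_field]])
  lev <- groups %||% sort(unique(lab))
  if (length(lev) != 2L || !all(lev %in% lab)) {
    stop("`", group_field, "` must provide exactly 2 groups")
  }
  a <- matrix$values[, lab == lev[1L], drop = FALSE]
  b <- matrix$values[, lab == lev[2L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  res <- purrr::map(seq_len(nrow(a)), function(i) {
    wt <- welch_t(a[i, ], b[i, ])
    wt$logFC <- mean(a[i, ], na.rm = TRUE) - mean(b[i, ], na.rm = TRUE)
    wt
  })
  out <- dplyr::bind_rows(res)
  tibble::tibble(
    gene = rownames(matrix$values),
    logFC = out$logFC, t = out$t, df = out$df, p = out$p,
    padj = bh_adjust(out$p)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `p * m / rank`, made monotone from
#' the largest p downward and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Filter a differential-expression table into a gene signature
#'
#' Up genes satisfy `logFC > lfc_cut` and `padj < padj_cut`; down genes
#' `logFC < -lfc_cut` and `padj < padj_cut`. The defaults (5, 0.01) keep only
#' extreme, well-supported genes.
#'
#' @param table Output of [per_gene_test()] (needs `gene`, `logFC`, `padj`).
#' @param lfc_cut Absolute log2 fold-change cutoff (exclusive); default 5.
#' @param padj_cut Adjusted-p cutoff (exclusive); default 0.01.
#' @param name Name for the derived signature.
#' @return A `gene_signature` (with a warning if empty).
#' @export
filter_degs <- function(table, lfc_cut = 5, padj_cut = 0.01, name = "degs") {
  stopifnot(all(c("gene", "logFC", "padj") %in% names(table)))
  up <- table$logFC > lfc_cut & table$padj < padj_cut
  down <- table$logFC < -lfc_cut & table$padj < padj_cut
  keep <- which(up | down)
  gene_signature(
    table$gene[keep],
    ifelse(up[keep], 1L, -1L),
    name = name
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided upper-tail hypergeometric probability of
#' observing at least the seen overlap between `hits` and the set, drawing
#' `|hits|` genes from the universe. Sets are intersected with the universe
#' first; BH adjustment is applied across sets.
#'
#' @param hits Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector of all testable genes (e.g. all genes in
#'   the expression matrix).
#' @param collection Gene sets: a tibble from [read_gmt()] or a named list of
#'   character vectors.
#' @return A tibble per set: `set`, `set_size` (within the universe),
#'   `overlap`, `p`, `padj`, sorted by `p`.
#' @export
overrepresentation <- function(hits, universe, collection) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(as.character(hits))
  stray <- setdiff(hits, universe)
  if (length(stray) > 0L) {
    stop("hits outside the universe: ", paste(head(stray, 5L), collapse = ", "))
  }
  sets <- if (is.data.frame(collection)) {
    stats::setNames(collection$genes, collection$set)
  } else {
    collection
  }
  if (is.null(names(sets))) stop("`collection` gene sets must be named")
  N <- length(universe)
  n <- length(hits)
  out <- purrr::imap(sets, function(genes, set_name) {
    in_universe <- intersect(genes, universe)
    K <- length(in_universe)
    k <- length(intersect(hits, in_universe))
    tibble::tibble(
      set = set_name, set_size = K, overlap = k,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(out)
  out$padj <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, .data$set)
}
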