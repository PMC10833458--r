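#' Modified Z-score centered on the StepMiner threshold
#'
#' Re-centers an expression value on its gene's step threshold and scales by
#' three standard deviations: `(expr - sthr) / (3 * stddev)`. Division by
#' `3 * stddev` (rather than multiplication by `stddev / 3`) is deliberate:
#' the score of a gene must shrink, not grow, with its noise level.
#'
#' @param expr Expression value(s) of one gene.
#' @param sthr The gene's StepMiner threshold (see [gene_threshold()]).
#' @param stddev The gene's sample standard deviation across all samples of
#'   the dataset (must be positive).
#' @return Numeric vector of the same length as `expr`.
#' @export
modified_zscore <- function(expr, sthr, stddev) {
  if (!is.numeric(stddev) || length(stddev) != 1L || !is.finite(stddev) ||
      stddev <= 0) {
    stop("`stddev` must be a single positive number")
  }
  (expr - sthr) / (3 * stddev)
}

# per-gene modified z-score matrix for the usable signature genes
signature_zscores <- function(matrix, signature) {
  stopifnot(inherits(matrix, "expr_mat"), inherits(signature, "gene_signature"))
  present <- signature$gene %in% rownames(matrix$values)
  if (any(!present)) {
    message(
      "dropping ", sum(!present), " signature gene(s) absent from matrix: ",
      paste(head(signature$gene[!present], 10L), collapse = ", ")
    )
  }
  if (!any(present)) {
    stop(
      "no signature gene found in matrix; missing: ",
      paste(signature$gene, collapse = ", ")
    )
  }
  sig <- signature[present, ]
  keep <- rep(TRUE, nrow(sig))
  z <- matrix(NA_real_, nrow = nrow(sig), ncol = ncol(matrix$values),
              dimnames = list(sig$gene, colnames(matrix$values)))
  for (i in seq_len(nrow(sig))) {
    v <- matrix$values[sig$gene[i], ]
    sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      warning("excluding zero-variance gene '", sig$gene[i], "' from scoring")
      keep[i] <- FALSE
      next
    }
    z[i, ] <- modified_zscore(v, gene_threshold(matrix, sig$gene[i]), sdv)
  }
  if (!any(keep)) stop("no usable (non-constant) signature gene in matrix")
  list(z = z[keep, , drop = FALSE], signature = sig[keep, ])
}

#' Composite signature score per sample
#'
#' Sums each sample's per-gene modified Z-scores over the signature. In the
#' default `signed` mode down-regulated genes are subtracted
#' (`score = sum(z[up]) - sum(z[down])`); `sum_all` adds every gene
#' regardless of direction, preserving the plain summed-score variant.
#' Signature genes absent from the matrix are dropped with a message;
#' zero-variance genes are excluded with a warning.
#'
#' @param matrix An `expr_mat` (log2 scale).
#' @param signature A `gene_signature`.
#' @param mode `"signed"` (default) or `"sum_all"`.
#' @return A tibble with columns `sample_id`, `score`.
#' @export
composite_score <- function(matrix, signature, mode = c("signed", "sum_all")) {
  mode <- match.arg(mode)
  zs <- signature_zscores(matrix, signature)
  w <- if (mode == "signed") zs$signature$direction else rep(1L, nrow(zs$signature))
  score <- as.numeric(colSums(zs$z * w))
  tibble::tibble(sample_id = colnames(zs$z), score = score)
}

#' ROC-AUC of scores against binary labels
#'
#' Probability that a random positive-class sample scores above a random
#' negative-class sample, computed in the Mann-Whitney rank form
#' `U / (n1 * n0)` with ties counted 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (or 0/1, or a two-level factor) of the same
#'   length; `TRUE`/1/second level marks the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels)) {
    stop("`labels` must be binary and match `scores` in length")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch's two-sample t-test
#'
#' Unpaired, unequal variances, unequal sample sizes; two-sided p-value with
#' Welch-Satterthwaite degrees of freedom. The statistic's sign follows
#' `mean(x) - mean(y)`. Degenerate zero-variance input (which the underlying
#' test rejects) is resolved by the limit: equal means give `t = 0, p = 1`,
#' unequal means give an infinite statistic and `p = 0`.
#'
#' @param x,y Numeric vectors with at least 2 finite values each.
#' @return A one-row tibble with columns `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 finite values per group")
  }
  res <- tryCatch(
    t.test(x, y, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) { # essentially constant data
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1))
    }
    return(tibble::tibble(t = sign(mean(x) - mean(y)) * Inf,
                          df = NA_real_, p = 0))
  }
  tibble::tibble(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = res$p.value
  )
}

#' Score a signature and classify two sample groups
#'
#' Computes the composite signature score of every sample, then measures how
#' well the score separates the two groups named by `group_field`: ROC-AUC
#' (positive class having higher scores) and Welch's t-test on the scores.
#'
#' @param matrix An `expr_mat` whose annotations contain `group_field`.
#' @param signature A `gene_signature`.
#' @param group_field Name of the annotation column holding a binary group
#'   label.
#' @param positive Which group label is the positive class; defaults to the
#'   second sorted unique label (state it explicitly in analyses).
#' @param mode Scoring mode, see [composite_score()].
#' @return A `score_report`: per-sample scores plus separation statistics.
#'   Use [tidy()] for the per-sample table, [glance()] for the one-row
#'   summary, and [autoplot()] for a violin-style plot.
#' @export
score_and_classify <- function(matrix, signature, group_field,
                               positive = NULL,
                               mode = c("signed", "sum_all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "expr_mat"))
  if (!group_field %in% names(matrix$annotations)) {
    stop("annotation column not found: ", group_field)
  }
  groups <- as.character(matrix$annotations[[group_field]])
  lev <- sort(unique(groups))
  if (length(lev) != 2L) {
    stop("`", group_field, "` must have exactly 2 levels, found ",
         length(lev))
  }
  positive <- positive %||% lev[2L]
  if (!positive %in% lev) stop("positive class '", positive, "' not a level")

  scores <- composite_score(matrix, signature, mode = mode)
  scores$group <- groups[match(scores$sample_id,
                               matrix$annotations$sample_id)]
  is_pos <- scores$group == positive

  auc <- roc_auc(scores$score, is_pos)
  wt <- welch_t(scores$score[is_pos], scores$score[!is_pos])

  structure(
    list(
      scores = dplyr::arrange(scores, .data$score),
      signature_name = attr(signature, "name") %||% "signature",
      n_genes = length(unique(signature$gene)),
      group_field = group_field,
      positive = positive,
      negative = setdiff(lev, positive),
      n_positive = sum(is_pos),
      n_negative = sum(!is_pos),
      auc = auc,
      direction = if (auc >= 0.5) "up" else "down",
      t = wt$t, df = wt$df, p = wt$p,
      mode = mode
    ),
    class = "score_report"
  )
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "<score_report> '%s' (%d genes, %s mode)\n", x$signature_name,
    x$n_genes, x$mode
  ))
  cat(sprintf(
    "  %s (n=%d, positive) vs %s (n=%d) on `%s`\n",
    x$positive, x$n_positive, x$negative, x$n_negative, x$group_field
  ))
  cat(sprintf("  ROC-AUC = %.3f (%s), Welch t = %.3f (df %.1f), p = %.3g\n",
              x$auc, x$direction, x$t, x$df, x$p))
  invisible(x)
}

#' @rdname score_and_classify
#' @param x A `score_report`.
#' @param ... Unused.
#' @export
tidy.score_report <- function(x, ...) x$scores

#' @rdname score_and_classify
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(
    signature = x$signature_name, n_genes = x$n_genes,
    positive = x$positive, n_positive = x$n_positive,
    negative = x$negative, n_negative = x$n_negative,
    auc = x$auc, direction = x$direction,
    t = x$t, df = x$df, p = x$p, mode = x$mode
  )
}

#' Write a score report as a tidy TSV
#'
#' Per-sample scores with the one-row summary prepended as `#` comments.
#'
#' @param x A `score_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(x, path) {
  stopifnot(inherits(x, "score_report"))
  g <- glance(x)
  header <- sprintf(
    "# signature=%s auc=%.6g t=%.6g p=%.6g positive=%s mode=%s",
    g$signature, g$auc, g$t, g$p, g$positive, g$mode
  )
  writeLines(header, path)
  readr::write_tsv(tidy(x), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
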