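#' Fit a one-step function to an ordered series
#'
#' Evaluates every split position `k` in `1..n-1`, fits the left segment to
#' the mean of the first `k` values and the right segment to the mean of the
#' rest, and keeps the split minimizing the sum of squared residuals (first
#' minimum wins when several splits tie). The regression statistic is
#'
#' \deqn{F = \frac{\sum_i (\hat X_i - \bar X)^2 / (m - 1)}
#'                {\sum_i (X_i - \hat X_i)^2 / (n - m)}}
#'
#' with `m = 3` model degrees of freedom (two segment means plus the step
#' position). The binarization threshold is the midpoint of the two segment
#' means, `sthr = (mu_left + mu_right) / 2`.
#'
#' A constant series has no step to fit: the fit is flagged `no_step`, with
#' `sthr` equal to the grand mean and an undefined F statistic.
#'
#' @param x Numeric vector, length >= 2, finite values, in the order the step
#'   is sought (use [gene_threshold()] for unordered per-gene expression,
#'   which sorts first).
#' @return An object of class `step_fit`: a list with elements `n`, `k`,
#'   `mu_left`, `mu_right`, `sse`, `fstat`, `sthr`, `no_step`, `fitted`.
#' @examples
#' fit_step(c(1, 1, 1, 5, 5, 5))
#' @export
fit_step <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  x <- unname(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to fit a step")
  if (any(!is.finite(x))) stop("`x` must be finite")

  grand <- mean(x)
  if (all(x == x[1L])) {
    return(new_step_fit(
      n = n, k = NA_integer_, mu_left = grand, mu_right = grand,
      sse = 0, fstat = NA_real_, sthr = grand, no_step = TRUE,
      fitted = rep(grand, n)
    ))
  }

  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs[n]
  total2 <- cs2[n]
  k <- seq_len(n - 1L)
  # per-split SSE = within-left + within-right sum of squares
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (total2 - cs2[k]) - (total - cs[k])^2 / (n - k)
  sse_all <- pmax(sse_left + sse_right, 0)
  # first minimum wins on ties; the tolerance keeps mathematically tied
  # splits (common in discretized data) from resolving on rounding noise
  tol <- 1e-10 * (total2 - total^2 / n)
  best <- which(sse_all <= min(sse_all) + tol)[1L]
  mu_left <- cs[best] / best
  mu_right <- (total - cs[best]) / (n - best)
  fitted <- c(rep(mu_left, best), rep(mu_right, n - best))
  sse <- sse_all[best]

  m <- 3
  fstat <- if (n > m) {
    num <- sum((fitted - grand)^2) / (m - 1)
    den <- sse / (n - m)
    if (den == 0) Inf else num / den
  } else {
    NA_real_
  }

  new_step_fit(
    n = n, k = as.integer(best), mu_left = mu_left, mu_right = mu_right,
    sse = sse, fstat = fstat, sthr = (mu_left + mu_right) / 2,
    no_step = FALSE, fitted = fitted
  )
}

new_step_fit <- function(n, k, mu_left, mu_right, sse, fstat, sthr,
                         no_step, fitted) {
  structure(
    list(n = n, k = k, mu_left = mu_left, mu_right = mu_right, sse = sse,
         fstat = fstat, sthr = sthr, no_step = no_step, fitted = fitted),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  if (x$no_step) {
    cat(sprintf("<step_fit> no step (constant series, n = %d), sthr = %g\n",
                x$n, x$sthr))
  } else {
    cat(sprintf(
      "<step_fit> n = %d, k = %d, means %.4g -> %.4g, sthr = %.4g, sse = %.4g\n",
      x$n, x$k, x$mu_left, x$mu_right, x$sthr, x$sse
    ))
  }
  invisible(x)
}

#' @rdname fit_step
#' @param x A `step_fit`.
#' @param ... Unused.
#' @export
tidy.step_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, mu_left = x$mu_left, mu_right = x$mu_right,
    sse = x$sse, fstat = x$fstat, sthr = x$sthr, no_step = x$no_step
  )
}

#' @export
glance.step_fit <- function(x, ...) tidy.step_fit(x, ...)

#' StepMiner threshold of one gene
#'
#' Sorts the gene's expression values ascending, fits a one-step function,
#' and returns the threshold `sthr`. Sorting makes the threshold independent
#' of sample order; a constant gene yields its constant value with a warning.
#'
#' @param matrix An `expr_mat`.
#' @param gene Gene id present in the matrix.
#' @return The threshold (a single number).
#' @export
gene_threshold <- function(matrix, gene) {
  stopifnot(inherits(matrix, "expr_mat"))
  if (!gene %in% rownames(matrix$values)) {
    stop("gene not in matrix: ", gene)
  }
  v <- matrix$values[gene, ]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("gene '", gene, "' has fewer than 2 usable values")
  fit <- fit_step(sort(v))
  if (fit$no_step) {
    warning("no step for constant gene '", gene, "'; threshold = its value")
  }
  fit$sthr
}

#' StepMiner thresholds for every gene of a matrix
#'
#' @param matrix An `expr_mat`.
#' @return A tibble with columns `gene`, `sthr`, `fstat`, `no_step`.
#' @export
gene_thresholds <- function(matrix) {
  stopifnot(inherits(matrix, "expr_mat"))
  fits <- apply(matrix$values, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      return(tibble::tibble(sthr = NA_real_, fstat = NA_real_, no_step = TRUE))
    }
    fit <- fit_step(sort(v))
    tibble::tibble(sthr = fit$sthr, fstat = fit$fstat, no_step = fit$no_step)
  })
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(matrix$values)),
    dplyr::bind_rows(fits)
  )
}

#' Binarize expression at per-gene StepMiner thresholds
#'
#' Each value is classified against its gene's threshold: above
#' `sthr + margin` is high (1), below `sthr - margin` is low (0), and the
#' intermediate band is `NA`. With the default `margin = 0` the output is
#' strictly binary and a value exactly at the threshold classifies as low.
#'
#' @param matrix An `expr_mat`.
#' @param margin Nonnegative half-width of the intermediate band; default 0.
#' @param thresholds Optional precomputed threshold table (`gene`, `sthr`) as
#'   returned by [gene_thresholds()]; computed from `matrix` when omitted.
#' @return An integer matrix (same dimnames) of 0 / 1 / `NA`.
#' @export
binarize <- function(matrix, margin = 0, thresholds = NULL) {
  stopifnot(inherits(matrix, "expr_mat"))
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0) {
    stop("`margin` must be a single nonnegative number")
  }
  thr <- thresholds %||% gene_thresholds(matrix)
  if (!all(rownames(matrix$values) %in% thr$gene)) {
    stop("`thresholds` must cover every gene of the matrix")
  }
  thr <- thr[match(rownames(matrix$values), thr$gene), ]
  v <- matrix$values
  out <- array(NA_integer_, dim = dim(v), dimnames = dimnames(v))
  hi <- !is.na(v) & v > thr$sthr + margin
  lo <- !is.na(v) & v < thr$sthr - margin
  out[hi] <- 1L
  out[lo] <- 0L
  if (margin == 0) {
    # ties at the threshold classify as low
    out[!hi & !lo & !is.na(v)] <- 0L
  }
  out
}
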