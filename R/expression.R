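#' Construct an expression matrix
#'
#' The canonical container every downstream stage consumes: a genes-by-samples
#' numeric matrix (log2 scale once normalized) plus a per-sample annotation
#' table. Gene and sample identifiers are opaque, case-sensitive strings; no
#' symbol/alias resolution is attempted.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique. `NA` marks an explicitly
#'   missing entry; non-finite values (`NaN`, `Inf`) are rejected.
#' @param annotations Optional tibble/data frame with a `sample_id` column
#'   covering every sample; extra columns carry group labels, survival fields,
#'   etc. Defaults to a bare `sample_id` table.
#' @param log_scale Logical flag recording whether `values` are already on
#'   log2 scale (`TRUE`) or raw counts (`FALSE`, see [log_cpm()]).
#' @return An object of class `expr_mat`.
#' @seealso [read_expression()], [log_cpm()]
#' @export
expression_matrix <- function(values, annotations = NULL, log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g) > 0L) {
    stop("duplicate gene id: ", dup_g[1L])
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0L) {
    stop("duplicate sample id: ", dup_s[1L])
  }
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite value at gene '%s', sample '%s'",
      gene_ids[idx[1L]], sample_ids[idx[2L]]
    ))
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(sample_id = sample_ids)
  } else {
    annotations <- tibble::as_tibble(annotations)
    if (!"sample_id" %in% names(annotations)) {
      stop("`annotations` must have a `sample_id` column")
    }
    missing <- setdiff(sample_ids, annotations$sample_id)
    if (length(missing) > 0L) {
      stop("annotations missing sample: ", missing[1L])
    }
    annotations <- annotations[match(sample_ids, annotations$sample_id), ]
  }
  structure(
    list(values = values, annotations = annotations,
         log_scale = isTRUE(log_scale)),
    class = "expr_mat"
  )
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
dimnames.expr_mat <- function(x) dimnames(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values),
    if (x$log_scale) "log2" else "count"
  ))
  extra <- setdiff(names(x$annotations), "sample_id")
  if (length(extra) > 0L) {
    cat("annotations:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.expr_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$annotations, by = "sample_id")
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects genes in rows: the first column holds gene ids and the header row
#' holds sample ids. Transposed input must be transposed by the caller before
#' reading -- there is deliberately no auto-detection, since a silently
#' transposed matrix is a classic corruption mode.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   treated as comments.
#' @param log_scale Whether the stored values are already log2 scale
#'   (default) or raw counts.
#' @param annotations Optional per-sample annotation table (see
#'   [expression_matrix()]).
#' @return An `expr_mat`.
#' @export
read_expression <- function(path, log_scale = TRUE, annotations = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L || !nzchar(trimws(lines[1L]))) {
    stop("no header in '", path, "'")
  }
  raw <- readr::read_tsv(
    I(lines),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2L) {
    stop("'", path, "' has no sample columns")
  }
  gene_ids <- raw[[1L]]
  sample_ids <- names(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- is.na(num) & !(is.na(body) | body %in% c("NA", "NaN"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
      body[idx[1L], idx[2L]], gene_ids[idx[1L]], idx[1L], sample_ids[idx[2L]]
    ))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num, annotations = annotations, log_scale = log_scale)
}

#' Write an expression matrix to TSV
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @param digits Optional number of significant digits; by default values are
#'   written at full double precision so a read/write round trip is lossless.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  values <- x$values
  if (!is.null(digits)) values <- signif(values, digits)
  out <- tibble::as_tibble(values, rownames = "gene")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Log-CPM normalization of a count matrix
#'
#' Scales each sample (column) to one million total counts, then applies
#' `log2(x + pseudocount)`. Column order is preserved.
#'
#' @param x A nonnegative count matrix with dimnames, or an `expr_mat` holding
#'   counts (`log_scale = FALSE`).
#' @param pseudocount Positive value added before the log; default 1.
#' @return An `expr_mat` on log2 scale.
#' @export
log_cpm <- function(x, pseudocount = 1) {
  annotations <- NULL
  if (inherits(x, "expr_mat")) {
    if (x$log_scale) {
      stop("`x` is flagged as log scale already; log_cpm expects raw counts")
    }
    annotations <- x$annotations
    x <- x$values
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number")
  }
  if (any(x < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  totals <- colSums(x, na.rm = TRUE)
  if (any(totals == 0)) {
    stop("all-zero counts for sample: ", colnames(x)[which(totals == 0)[1L]])
  }
  cpm <- sweep(x, 2L, totals, "/") * 1e6
  expression_matrix(log2(cpm + pseudocount),
                    annotations = annotations, log_scale = TRUE)
}

#' Construct a gene signature
#'
#' A signature is a set of genes with directions: +1 for genes expected high
#' in the positive condition, -1 for genes expected low. Down genes contribute
#' with opposite sign to the composite score (see [composite_score()]).
#'
#' @param genes Character vector of gene ids (no duplicates).
#' @param directions Vector of +1/-1 (or "up"/"down"), one per gene.
#' @param name Signature name.
#' @return A tibble of class `gene_signature` with columns `gene`, `direction`.
#' @export
gene_signature <- function(genes, directions, name = "signature") {
  genes <- as.character(genes)
  directions <- parse_direction(directions)
  if (length(genes) != length(directions)) {
    stop("`genes` and `directions` must have equal length")
  }
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) stop("duplicate gene in signature: ", dup[1L])
  if (length(genes) == 0L) {
    warning("empty gene signature '", name, "'")
  }
  out <- tibble::tibble(gene = genes, direction = directions)
  class(out) <- c("gene_signature", class(out))
  attr(out, "name") <- name
  out
}

parse_direction <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(1, -1))) {
      stop("numeric directions must be +1 or -1")
    }
    return(as.integer(x))
  }
  tok <- tolower(as.character(x))
  out <- dplyr::case_when(
    tok %in% c("up", "+1", "1") ~ 1L,
    tok %in% c("down", "-1") ~ -1L,
    .default = NA_integer_
  )
  if (anyNA(out)) {
    stop("unknown direction token: '", x[which(is.na(out))[1L]], "'")
  }
  out
}

#' Read a gene signature from a two-column TSV
#'
#' Each line holds `gene_id<TAB>direction` with direction one of
#' `up`, `down`, `+1`, `-1`. No header line is expected.
#'
#' @param path Path to the signature file.
#' @param name Signature name; defaults to the file name.
#' @return A `gene_signature`.
#' @export
read_signature <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(
    path,
    col_names = c("gene", "direction"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  gene_signature(raw$gene, raw$direction, name = name)
}

#' Write a gene signature to TSV
#'
#' @param signature A `gene_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  out <- tibble::tibble(
    gene = signature$gene,
    direction = ifelse(signature$direction > 0, "up", "down")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' @param path TSV with a header; must contain a `sample_id` column. Typical
#'   extra columns: a group label, survival `time` and `event`.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         comment = "#", progress = FALSE)
  if (!"sample_id" %in% names(out)) {
    stop("annotation table must have a `sample_id` column")
  }
  out
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set`, `description`, and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line ", short[1L], ": fewer than 3 fields")
  }
  tibble::tibble(
    set = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}
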