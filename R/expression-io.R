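# Expression matrices travel as tibbles: first column `gene_id` (character,
# unique), remaining columns one numeric vector per sample, log2 scale.
# Sample class labels travel separately as a two-column tibble
# (sample_id, label) with label coded 0 = control, 1 = case.

#' Validate an expression tibble and return its numeric matrix
#'
#' Internal workhorse: checks the tidy expression layout (gene_id first,
#' numeric sample columns, finite values, unique ids) and returns the
#' genes-by-samples numeric matrix with dimnames.
#'
#' @param expr Expression tibble.
#' @param what Label used in error messages.
#' @return Numeric matrix, rows = genes, columns = samples.
#' @keywords internal
expr_matrix <- function(expr, what = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2L) {
    abort(sprintf("`%s` must be a data frame with a gene_id column and >= 1 sample column", what))
  }
  if (names(expr)[1] != "gene_id") {
    abort(sprintf("first column of `%s` must be named 'gene_id', found '%s'", what, names(expr)[1]))
  }
  gene_ids <- as.character(expr[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(sprintf("duplicate gene_id values in `%s`: %s (resolve with read_expression(duplicate_policy=))",
                  what, paste(head(dup, 5L), collapse = ", ")))
  }
  vals <- expr[-1L]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric sample column(s) in `%s`: %s", what, paste(head(bad, 5L), collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (anyNA(m) || !all(is.finite(m))) {
    ij <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite value in `%s` at gene '%s', sample '%s' (missing values are not supported)",
                  what, gene_ids[ij[1L]], colnames(m)[ij[2L]]))
  }
  m
}

#' Convert a genes-by-samples matrix to the tidy expression layout
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return Expression tibble (`gene_id` + one column per sample).
#' @export
as_expr_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers with the gene identifier in
#' the first column. Duplicate gene rows are resolved by the chosen policy:
#' per-sample mean (order-independent, default) or the single row with
#' maximal variance.
#'
#' @param path Path to the TSV matrix.
#' @param labels_path Optional path to a sample-annotation TSV with columns
#'   `sample_id` and `label`; every annotated sample must exist in the matrix.
#' @param duplicate_policy How to resolve duplicated gene identifiers.
#' @return Expression tibble; when `labels_path` is given the label tibble is
#'   attached as attribute `"labels"` (also retrievable with [read_labels()]).
#' @export
read_expression <- function(path, labels_path = NULL,
                            duplicate_policy = c("mean", "max_variance")) {
  duplicate_policy <- match.arg(duplicate_policy)
  hdr <- names(readr::read_tsv(path, n_max = 0L, col_types = readr::cols(), progress = FALSE))
  if (length(hdr) < 2L) abort(sprintf("malformed header in '%s': need gene column + >= 1 sample", path))
  if (anyDuplicated(hdr[-1L])) {
    abort(sprintf("malformed header in '%s': duplicated sample id '%s'",
                  path, hdr[-1L][duplicated(hdr[-1L])][1L]))
  }
  spec <- do.call(readr::cols, c(
    setNames(list(readr::col_character()), hdr[1L]),
    list(.default = readr::col_double())
  ))
  # parse problems surface as our own error below, not as a readr warning
  raw <- suppressWarnings(readr::read_tsv(path, col_types = spec, progress = FALSE))
  names(raw)[1L] <- "gene_id"
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(sprintf("non-numeric cell in '%s' at row %d, column %d (expected %s)",
                  path, prob$row[1L], prob$col[1L], prob$expected[1L]))
  }
  if (anyNA(raw)) {
    ij <- which(is.na(as.matrix(raw[-1L])), arr.ind = TRUE)[1L, ]
    abort(sprintf("missing value in '%s' at gene '%s', sample '%s'",
                  path, raw$gene_id[ij[1L]], names(raw)[-1L][ij[2L]]))
  }
  expr <- resolve_duplicates(raw, duplicate_policy)
  if (!is.null(labels_path)) {
    labels <- read_labels(labels_path)
    missing <- setdiff(labels$sample_id, names(expr)[-1L])
    if (length(missing)) {
      abort(sprintf("annotated sample(s) not in matrix '%s': %s",
                    path, paste(head(missing, 5L), collapse = ", ")))
    }
    attr(expr, "labels") <- labels
  }
  expr
}

resolve_duplicates <- function(raw, policy) {
  if (!anyDuplicated(raw$gene_id)) return(raw)
  if (policy == "mean") {
    out <- raw |>
      group_by(gene_id = .data$gene_id) |>
      summarise(across(dplyr::everything(), mean), .groups = "drop")
    # restore first-occurrence order
    out[match(unique(raw$gene_id), out$gene_id), ]
  } else {
    v <- apply(as.matrix(raw[-1L]), 1L, stats::var)
    keep <- !logical(nrow(raw))
    for (g in unique(raw$gene_id[duplicated(raw$gene_id)])) {
      idx <- which(raw$gene_id == g)
      keep[idx] <- FALSE
      keep[idx[which.max(v[idx])]] <- TRUE
    }
    raw[keep, ]
  }
}

#' Read a sample-annotation table
#'
#' @param path TSV with columns `sample_id` and `label` (0 = control, 1 = case).
#' @return Tibble with character `sample_id` and integer `label`.
#' @export
read_labels <- function(path) {
  labels <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(labels))) {
    abort(sprintf("annotation '%s' must have columns sample_id, label", path))
  }
  labels[c("sample_id", "label")]
}

#' Write an expression tibble as TSV
#'
#' Inverse of [read_expression()]; round-trips values at the given precision.
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @param digits Significant digits written.
#' @export
write_expression <- function(expr, path, digits = 10L) {
  m <- expr_matrix(expr)
  out <- as_expr_tbl(signif(m, digits))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Log2(x + 1) transform of non-negative abundance values
#'
#' Standard final transform for TPM-scale RNA-seq abundances: each cell
#' becomes log2(value + 1), so 0 maps to 0 and 1 maps to 1.
#'
#' @param counts Expression tibble of non-negative values (e.g. TPM).
#' @return Expression tibble on log2 scale.
#' @export
log2_tpm <- function(counts) {
  m <- expr_matrix(counts, "counts")
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("negative abundance at gene '%s', sample '%s'",
                  rownames(m)[ij[1L]], colnames(m)[ij[2L]]))
  }
  as_expr_tbl(log2(m + 1))
}

#' Dynamic-range gene filter
#'
#' Drops genes whose discretized calls are almost one-sided: a gene is kept
#' only if at least `min_frac` of its samples are called HIGH and at least
#' `min_frac` are called LOW (fractions over all samples, intermediates
#' included in the denominator). Genes with too small a dynamic range cannot
#' support a meaningful low/high split and would only add noise to the
#' pairwise Boolean analysis.
#'
#' @param expr Expression tibble the trits were computed from.
#' @param trits A [discretize_matrix()] result on the same data.
#' @param min_frac Minimum fraction of LOW and of HIGH calls (default 0.05).
#' @return Expression tibble restricted to passing genes, order preserved.
#'   Genes skipped during discretization (constant rows) are dropped too.
#' @export
filter_dynamic_range <- function(expr, trits, min_frac = 0.05) {
  stopifnot(inherits(trits, "trit_matrix"), min_frac >= 0, min_frac <= 0.5)
  m <- expr_matrix(expr)
  extra <- setdiff(rownames(trits$trits), rownames(m))
  if (length(extra)) {
    abort(sprintf("trits contain gene(s) absent from expr: %s",
                  paste(head(extra, 5L), collapse = ", ")))
  }
  if (!identical(colnames(trits$trits), colnames(m))) {
    abort("sample sets of expr and trits differ")
  }
  tr <- trits$trits
  ns <- ncol(tr)
  frac_low <- rowSums(tr == TRIT_LOW) / ns
  frac_high <- rowSums(tr == TRIT_HIGH) / ns
  keep <- rownames(tr)[frac_low >= min_frac & frac_high >= min_frac]
  expr[expr$gene_id %in% keep, , drop = FALSE]
}
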