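# StepMiner: fit a single rising step to a gene's sorted expression values.
# The midpoint of the two segment means is the discretization threshold; a
# +/- margin band (0.5 on log2 scale, i.e. 2-fold) around it is called
# INTERMEDIATE and excluded from the pairwise Boolean analysis.

#' Fit a single rising step to a numeric vector
#'
#' Values are sorted ascending internally, every step position
#' k = 1..n-1 is evaluated by fitting the two segment means, and the
#' position with minimal residual sum of squares wins (ties broken by the
#' smallest k). The threshold is the midpoint of the two segment means.
#' The regression statistic is
#' \deqn{F = \frac{\sum_i (\hat X_i - \bar X)^2 / (m - 1)}
#'            {\sum_i (X_i - \hat X_i)^2 / (n - m)}}
#' with fitted values \eqn{\hat X_i} equal to the segment means and model
#' degrees of freedom `m` (default 3: two means plus the breakpoint).
#' A perfect step (zero residual) reports `F = Inf`.
#'
#' @param values Numeric vector, length >= 3, finite, not all equal.
#' @param m_df Model degrees of freedom used in the F statistic.
#' @return An object of class `step_fit`: a list with `step_index` (k on the
#'   sorted series), `mean_low`, `mean_high`, `threshold`, `f_stat`, `sse`,
#'   `stddev` (sample sd, n-1 denominator), `n`, `m_df`.
#' @export
fit_step <- function(values, m_df = 3) {
  if (!is.numeric(values) || length(values) < 3L) {
    abort("undefined threshold: need >= 3 numeric values")
  }
  if (anyNA(values) || !all(is.finite(values))) abort("values must be finite")
  if (max(values) == min(values)) {
    abort("undefined threshold: constant vector")
  }
  xs <- sort(unname(values))
  n <- length(xs)
  cs <- cumsum(xs)
  k_all <- seq_len(n - 1L)
  m1 <- cs[k_all] / k_all
  m2 <- (cs[n] - cs[k_all]) / (n - k_all)
  # SSE_k = sum(x^2) - k m1^2 - (n-k) m2^2; only the comparison needs it
  sse_k <- sum(xs^2) - k_all * m1^2 - (n - k_all) * m2^2
  k <- which.min(sse_k)  # which.min takes the first (smallest k) on ties
  fitted <- c(rep(m1[k], k), rep(m2[k], n - k))
  sse <- sum((xs - fitted)^2)
  ssr <- sum((fitted - mean(xs))^2)
  f_stat <- if (sse == 0) Inf else (ssr / (m_df - 1)) / (sse / (n - m_df))
  structure(list(
    step_index = k,
    mean_low = m1[k],
    mean_high = m2[k],
    threshold = (m1[k] + m2[k]) / 2,
    f_stat = f_stat,
    sse = sse,
    stddev = sd(values),
    n = n,
    m_df = m_df
  ), class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> n=%d k=%d threshold=%.4g F=%.4g sse=%.4g\n",
              x$n, x$step_index, x$threshold, x$f_stat, x$sse))
  invisible(x)
}

#' @rdname fit_step
#' @param x A `step_fit` object.
#' @param ... Unused.
#' @method tidy step_fit
#' @export
tidy.step_fit <- function(x, ...) {
  tibble(step_index = x$step_index, mean_low = x$mean_low,
         mean_high = x$mean_high, threshold = x$threshold,
         f_stat = x$f_stat, sse = x$sse, stddev = x$stddev, n = x$n)
}

#' Per-gene step fits for an expression tibble
#'
#' @param expr Expression tibble.
#' @param m_df Model degrees of freedom for the F statistic.
#' @return Tibble with one row per fit-able gene (columns of
#'   [tidy.step_fit()] plus `gene_id`); genes failing the fit preconditions
#'   are absent (see [discretize_matrix()] for the skip report).
#' @export
step_fits <- function(expr, m_df = 3) {
  m <- expr_matrix(expr)
  fits <- lapply(rownames(m), function(g) {
    tryCatch(tidy(fit_step(m[g, ], m_df = m_df)), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  bind_cols(tibble(gene_id = rownames(m)[ok]), bind_rows(fits[ok]))
}

#' Discretize one value against a threshold with a noise margin
#'
#' @param value Numeric vector of expression values.
#' @param threshold StepMiner threshold.
#' @param margin Noise half-width; values within `threshold +/- margin`
#'   (boundaries included) are INTERMEDIATE.
#' @return Integer trit vector: 0 = LOW, 1 = INTERMEDIATE, 2 = HIGH.
#' @export
discretize <- function(value, threshold, margin = 0.5) {
  stopifnot(is.numeric(value), is.numeric(threshold), margin >= 0)
  if (anyNA(value) || !all(is.finite(value))) abort("value must be finite")
  # LOW = 0, INTERMEDIATE = 1, HIGH = 2; boundaries are INTERMEDIATE
  (value >= threshold - margin) + (value > threshold + margin)
}

#' Discretize an expression tibble into a trit matrix
#'
#' Fits the StepMiner threshold per gene (on its sorted values) and applies
#' it with the noise margin to that gene's unsorted values. Genes that
#' cannot be fit (constant, too short) are reported in `skipped`, not
#' silently dropped.
#'
#' @param expr Expression tibble.
#' @param margin Noise half-width (default 0.5, i.e. 2-fold on log2 scale).
#' @param m_df Model degrees of freedom for the F statistic.
#' @return An object of class `trit_matrix`: list with `trits` (integer
#'   genes-by-samples matrix, 0/1/2), `fits` (the [step_fits()] tibble),
#'   `skipped` (character), and `margin`.
#' @export
discretize_matrix <- function(expr, margin = 0.5, m_df = 3) {
  m <- expr_matrix(expr)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty expression matrix")
  fits <- step_fits(expr, m_df = m_df)
  skipped <- setdiff(rownames(m), fits$gene_id)
  if (length(skipped)) {
    inform(sprintf("discretize_matrix: skipped %d gene(s) with undefined threshold: %s",
                   length(skipped), paste(head(skipped, 5L), collapse = ", ")))
  }
  keep <- m[fits$gene_id, , drop = FALSE]
  thr <- matrix(fits$threshold[row(keep)], nrow = nrow(keep))
  tr <- discretize(keep, thr, margin)
  dimnames(tr) <- dimnames(keep)
  structure(list(trits = tr, fits = fits, skipped = skipped, margin = margin),
            class = "trit_matrix")
}

#' @export
print.trit_matrix <- function(x, ...) {
  cat(sprintf("<trit_matrix> %d genes x %d samples (margin %.3g, %d skipped)\n",
              nrow(x$trits), ncol(x$trits), x$margin, length(x$skipped)))
  invisible(x)
}

#' @rdname discretize_matrix
#' @param x A `trit_matrix`.
#' @param ... Unused.
#' @method tidy trit_matrix
#' @export
tidy.trit_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$trits, stringsAsFactors = FALSE)) |>
    setNames(c("gene_id", "sample_id", "trit")) |>
    mutate(trit = as.integer(.data$trit),
           call = c("LOW", "INTERMEDIATE", "HIGH")[.data$trit + 1L])
}

#' @rdname discretize_matrix
#' @method glance trit_matrix
#' @export
glance.trit_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$trits), n_samples = ncol(x$trits),
         n_skipped = length(x$skipped), margin = x$margin,
         frac_intermediate = mean(x$trits == TRIT_INT))
}
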