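# Independent oracles, written as direct transcriptions of the defining
# formulas; deliberately naive and separate from the package internals.

# Exhaustive step fit: loop over every split point, recompute segment means
# and residual sum of squares from scratch.
oracle_fit_step <- function(values) {
  xs <- sort(values)
  n <- length(xs)
  best <- NULL
  for (k in 1:(n - 1)) {
    m1 <- mean(xs[1:k])
    m2 <- mean(xs[(k + 1):n])
    sse <- sum((xs[1:k] - m1)^2) + sum((xs[(k + 1):n] - m2)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(k = k, mean_low = m1, mean_high = m2,
                   threshold = (m1 + m2) / 2, sse = sse)
    }
  }
  best
}

# Sparse-quadrant test for a single quadrant of one count table.
oracle_sparse <- function(a00, a01, a10, a11, quadrant, sthr, pthr) {
  total <- a00 + a01 + a10 + a11
  if (total == 0) return(FALSE)
  n <- switch(quadrant, "00" = a00, "01" = a01, "10" = a10, "11" = a11)
  row <- switch(quadrant, "00" = , "01" = a00 + a01, a10 + a11)
  col <- switch(quadrant, "00" = , "10" = a00 + a10, a01 + a11)
  if (row == 0 || col == 0) return(FALSE)
  nhat <- (row / total) * (col / total) * total
  if (nhat <= 0) return(FALSE)
  s <- (nhat - n) / sqrt(nhat)
  p <- (n / row + n / col) / 2
  s > sthr && p < pthr
}

# One-table relationship classifier following the six defining equations:
# equivalent = sparse {01,10}; opposite = sparse {00,11}; A low => B high
# from sparse 00; A low => B low from sparse 01; A high => B high from
# sparse 10; A high => B low from sparse 11; only the single-quadrant and
# diagonal-pair patterns are relationships.
oracle_classify <- function(a00, a01, a10, a11, sthr = 3, pthr = 0.1) {
  sp <- vapply(c("00", "01", "10", "11"), function(q) {
    oracle_sparse(a00, a01, a10, a11, q, sthr, pthr)
  }, logical(1))
  k <- sum(sp)
  if (k == 2 && sp[["01"]] && sp[["10"]]) return("EQUIVALENT")
  if (k == 2 && sp[["00"]] && sp[["11"]]) return("OPPOSITE")
  if (k == 1) {
    return(c("00" = "LOHI", "01" = "LOLO",
             "10" = "HIHI", "11" = "HILO")[[names(sp)[sp]]])
  }
  "NONE"
}

# Pair-counting ROC-AUC: concordant case/control pairs plus half ties.
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (x in cases) for (y in ctrls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(ctrls))
}
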