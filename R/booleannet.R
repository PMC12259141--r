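# BooleanNet sparse-quadrant statistics. For a gene pair (A, B) the samples
# with both genes called LOW or HIGH fall in four quadrants
#   a00 = A low & B low,  a01 = A low & B high,
#   a10 = A high & B low, a11 = A high & B high
# (intermediate calls excluded). A quadrant ij with observed count n and
# independence expectation nhat = (row marginal / total) * (col marginal /
# total) * total is sparse when S = (nhat - n) / sqrt(nhat) exceeds sThr and
# the error rate p = (n / rowsum + n / colsum) / 2 is below pThr. One sparse
# quadrant gives an asymmetric implication; the sparse diagonal pairs give
# EQUIVALENT ({01,10}) and OPPOSITE ({00,11}).

quadrant_defs <- list(
  # row marginal = A side, col marginal = B side for each quadrant
  q00 = list(row = c("a00", "a01"), col = c("a00", "a10")),
  q01 = list(row = c("a00", "a01"), col = c("a01", "a11")),
  q10 = list(row = c("a10", "a11"), col = c("a00", "a10")),
  q11 = list(row = c("a10", "a11"), col = c("a01", "a11"))
)

#' Quadrant counts for a pair of trit vectors
#'
#' @param trits_a,trits_b Equal-length integer trit vectors (0/1/2) aligned
#'   by sample.
#' @return One-row tibble with `a00`, `a01`, `a10`, `a11`, `total`; samples
#'   INTERMEDIATE in either gene are excluded.
#' @export
quadrant_counts <- function(trits_a, trits_b) {
  if (length(trits_a) != length(trits_b)) abort("trit vectors differ in length")
  ok <- trits_a != TRIT_INT & trits_b != TRIT_INT
  a <- trits_a[ok] == TRIT_HIGH
  b <- trits_b[ok] == TRIT_HIGH
  tibble(
    a00 = sum(!a & !b), a01 = sum(!a & b),
    a10 = sum(a & !b), a11 = sum(a & b)
  ) |> mutate(total = .data$a00 + .data$a01 + .data$a10 + .data$a11)
}

# Vectorized sparsity statistics for one quadrant over count vectors.
# Returns list(s, p); undefined cases (zero expectation or marginal) get the
# not-sparse sentinel s = -Inf, p = 1.
sparsity_core <- function(a00, a01, a10, a11, quadrant) {
  counts <- list(a00 = a00, a01 = a01, a10 = a10, a11 = a11)
  total <- a00 + a01 + a10 + a11
  def <- quadrant_defs[[paste0("q", quadrant)]]
  n <- counts[[paste0("a", quadrant)]]
  rowsum <- counts[[def$row[1]]] + counts[[def$row[2]]]
  colsum <- counts[[def$col[1]]] + counts[[def$col[2]]]
  nhat <- rowsum * colsum / total
  ok <- total > 0 & nhat > 0 & rowsum > 0 & colsum > 0
  s <- ifelse(ok, (nhat - n) / sqrt(pmax(nhat, 1e-300)), -Inf)
  p <- ifelse(ok, (n / pmax(rowsum, 1) + n / pmax(colsum, 1)) / 2, 1)
  list(s = s, p = p)
}

#' Sparsity statistic for one quadrant
#'
#' @param counts Data frame with columns `a00`, `a01`, `a10`, `a11`
#'   (e.g. from [quadrant_counts()]); vectorized over rows.
#' @param quadrant One of `"00"`, `"01"`, `"10"`, `"11"`.
#' @return Tibble with columns `s` and `p`. When the statistic is undefined
#'   (empty expectation or a zero marginal) the quadrant is reported
#'   not-sparse via the sentinel `s = -Inf`, `p = 1`.
#' @export
sparsity_stat <- function(counts, quadrant = c("00", "01", "10", "11")) {
  quadrant <- match.arg(quadrant)
  stopifnot(all(c("a00", "a01", "a10", "a11") %in% names(counts)))
  res <- sparsity_core(counts$a00, counts$a01, counts$a10, counts$a11, quadrant)
  tibble(s = res$s, p = res$p)
}

# Vectorized classifier over count vectors; returns list of relation
# character vector plus the 8 statistic vectors.
classify_core <- function(a00, a01, a10, a11, sthr = 3, pthr = 0.1) {
  st <- lapply(c("00", "01", "10", "11"),
               function(q) sparsity_core(a00, a01, a10, a11, q))
  names(st) <- c("q00", "q01", "q10", "q11")
  sp <- lapply(st, function(x) x$s > sthr & x$p < pthr)
  nsp <- sp$q00 + sp$q01 + sp$q10 + sp$q11
  rel <- rep("NONE", length(a00))
  rel[nsp == 2 & sp$q01 & sp$q10] <- "EQUIVALENT"
  rel[nsp == 2 & sp$q00 & sp$q11] <- "OPPOSITE"
  one <- nsp == 1
  rel[one & sp$q00] <- "LOHI"
  rel[one & sp$q01] <- "LOLO"
  rel[one & sp$q10] <- "HIHI"
  rel[one & sp$q11] <- "HILO"
  list(relation = rel,
       s00 = st$q00$s, p00 = st$q00$p, s01 = st$q01$s, p01 = st$q01$p,
       s10 = st$q10$s, p10 = st$q10$p, s11 = st$q11$s, p11 = st$q11$p)
}

#' Classify the Boolean implication relationship of a gene pair
#'
#' Marks each quadrant sparse iff `S > sthr` and `p < pthr`, then maps the
#' sparse pattern to a relationship: sparse `{01,10}` -> `EQUIVALENT`,
#' sparse `{00,11}` -> `OPPOSITE`, exactly one sparse quadrant -> the
#' corresponding asymmetric implication (00 -> `LOHI` "A low => B high",
#' 01 -> `LOLO`, 10 -> `HIHI`, 11 -> `HILO`), anything else (no sparse
#' quadrant, an adjacent sparse pair, or three or more) -> `NONE`.
#'
#' @param counts Data frame with columns `a00`, `a01`, `a10`, `a11`;
#'   vectorized over rows.
#' @param sthr Sparsity-statistic threshold (default 3).
#' @param pthr Error-rate threshold (default 0.1).
#' @return `counts` with added columns `relation` and `s00`...`p11`.
#' @export
classify_relation <- function(counts, sthr = 3, pthr = 0.1) {
  stopifnot(all(c("a00", "a01", "a10", "a11") %in% names(counts)))
  res <- classify_core(counts$a00, counts$a01, counts$a10, counts$a11, sthr, pthr)
  bind_cols(as_tibble(counts),
            tibble(relation = res$relation),
            as_tibble(res[-1L]))
}

#' Build the Boolean implication network
#'
#' Evaluates every unordered gene pair once (pairs stored with
#' `gene_a < gene_b` lexicographically) and keeps the non-`NONE`
#' relationships as edges. Pair counting is done with indicator-matrix
#' cross-products, so the cost is a handful of dense matrix products.
#'
#' @param trits A [discretize_matrix()] result whose genes passed the
#'   dynamic-range filter.
#' @param sthr,pthr BooleanNet thresholds (defaults 3 and 0.1).
#' @param min_total Optional floor on the number of non-intermediate
#'   samples a pair needs to be evaluated (default 0: the statistics
#'   self-penalize small totals).
#' @return Tibble of edges: `gene_a`, `gene_b`, `relation`, the quadrant
#'   counts and per-quadrant statistics; attributes `params` (list) and
#'   `n_pairs` (pairs tested).
#' @export
build_bin <- function(trits, sthr = 3, pthr = 0.1, min_total = 0L) {
  stopifnot(inherits(trits, "trit_matrix"))
  tr <- trits$trits
  if (nrow(tr) < 2L) abort("need >= 2 genes to build a network")
  res <- pairwise_relations(tr, sthr = sthr, pthr = pthr, min_total = min_total,
                            keep_none = FALSE)
  structure(res$edges,
            params = list(sthr = sthr, pthr = pthr, margin = trits$margin,
                          min_total = min_total),
            genes = rownames(tr),
            n_pairs = res$n_pairs)
}

# Shared pairwise engine. Computes quadrant counts for all unordered pairs
# of rows of a trit matrix via indicator cross-products and classifies them.
pairwise_relations <- function(tr, sthr, pthr, min_total = 0L, keep_none = FALSE) {
  genes <- rownames(tr)
  lo <- (tr == TRIT_LOW) * 1
  hi <- (tr == TRIT_HIGH) * 1
  a00 <- tcrossprod(lo)
  a01 <- tcrossprod(lo, hi)
  a10 <- t(a01)
  a11 <- tcrossprod(hi)
  ut <- upper.tri(a00)
  idx <- which(ut, arr.ind = TRUE)
  a00 <- a00[ut]; a01v <- a01[ut]; a10v <- a10[ut]; a11 <- a11[ut]
  total <- a00 + a01v + a10v + a11
  res <- classify_core(a00, a01v, a10v, a11, sthr, pthr)
  relation <- res$relation
  relation[total <= min_total] <- "NONE"
  n_pairs <- length(relation)
  keep <- if (keep_none) rep(TRUE, n_pairs) else relation != "NONE"
  ia <- idx[keep, 1L]
  ib <- idx[keep, 2L]
  # upper.tri indexes (row < col); store pairs lexicographically by gene id,
  # flipping the asymmetric relation when the ids swap
  ga <- genes[ia]; gb <- genes[ib]
  flip <- ga > gb
  rel <- relation[keep]
  rel[flip] <- swap_relation(rel[flip])
  edges <- tibble(
    gene_a = ifelse(flip, gb, ga), gene_b = ifelse(flip, ga, gb),
    relation = rel,
    a00 = a00[keep],
    a01 = ifelse(flip, a10v[keep], a01v[keep]),
    a10 = ifelse(flip, a01v[keep], a10v[keep]),
    a11 = a11[keep],
    s00 = res$s00[keep], p00 = res$p00[keep],
    s01 = ifelse(flip, res$s10[keep], res$s01[keep]),
    p01 = ifelse(flip, res$p10[keep], res$p01[keep]),
    s10 = ifelse(flip, res$s01[keep], res$s10[keep]),
    p10 = ifelse(flip, res$p01[keep], res$p10[keep]),
    s11 = res$s11[keep], p11 = res$p11[keep]
  ) |> arrange(.data$gene_a, .data$gene_b)
  list(edges = edges, n_pairs = n_pairs)
}

#' Relation seen from the swapped operand order
#'
#' Under the swap A,B -> B,A the symmetric relations and the cross
#' implications are unchanged (`EQUIVALENT`, `OPPOSITE`, `LOHI`, `HILO`)
#' while `LOLO` and `HIHI` exchange (A low => B low is B high => A high).
#'
#' @param relation Character vector of relation labels.
#' @return Character vector of the dual labels.
#' @export
swap_relation <- function(relation) {
  out <- relation
  out[relation == "LOLO"] <- "HIHI"
  out[relation == "HIHI"] <- "LOLO"
  out
}

#' Permutation false-discovery rate of the implication calls
#'
#' Discretizes the matrix, applies the dynamic-range filter, then permutes
#' each surviving gene's calls independently across samples (thresholds
#' unchanged, so permuting the trit rows is identical to permuting the
#' expression values) and reports the fraction of gene pairs that still
#' receive any Boolean implication relationship.
#'
#' @param expr Expression tibble.
#' @param sthr,pthr BooleanNet thresholds.
#' @param margin Discretization noise margin.
#' @param min_frac Dynamic-range filter fraction.
#' @param seed Integer seed fixing the permutation.
#' @return One-row tibble: `fdr`, `n_edges`, `n_pairs`, `n_genes`.
#' @export
permutation_fdr <- function(expr, sthr = 3, pthr = 0.1, margin = 0.5,
                            min_frac = 0.05, seed = 1L) {
  trits <- discretize_matrix(expr, margin = margin)
  kept <- filter_dynamic_range(expr, trits, min_frac = min_frac)
  tr <- trits$trits[kept$gene_id, , drop = FALSE]
  perm <- withr::with_seed(seed, {
    t(apply(tr, 1L, sample))
  })
  dimnames(perm) <- dimnames(tr)
  res <- pairwise_relations(perm, sthr = sthr, pthr = pthr, keep_none = FALSE)
  tibble(fdr = nrow(res$edges) / res$n_pairs,
         n_edges = nrow(res$edges), n_pairs = res$n_pairs,
         n_genes = nrow(perm))
}
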