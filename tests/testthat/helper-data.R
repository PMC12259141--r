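# Small fixture builders used across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

expr_matrix_for_tests <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  m
}

expr_from_rows <- function(rows, samples = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- samples %||% sprintf("S%03d", seq_len(ncol(m)))
  as_expr_tbl(m)
}

# A tiny two-state expression tibble whose StepMiner thresholds are obvious:
# each gene alternates between lo and hi values.
two_level_expr <- function(states_list, lo = 1, hi = 3) {
  rows <- lapply(states_list, function(s) ifelse(s == 1, hi, lo))
  expr_from_rows(setNames(rows, names(states_list)))
}

# Hand-built cluster tibble with the rank structure extract_clusters emits.
fake_cluster <- function(n, cluster_id = 1L) {
  tibble::tibble(
    gene_id = sprintf("c%d_g%02d", cluster_id, seq_len(n)),
    cluster_id = cluster_id,
    rank = seq_len(n),
    n_equiv = rev(seq_len(n)) - 1L,
    size = n
  )
}

# Minimal edge tibble for the clustering functions (only the columns they
# consume) with an explicit node universe.
fake_bin <- function(gene_a, gene_b, relation, genes = NULL) {
  edges <- tibble::tibble(gene_a = gene_a, gene_b = gene_b, relation = relation)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges$relation[swap] <- swap_relation(edges$relation[swap])
  attr(edges, "genes") <- genes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  edges
}
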