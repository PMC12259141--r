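# Composite-score gene signatures. Expression is put on a common scale by a
# modified Z-score centered at the StepMiner threshold,
#   z = (x - t - 0.5) / (3 * sd),
# gene-set averages of z are combined with +/-1 weights into a per-sample
# composite score, and classification performance is read off as the
# Mann-Whitney ROC-AUC of case vs control scores.

#' Modified Z-score normalization around the StepMiner threshold
#'
#' `(x - threshold - 0.5) / (3 * stddev)`: a value half a log2 unit above
#' the threshold (the upper edge of the noise margin) maps to 0, three
#' standard deviations above that maps to 1.
#'
#' @param x Expression value(s).
#' @param threshold StepMiner threshold of the gene.
#' @param stddev Sample standard deviation of the gene (must be > 0).
#' @return Normalized value(s).
#' @export
normalize_expr <- function(x, threshold, stddev) {
  if (any(stddev <= 0)) abort("stddev must be > 0 (gene unusable for scoring)")
  (x - threshold - 0.5) / (3 * stddev)
}

#' Composite score of weighted gene sets
#'
#' For each sample and each gene set, the set's genes (those present in the
#' matrix) are normalized with [normalize_expr()] and averaged; the score
#' is the weighted sum of the set averages.
#'
#' @param expr Expression tibble.
#' @param fits Per-gene fit tibble with `gene_id`, `threshold`, `stddev`
#'   (from [step_fits()] or a [discretize_matrix()] result's `$fits`).
#' @param sets Named list of gene-id vectors.
#' @param weights Numeric weight per set (recycled singleton allowed).
#' @return Tibble `sample_id`, `score`; attribute `"coverage"` records per
#'   set how many genes were usable.
#' @export
composite_score <- function(expr, fits, sets, weights = 1) {
  m <- expr_matrix(expr)
  if (!is.list(sets)) sets <- list(set1 = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  weights <- rep_len(weights, length(sets))
  usable <- intersect(fits$gene_id[fits$stddev > 0], rownames(m))
  thr <- setNames(fits$threshold, fits$gene_id)
  sdv <- setNames(fits$stddev, fits$gene_id)
  coverage <- tibble(set = names(sets),
                     n_genes = lengths(sets),
                     n_used = NA_integer_)
  score <- numeric(ncol(m))
  for (i in seq_along(sets)) {
    genes <- intersect(sets[[i]], usable)
    coverage$n_used[i] <- length(genes)
    if (!length(genes)) {
      abort(sprintf("gene set '%s' has no usable gene in the matrix", names(sets)[i]))
    }
    z <- normalize_expr(m[genes, , drop = FALSE], thr[genes], sdv[genes])
    score <- score + weights[i] * colMeans(z)
  }
  dropped <- sum(coverage$n_genes - coverage$n_used)
  if (dropped > 0) {
    inform(sprintf("composite_score: %d signature gene(s) absent or unusable", dropped))
  }
  structure(tibble(sample_id = colnames(m), score = unname(score)),
            coverage = coverage)
}

#' ROC-AUC as the Mann-Whitney probability estimate
#'
#' `P(score_case > score_control) + P(tie)/2`, computed from rank sums;
#' orientation is "higher score = case".
#'
#' @param scores Numeric vector.
#' @param labels Binary vector aligned with `scores` (1/TRUE = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary (0 = control, 1 = case)")
  as.integer(labels)
}

#' Welch two-sample t-test
#'
#' Unpaired, unequal-variance t-test with Satterthwaite degrees of freedom
#' and a two-sided p-value (delegates to [stats::t.test()]).
#'
#' @param group1,group2 Numeric vectors (>= 2 values each).
#' @return One-row tibble `t`, `df`, `p`.
#' @export
welch_ttest <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) abort("each group needs >= 2 values")
  if (stats::var(group1) == 0 && stats::var(group2) == 0) {
    if (mean(group1) == mean(group2)) return(tibble(t = 0, df = Inf, p = 1))
    abort("degenerate variance in both groups")
  }
  ht <- t.test(group1, group2, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Train an up/down gene signature from cluster candidates
#'
#' Three stages, each applied across every training dataset with
#' dataset-local StepMiner fits:
#' 1. candidate clusters: each cluster is scored with [composite_score()]
#'    (weight +1) in every dataset; up-candidates need cluster AUC
#'    `>= cluster_auc` in all datasets, down-candidates `<= 1 - cluster_auc`
#'    (explicit `up_clusters` / `down_clusters` override this pre-filter);
#' 2. per-gene filter: genes of the candidate clusters keep the "higher
#'    expression = case" orientation; up-genes need single-gene AUC
#'    `> auc_up` in all datasets, down-genes `< auc_down` in all;
#' 3. ranking: survivors are ordered by the Welch t statistic (case vs
#'    control) in the ranking dataset — descending for up, ascending for
#'    down — and the top `top_k` of each direction are kept with weights
#'    +1 (up) and -1 (down).
#'
#' @param training List of datasets, each a list with elements `expr`
#'   (expression tibble) and `labels` (tibble `sample_id`, `label`).
#' @param clusters Cluster tibble from [extract_clusters()] supplying the
#'   candidate gene pools.
#' @param rank_on Index (or name) of the training dataset used for the
#'   t-statistic ranking.
#' @param auc_up,auc_down Single-gene ROC-AUC filters (defaults 0.6, 0.3).
#' @param top_k Genes kept per direction (default 20); a shortfall keeps
#'   all survivors with a warning.
#' @param cluster_auc Cluster-level AUC cutoff for candidacy (default 0.6).
#' @param up_clusters,down_clusters Optional explicit cluster ids that
#'   bypass the cluster-level AUC pre-filter.
#' @param min_cluster_size Clusters smaller than this are not candidates
#'   (default 2).
#' @return Object of class `gene_signature`: list with `up`, `down`
#'   (ordered gene ids), `weights = c(up = 1, down = -1)` and `provenance`.
#' @export
train_signature <- function(training, clusters, rank_on = 1L,
                            auc_up = 0.6, auc_down = 0.3, top_k = 20L,
                            cluster_auc = 0.6,
                            up_clusters = NULL, down_clusters = NULL,
                            min_cluster_size = 2L) {
  stopifnot(length(training) >= 1L)
  prep <- lapply(seq_along(training), function(i) {
    d <- training[[i]]
    if (is.null(d$expr) || is.null(d$labels)) {
      abort(sprintf("training dataset %d lacks expr or labels", i))
    }
    m <- expr_matrix(d$expr)
    lab <- d$labels
    miss <- setdiff(colnames(m), lab$sample_id)
    if (length(miss)) abort(sprintf("dataset %d: unlabeled sample(s): %s", i,
                                    paste(head(miss, 3L), collapse = ", ")))
    y <- as_binary_labels(lab$label[match(colnames(m), lab$sample_id)])
    if (length(unique(y)) < 2L) abort(sprintf("dataset %d has a single class", i))
    list(expr = d$expr, m = m, y = y, fits = step_fits(d$expr))
  })

  cl_ids <- unique(clusters$cluster_id[clusters$size >= min_cluster_size])
  if (is.null(up_clusters) || is.null(down_clusters)) {
    auc_mat <- vapply(prep, function(d) {
      vapply(cl_ids, function(ci) {
        genes <- clusters$gene_id[clusters$cluster_id == ci]
        sc <- tryCatch(
          composite_score(d$expr, d$fits, list(cl = genes), weights = 1),
          error = function(e) NULL)
        if (is.null(sc)) return(NA_real_)
        roc_auc(sc$score, d$y)
      }, numeric(1))
    }, numeric(length(cl_ids)))
    auc_mat <- matrix(auc_mat, nrow = length(cl_ids))
    all_true <- function(z) all(!is.na(z) & z)
    if (is.null(up_clusters)) {
      up_clusters <- cl_ids[apply(auc_mat >= cluster_auc, 1L, all_true)]
    }
    if (is.null(down_clusters)) {
      down_clusters <- cl_ids[apply(auc_mat <= 1 - cluster_auc, 1L, all_true)]
    }
  }
  up_pool <- clusters$gene_id[clusters$cluster_id %in% up_clusters]
  down_pool <- clusters$gene_id[clusters$cluster_id %in% down_clusters]

  gene_aucs <- function(pool) {
    vapply(prep, function(d) {
      vapply(pool, function(g) {
        if (!g %in% rownames(d$m)) return(NA_real_)
        roc_auc(d$m[g, ], d$y)
      }, numeric(1))
    }, numeric(length(pool)))
  }
  up_keep <- character(0); down_keep <- character(0)
  if (length(up_pool)) {
    a <- matrix(gene_aucs(up_pool), nrow = length(up_pool))
    up_keep <- up_pool[apply(a > auc_up, 1L, function(z) all(!is.na(z) & z))]
  }
  if (length(down_pool)) {
    a <- matrix(gene_aucs(down_pool), nrow = length(down_pool))
    down_keep <- down_pool[apply(a < auc_down, 1L, function(z) all(!is.na(z) & z))]
  }
  if (!length(up_keep) || !length(down_keep)) {
    abort(sprintf("no surviving %s-regulated genes after the AUC filters",
                  if (!length(up_keep)) "up" else "down"))
  }

  rk <- prep[[rank_on]]
  tstat <- function(g) {
    welch_ttest(rk$m[g, rk$y == 1L], rk$m[g, rk$y == 0L])$t
  }
  t_up <- vapply(up_keep, tstat, numeric(1))
  t_down <- vapply(down_keep, tstat, numeric(1))
  take <- function(genes, tv, decreasing) {
    ord <- order(tv, decreasing = decreasing)
    if (length(genes) < top_k) {
      warn(sprintf("only %d survivor(s) for top_k = %d", length(genes), top_k))
    }
    genes[ord][seq_len(min(top_k, length(genes)))]
  }
  structure(list(
    up = take(up_keep, t_up, TRUE),
    down = take(down_keep, t_down, FALSE),
    weights = c(up = 1, down = -1),
    provenance = list(up_clusters = up_clusters, down_clusters = down_clusters,
                      auc_up = auc_up, auc_down = auc_down,
                      cluster_auc = cluster_auc, top_k = top_k,
                      rank_on = rank_on, n_datasets = length(training))
  ), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d up (+1), %d down (-1)\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' @rdname train_signature
#' @param x A `gene_signature`.
#' @param ... Unused.
#' @method tidy gene_signature
#' @export
tidy.gene_signature <- function(x, ...) {
  bind_rows(
    tibble(gene_id = x$up, direction = "up", weight = 1,
           rank = seq_along(x$up)),
    tibble(gene_id = x$down, direction = "down", weight = -1,
           rank = seq_along(x$down))
  )
}

#' Score and evaluate a signature on a labeled dataset
#'
#' Computes dataset-local StepMiner fits, the composite score with the
#' signature's +/-1 weights, the ROC-AUC (higher score = case) and the
#' Welch t-test of case vs control scores. The score-scale noise margin
#' (the composite image of the +/-0.5 expression band) is reported but not
#' used for classification.
#'
#' @param expr Expression tibble.
#' @param labels Tibble `sample_id`, `label` covering the samples.
#' @param signature A `gene_signature` (or list with `up`/`down`).
#' @return Object of class `signature_eval` with `scores` (tibble
#'   `sample_id`, `score`, `label`), `auc`, `t`, `df`, `p`, `score_margin`.
#' @export
evaluate_signature <- function(expr, labels, signature) {
  m <- expr_matrix(expr)
  if (is.null(labels)) abort("labels are required for evaluation")
  y <- as_binary_labels(labels$label[match(colnames(m), labels$sample_id)])
  if (anyNA(y)) abort(sprintf("missing label for sample '%s'",
                              colnames(m)[which(is.na(y))[1L]]))
  fits <- step_fits(expr)
  sets <- list(up = signature$up, down = signature$down)
  sc <- composite_score(expr, fits, sets, weights = c(1, -1))
  cov <- attr(sc, "coverage")
  usable <- fits[fits$stddev > 0, ]
  margin_of <- function(genes) {
    genes <- intersect(genes, usable$gene_id)
    mean(0.5 / (3 * usable$stddev[match(genes, usable$gene_id)]))
  }
  score_margin <- margin_of(signature$up) + margin_of(signature$down)
  tt <- welch_ttest(sc$score[y == 1L], sc$score[y == 0L])
  structure(list(
    scores = mutate(sc, label = y) |> arrange(.data$score),
    auc = roc_auc(sc$score, y),
    t = tt$t, df = tt$df, p = tt$p,
    score_margin = score_margin,
    coverage = cov
  ), class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("<signature_eval> %d samples  AUC = %.3f  t = %.2f  p = %.3g\n",
              nrow(x$scores), x$auc, x$t, x$p))
  invisible(x)
}

#' @rdname evaluate_signature
#' @param x A `signature_eval`.
#' @param ... Unused.
#' @method tidy signature_eval
#' @export
tidy.signature_eval <- function(x, ...) x$scores

#' @rdname evaluate_signature
#' @method glance signature_eval
#' @export
glance.signature_eval <- function(x, ...) {
  tibble(auc = x$auc, t = x$t, df = x$df, p = x$p,
         score_margin = x$score_margin,
         n_case = sum(x$scores$label == 1L),
         n_control = sum(x$scores$label == 0L))
}
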