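# End-to-end wiring: discretize -> dynamic-range filter -> implication
# network -> clustered network -> signature training -> evaluation, with
# optional per-stage TSV/JSON artifacts and a run manifest.

default_config <- function() {
  list(sthr = 3, pthr = 0.1, margin = 0.5, jaccard_cutoff = 0.5,
       min_frac = 0.05, auc_up = 0.6, auc_down = 0.3, top_k = 20L,
       cluster_auc = 0.6, rank_on = 1L, cluster_mode = "all_edges",
       majority_threshold = 0.5, seed = 1L)
}

#' Run the full Boolean implication pipeline
#'
#' Discretizes the ranking dataset, applies the dynamic-range filter,
#' builds the implication network and its clustered form, trains the
#' up/down signature across all training datasets, and evaluates it on
#' each. Any stage failure aborts with the stage name. When `out_dir` is
#' given, per-stage TSVs, the signature JSON, and a machine-readable run
#' manifest (resolved config, seed, package version, per-stage counts) are
#' written there.
#'
#' @param training List of datasets (each `list(expr, labels)`), e.g. the
#'   `datasets` element of [make_case_control_trio()].
#' @param out_dir Optional output directory.
#' @param config Named list overriding the defaults (sthr 3, pthr 0.1,
#'   margin 0.5, jaccard_cutoff 0.5, min_frac 0.05, auc_up 0.6,
#'   auc_down 0.3, top_k 20, cluster_auc 0.6, rank_on 1).
#' @return List with `trits`, `filtered`, `bin`, `clusters`, `cbin`,
#'   `signature`, `evaluations` (one `signature_eval` per dataset),
#'   `config`, `manifest`.
#' @export
run_pipeline <- function(training, out_dir = NULL, config = list()) {
  cfg <- modifyList(default_config(), config)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  ref <- stage("input", {
    if (!length(training)) abort("no training datasets")
    for (i in seq_along(training)) {
      if (is.null(training[[i]]$labels)) abort(sprintf("dataset %d has no labels", i))
    }
    training[[cfg$rank_on]]$expr
  })
  trits <- stage("discretize", discretize_matrix(ref, margin = cfg$margin))
  filtered <- stage("filter", filter_dynamic_range(ref, trits, min_frac = cfg$min_frac))
  ftrits <- stage("filter", {
    f <- trits
    f$trits <- f$trits[filtered$gene_id, , drop = FALSE]
    f$fits <- f$fits[f$fits$gene_id %in% filtered$gene_id, ]
    f
  })
  bin <- stage("boolean-net", build_bin(ftrits, sthr = cfg$sthr, pthr = cfg$pthr))
  clusters <- stage("cluster", extract_clusters(bin, jaccard_cutoff = cfg$jaccard_cutoff,
                                                mode = cfg$cluster_mode))
  cbin <- stage("cluster", link_clusters(bin, clusters,
                                         majority_threshold = cfg$majority_threshold))
  signature <- stage("train", train_signature(
    training, clusters, rank_on = cfg$rank_on, auc_up = cfg$auc_up,
    auc_down = cfg$auc_down, top_k = cfg$top_k, cluster_auc = cfg$cluster_auc))
  evaluations <- stage("score", lapply(training, function(d) {
    evaluate_signature(d$expr, d$labels, signature)
  }))
  manifest <- list(
    package = "boolimpl",
    version = as.character(utils::packageVersion("boolimpl")),
    config = cfg,
    counts = list(
      genes_in = nrow(ref), genes_filtered = nrow(filtered),
      pairs_tested = attr(bin, "n_pairs"),
      edges_by_type = as.list(table(bin$relation)),
      n_clusters = length(unique(clusters$cluster_id)),
      cbin_edges = nrow(cbin),
      signature = list(up = length(signature$up), down = length(signature$down)),
      auc = vapply(evaluations, function(e) e$auc, numeric(1))
    )
  )
  out <- list(trits = trits, filtered = filtered, bin = bin,
              clusters = clusters, cbin = cbin, signature = signature,
              evaluations = evaluations, config = cfg, manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  w(as_expr_tbl(res$trits$trits), "trits.tsv")
  w(res$trits$fits, "thresholds.tsv")
  w(res$bin, "edges.tsv")
  w(res$clusters, "clusters.tsv")
  w(res$cbin, "cbin.tsv")
  jsonlite::write_json(
    list(up = res$signature$up, down = res$signature$down,
         weights = as.list(res$signature$weights),
         provenance = res$signature$provenance),
    file.path(out_dir, "signature.json"), auto_unbox = TRUE, digits = NA)
  scores <- purrr::imap(res$evaluations, function(e, i) {
    mutate(tidy(e), dataset = as.integer(i))
  }) |> bind_rows()
  w(scores, "scores.tsv")
  summary <- lapply(res$evaluations, function(e) glance(e))
  jsonlite::write_json(summary, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Edge color legend for network exports
#'
#' The conventional color coding of the six relationship types used when
#' exporting the clustered network for drawing.
#'
#' @return Named character vector mapping relation labels to colors.
#' @export
relation_colors <- function() {
  c(LOHI = "orange", LOLO = "darkblue", HIHI = "green", HILO = "red",
    EQUIVALENT = "lightblue", OPPOSITE = "black")
}
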