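# Clustered Boolean implication network: cluster genes along equivalence
# edges after pruning weak links by Jaccard similarity of their closed
# equivalence neighborhoods, rank genes within clusters by equivalence
# degree, and type cluster-to-cluster edges by the majority relationship
# over a small set of representative genes.

#' Cluster the implication network along pruned equivalence edges
#'
#' Builds the undirected graph of `EQUIVALENT` edges, computes for every
#' edge (A, B) the Jaccard coefficient of the closed neighborhoods
#' `J = |N[A] n N[B]| / |N[A] u N[B]|` (closed: each node counts as its own
#' neighbor, so twin nodes score 1), drops edges with `J < jaccard_cutoff`,
#' and takes the connected components of the remainder as clusters. The
#' default prunes every equivalence edge; `mode = "mst"` instead builds a
#' minimum spanning tree per component (edge weight `1 - J`), prunes the
#' weak tree edges, and takes components of the surviving tree edges.
#' Genes of the network with no surviving equivalence edge become size-1
#' clusters. Within each cluster, members are ranked by their number of
#' equivalences to other members (rank 1 = most; ties broken
#' lexicographically by gene id).
#'
#' @param bin Edge tibble from [build_bin()].
#' @param jaccard_cutoff Minimum Jaccard similarity for an edge to survive
#'   (default 0.5: members must share at least half of their combined
#'   equivalence connections).
#' @param mode `"all_edges"` (default) or `"mst"`.
#' @return Tibble with `gene_id`, `cluster_id`, `rank`, `n_equiv`
#'   (within-cluster equivalences) and `size`. Cluster ids are integers
#'   assigned by decreasing size, ties by smallest member gene id.
#' @export
extract_clusters <- function(bin, jaccard_cutoff = 0.5,
                             mode = c("all_edges", "mst")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(bin))
  genes <- attr(bin, "genes") %||% sort(unique(c(bin$gene_a, bin$gene_b)))
  eq <- bin[bin$relation == "EQUIVALENT", c("gene_a", "gene_b")]
  g <- igraph::graph_from_data_frame(eq, directed = FALSE,
                                     vertices = data.frame(name = genes))
  if (nrow(eq)) {
    j <- edge_jaccard(g)
    keep_edges <- switch(mode,
      all_edges = j >= jaccard_cutoff,
      mst = {
        tree <- igraph::mst(g, weights = 1 - j)
        in_tree <- igraph::get_edge_ids(g, t(igraph::ends(tree, igraph::E(tree))))
        keep <- logical(igraph::ecount(g))
        keep[in_tree[j[in_tree] >= jaccard_cutoff]] <- TRUE
        keep
      })
    pruned <- igraph::subgraph_from_edges(g, igraph::E(g)[keep_edges],
                                          delete.vertices = FALSE)
  } else {
    pruned <- g
  }
  comp <- igraph::components(pruned)$membership
  members <- split(names(comp), comp)
  # deterministic cluster ids: by decreasing size, ties by smallest gene id
  members <- members[order(-lengths(members),
                           vapply(members, min, character(1)))]
  names(members) <- seq_along(members)
  adj <- igraph::as_adj_list(g)
  purrr::imap(members, function(genes_in, i) {
    n_eq <- vapply(genes_in, function(v) {
      length(intersect(names(adj[[v]]), genes_in))
    }, integer(1))
    ord <- order(-n_eq, genes_in)
    tibble(gene_id = genes_in[ord],
           cluster_id = as.integer(i),
           rank = seq_along(genes_in),
           n_equiv = n_eq[ord],
           size = length(genes_in))
  }) |>
    bind_rows()
}

# Jaccard similarity of closed neighborhoods for every edge of g,
# in igraph edge order.
edge_jaccard <- function(g) {
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  adj <- igraph::as_adj_list(g)
  closed <- lapply(seq_along(adj), function(i) c(i, as.integer(adj[[i]])))
  vapply(seq_len(nrow(ends)), function(e) {
    na <- closed[[ends[e, 1L]]]
    nb <- closed[[ends[e, 2L]]]
    length(intersect(na, nb)) / length(union(na, nb))
  }, numeric(1))
}

#' Representative genes of a cluster
#'
#' Picks the rank positions used to test cluster-to-cluster relationships:
#' for clusters larger than 10 the ranks `{1, 2, floor(n/2), floor(n/2)-1,
#' floor(n/4), floor(n/8)}` (duplicates removed, order preserved); for
#' sizes 2..10 the top two and the middle one; a singleton is its own
#' representative.
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @param cluster_id Which cluster.
#' @return Character vector of gene ids at the sampled ranks.
#' @export
sample_representatives <- function(clusters, cluster_id) {
  cl <- clusters[clusters$cluster_id == cluster_id, ]
  if (!nrow(cl)) abort(sprintf("empty or unknown cluster '%s'", cluster_id))
  n <- nrow(cl)
  ranks <- if (n > 10L) {
    c(1L, 2L, n %/% 2L, n %/% 2L - 1L, n %/% 4L, n %/% 8L)
  } else if (n >= 2L) {
    c(1L, 2L, n %/% 2L)
  } else {
    1L
  }
  ranks <- unique(ranks[ranks >= 1L & ranks <= n])
  cl$gene_id[match(ranks, cl$rank)]
}

#' Type the cluster-to-cluster edges of the clustered network
#'
#' For each ordered cluster pair (A, B), pairs A's rank-1 gene (the member
#' with most within-cluster equivalences) against the representatives of B
#' and tallies the pairwise relationships found in the implication network
#' (absent pairs count as `NONE`). An edge is emitted iff the modal
#' non-`NONE` relationship covers more than `majority_threshold` of the
#' tested pairs.
#'
#' @param bin Edge tibble from [build_bin()].
#' @param clusters Cluster tibble from [extract_clusters()] over the same
#'   network.
#' @param majority_threshold Strict lower bound on the winning
#'   relationship's share of tested pairs (default 0.5).
#' @return Tibble `cluster_a`, `cluster_b`, `relation`, `support`
#'   (winning share), `n_tested`.
#' @export
link_clusters <- function(bin, clusters, majority_threshold = 0.5) {
  stopifnot(is.data.frame(bin), is.data.frame(clusters))
  ids <- unique(clusters$cluster_id)
  top <- clusters$gene_id[clusters$rank == 1L][match(ids, clusters$cluster_id[clusters$rank == 1L])]
  names(top) <- ids
  reps <- lapply(ids, function(i) sample_representatives(clusters, i))
  names(reps) <- ids
  # fast ordered-pair relation lookup
  key <- paste(bin$gene_a, bin$gene_b, sep = "\r")
  rel_of <- function(x, y) {
    fwd <- x < y
    k <- ifelse(fwd, paste(x, y, sep = "\r"), paste(y, x, sep = "\r"))
    r <- bin$relation[match(k, key)]
    r[is.na(r)] <- "NONE"
    ifelse(fwd, r, swap_relation(r))
  }
  out <- list()
  for (a in as.character(ids)) {
    for (b in as.character(ids)) {
      if (a == b) next
      rels <- rel_of(rep(top[[a]], length(reps[[b]])), reps[[b]])
      tab <- table(rels[rels != "NONE"])
      if (!length(tab)) next
      win <- names(tab)[which.max(tab)]
      support <- max(tab) / length(rels)
      if (support > majority_threshold) {
        out[[length(out) + 1L]] <- tibble(
          cluster_a = as.integer(a), cluster_b = as.integer(b),
          relation = win, support = support, n_tested = length(rels))
      }
    }
  }
  if (!length(out)) {
    return(tibble(cluster_a = integer(), cluster_b = integer(),
                  relation = character(), support = numeric(),
                  n_tested = integer()))
  }
  bind_rows(out) |> arrange(.data$cluster_a, .data$cluster_b)
}

#' Cluster-size histogram
#'
#' The size distribution of the equivalence clusters; plotted on log-log
#' axes this is the scale-free diagnostic of the network.
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @return Tibble `size`, `n_clusters` (counts sum to the number of
#'   clusters), sorted by size.
#' @export
cluster_size_distribution <- function(clusters) {
  if (!nrow(clusters)) return(tibble(size = integer(), n_clusters = integer()))
  clusters |>
    dplyr::distinct(.data$cluster_id, .data$size) |>
    count(size = .data$size, name = "n_clusters") |>
    arrange(.data$size)
}
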