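test_that("a complete triangle of equivalences is one cluster", {
  bin <- fake_bin(c("A", "A", "B"), c("B", "C", "C"), rep("EQUIVALENT", 3))
  cl <- extract_clusters(bin)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$gene_id, c("A", "B", "C"))
  expect_equal(sort(cl$rank), 1:3)
  # every closed neighborhood is identical -> ranks tie, broken by gene id
  expect_equal(cl$gene_id[cl$rank == 1], "A")
})

test_that("a hub-and-leaves star dissolves into singletons at cutoff 0.5", {
  bin <- fake_bin(rep("H", 4), paste0("L", 1:4), rep("EQUIVALENT", 4))
  cl <- extract_clusters(bin, jaccard_cutoff = 0.5)
  # J(H, leaf) = |{H,L}| / |{H,L1..L4,L}| = 2/5 < 0.5
  expect_equal(length(unique(cl$cluster_id)), 5L)
  expect_true(all(cl$size == 1L))
})

test_that("two planted cliques joined by one spurious edge are separated", {
  g1 <- sprintf("a%02d", 1:10)
  g2 <- sprintf("b%02d", 1:10)
  clique_edges <- function(g) {
    idx <- t(utils::combn(g, 2))
    fake_bin(idx[, 1], idx[, 2], rep("EQUIVALENT", nrow(idx)))
  }
  bin <- dplyr::bind_rows(clique_edges(g1), clique_edges(g2),
                          fake_bin("a01", "b01", "EQUIVALENT"))
  attr(bin, "genes") <- c(g1, g2)
  cl <- extract_clusters(bin)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  part <- split(cl$gene_id, cl$cluster_id)
  expect_setequal(vapply(part, length, integer(1)), c(10L, 10L))
  expect_true(all(g1 %in% part[[1]]) || all(g1 %in% part[[2]]))
  # mst mode gives the same two cliques here
  cl_mst <- extract_clusters(bin, mode = "mst")
  expect_equal(length(unique(cl_mst$cluster_id)), 2L)
})

test_that("clustering is independent of gene input order", {
  cl <- make_clique_matrix(k_cliques = 3, clique_size = 6, n_null = 8,
                           n_samples = 120, seed = 15)
  run <- function(expr) {
    trits <- discretize_matrix(expr)
    kept <- filter_dynamic_range(expr, trits)
    trits$trits <- trits$trits[kept$gene_id, , drop = FALSE]
    extract_clusters(build_bin(trits))
  }
  c1 <- run(cl$expr)
  c2 <- run(cl$expr[rev(seq_len(nrow(cl$expr))), ])
  expect_equal(c1, c2)
})

test_that("no opposite pair survives inside one cluster", {
  cl <- make_clique_matrix(k_cliques = 4, clique_size = 6, n_null = 10,
                           n_samples = 150, seed = 2)
  trits <- discretize_matrix(cl$expr)
  kept <- filter_dynamic_range(cl$expr, trits)
  trits$trits <- trits$trits[kept$gene_id, , drop = FALSE]
  bin <- build_bin(trits)
  clusters <- extract_clusters(bin)
  memb <- setNames(clusters$cluster_id, clusters$gene_id)
  opp <- bin[bin$relation == "OPPOSITE", ]
  expect_true(all(memb[opp$gene_a] != memb[opp$gene_b]))
})

test_that("representative sampling follows the rank recipe", {
  expect_equal(sample_representatives(fake_cluster(1), 1L), "c1_g01")
  # n = 5: ranks {1, 2, floor(5/2)=2} deduplicate to {1, 2}
  expect_equal(sample_representatives(fake_cluster(5), 1L),
               c("c1_g01", "c1_g02"))
  # n = 16: {1, 2, 8, 7, 4, 2} deduplicate to {1, 2, 8, 7, 4}, order kept
  expect_equal(sample_representatives(fake_cluster(16), 1L),
               sprintf("c1_g%02d", c(1, 2, 8, 7, 4)))
  expect_error(sample_representatives(fake_cluster(3), 99L), "empty or unknown")
})

test_that("cluster links need a strict majority of agreeing pairs", {
  clusters <- dplyr::bind_rows(fake_cluster(1, 1L), fake_cluster(5, 2L))
  a <- "c1_g01"
  b <- sample_representatives(clusters, 2L)
  unanimous <- fake_bin(rep(a, 2), b, rep("LOHI", 2),
                        genes = c(a, sprintf("c2_g%02d", 1:5)))
  cb <- link_clusters(unanimous, clusters)
  expect_equal(cb$relation[cb$cluster_a == 1 & cb$cluster_b == 2], "LOHI")
  expect_equal(cb$support[cb$cluster_a == 1 & cb$cluster_b == 2], 1)
  # a 50/50 split between two types fails the strict majority
  split_bin <- fake_bin(rep(a, 2), b, c("LOHI", "HIHI"),
                        genes = c(a, sprintf("c2_g%02d", 1:5)))
  cb2 <- link_clusters(split_bin, clusters)
  expect_false(any(cb2$cluster_a == 1 & cb2$cluster_b == 2))
})

test_that("planted inter-cluster implications appear typed in the CBIN", {
  withr::with_seed(77, {
    n <- 200
    s1 <- rbinom(n, 1, 0.5)
    s2 <- plant_relation(s1, "LOLO")
    s3 <- plant_relation(s2, "HIHI")
    states <- c(
      setNames(lapply(1:5, function(i) s1), paste0("a", 1:5)),
      setNames(lapply(1:5, function(i) s2), paste0("b", 1:5)),
      setNames(lapply(1:5, function(i) s3), paste0("c", 1:5))
    )
    expr <- two_level_expr(states)
    trits <- discretize_matrix(expr)
    bin <- build_bin(trits)
    clusters <- extract_clusters(bin)
    memb <- setNames(clusters$cluster_id, clusters$gene_id)
    expect_equal(length(unique(memb)), 3L)
    cbin <- link_clusters(bin, clusters)
    rel <- function(x, y) {
      cbin$relation[cbin$cluster_a == memb[[x]] & cbin$cluster_b == memb[[y]]]
    }
    expect_equal(rel("a1", "b1"), "LOLO")
    expect_equal(rel("b1", "c1"), "HIHI")
  })
})

test_that("cluster size histogram counts clusters", {
  clusters <- dplyr::bind_rows(fake_cluster(3, 1L), fake_cluster(3, 2L),
                               fake_cluster(1, 3L))
  d <- cluster_size_distribution(clusters)
  expect_equal(d, tibble::tibble(size = c(1L, 3L), n_clusters = c(1L, 2L)))
  expect_equal(nrow(cluster_size_distribution(clusters[0, ])), 0L)
})
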