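test_that("modified Z normalization is anchored at threshold + margin", {
  expect_equal(normalize_expr(2.5, 2, 1), 0)
  expect_equal(normalize_expr(2 + 0.5 + 3, 2, 1), 1)
  expect_equal(normalize_expr(4, 2, 1), 0.5)
  expect_error(normalize_expr(1, 2, 0), "stddev")
})

test_that("composite scores combine set averages with weights", {
  expr <- expr_from_rows(list(u = c(3.5, -2.5), d = c(-2.5, 3.5)),
                         samples = c("S1", "S2"))
  fits <- tibble::tibble(gene_id = c("u", "d"), threshold = 0, stddev = 1)
  # normalized u = (1, -1), d = (-1, 1)
  one <- composite_score(expr, fits, list(up = "u"), weights = 1)
  expect_equal(one$score, c(1, -1))
  both <- composite_score(expr, fits, list(up = "u", down = "d"),
                          weights = c(1, -1))
  expect_equal(both$score, c(2, -2))
  cancel <- composite_score(expr, fits, list(a = c("u", "d"), b = c("u", "d")),
                            weights = c(1, -1))
  expect_equal(cancel$score, c(0, 0))
  expect_error(composite_score(expr, fits, list(ghost = "nope")), "ghost")
})

test_that("composite score ordering is invariant to per-gene affine rescaling", {
  trio <- make_case_control_trio(n_datasets = 1, n_genes = 40, n_per_class = 25,
                                 n_up = 5, n_down = 5, seed = 31)
  expr <- trio$datasets[[1]]$expr
  sets <- list(up = trio$truth$up, down = trio$truth$down)
  s1 <- composite_score(expr, step_fits(expr), sets, c(1, -1))
  m <- expr_matrix_for_tests(expr)
  scale <- withr::with_seed(1, runif(nrow(m), 0.5, 3))
  shift <- withr::with_seed(2, rnorm(nrow(m), 0, 4))
  rescaled <- as_expr_tbl(m * scale + shift)
  s2 <- composite_score(rescaled, step_fits(rescaled), sets, c(1, -1))
  # thresholds and sd recompute on the rescaled data: scores shift by a
  # sample-independent constant, so ranking and AUC are unchanged
  expect_equal(diff(range(s2$score - s1$score)), 0, tolerance = 1e-8)
  y <- trio$datasets[[1]]$labels$label
  expect_equal(roc_auc(s2$score, y), roc_auc(s1$score, y))
})

test_that("roc_auc matches the pair-counting oracle including ties", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(3, 2, 1, 2.5), c(1, 1, 0, 0)), 0.75)
  withr::with_seed(5, {
    for (i in 1:40) {
      n <- sample(2:12, 1)
      scores <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(roc_auc(scores, 1 - labels), 1 - roc_auc(scores, labels))
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(61, {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, 0.4)
    ref <- as.numeric(pROC::auc(labels, scores, direction = "<", quiet = TRUE))
    expect_equal(roc_auc(scores, labels), ref)
  })
})

test_that("welch_ttest reproduces hand-computed values", {
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  tt <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4, tolerance = 1e-9)
  swapped <- welch_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -tt$t)
  expect_equal(swapped$p, tt$p)
})

test_that("bh_adjust applies the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("training recovers planted signature genes with the default filters", {
  trio <- make_case_control_trio(n_genes = 200, n_per_class = 60, seed = 13)
  res <- run_pipeline(trio$datasets)
  sig <- res$signature
  expect_length(sig$up, 20)
  expect_length(sig$down, 20)
  expect_true(all(sig$up %in% trio$truth$up))
  expect_true(all(sig$down %in% trio$truth$down))
  expect_equal(unname(sig$weights), c(1, -1))
  td <- tidy(sig)
  expect_equal(nrow(td), 40)
  expect_setequal(td$weight, c(1, -1))
})

test_that("a shortfall of survivors keeps them all with a warning", {
  trio <- make_case_control_trio(n_genes = 150, n_per_class = 50,
                                 n_up = 5, n_down = 5, seed = 17)
  w <- testthat::capture_warnings(res <- run_pipeline(trio$datasets))
  expect_true(any(grepl("survivor", w)))
  expect_length(res$signature$up, 5)
  expect_length(res$signature$down, 5)
})

test_that("genes whose effect flips in one dataset are excluded", {
  trio <- make_case_control_trio(n_genes = 150, n_per_class = 60, n_up = 10,
                                 n_down = 10, seed = 23)
  flip_gene <- trio$truth$up[1]
  d2 <- trio$datasets[[2]]
  m <- expr_matrix_for_tests(d2$expr)
  y <- d2$labels$label[match(colnames(m), d2$labels$sample_id)]
  # swap the case and control values of one planted up gene in dataset 2
  m[flip_gene, ] <- c(m[flip_gene, y == 1], m[flip_gene, y == 0])
  trio$datasets[[2]]$expr <- as_expr_tbl(m)
  res <- suppressWarnings(run_pipeline(trio$datasets))
  expect_false(flip_gene %in% res$signature$up)
  expect_true(all(setdiff(trio$truth$up, flip_gene) %in% res$signature$up))
})

test_that("evaluation reports separation on training data and flips cleanly", {
  trio <- make_case_control_trio(n_genes = 120, n_per_class = 50, n_up = 10,
                                 n_down = 10, seed = 29)
  d <- trio$datasets[[1]]
  sig <- list(up = trio$truth$up, down = trio$truth$down)
  ev <- evaluate_signature(d$expr, d$labels, sig)
  expect_gt(ev$auc, 0.9)
  expect_lt(ev$p, 1e-6)
  expect_gt(ev$score_margin, 0)
  # swapped signature mirrors the AUC
  ev_sw <- evaluate_signature(d$expr, d$labels,
                              list(up = sig$down, down = sig$up))
  expect_equal(ev_sw$auc, 1 - ev$auc)
  # permuted labels: near-chance classification
  perm <- d$labels
  perm$label <- withr::with_seed(3, sample(perm$label))
  ev_perm <- evaluate_signature(d$expr, perm, sig)
  expect_lt(abs(ev_perm$auc - 0.5), 0.15)
  gl <- glance(ev)
  expect_equal(gl$n_case, 50L)
  expect_equal(nrow(tidy(ev)), 100L)
})
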