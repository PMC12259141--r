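# Synthetic expression data with known ground truth. Genes are Gaussian
# mixtures over latent binary states (the separable low/high regimes the
# Boolean analysis assumes); implication structure is planted by
# constraining child states given parent states, and case/control effects
# by tying planted genes' states to the class label.

default_mu <- c(low = 2, high = 5)
default_sd <- 0.5

sample_ids <- function(n) sprintf("S%03d", seq_len(n))
gene_ids <- function(n, prefix = "g") sprintf("%s%04d", prefix, seq_len(n))

# values for a binary state vector: N(mu_low, sd) when 0, N(mu_high, sd)
# when 1 (no RNG state management here; callers seed)
states_to_values <- function(states, mu_low, mu_high, sd) {
  ifelse(states == 1L, mu_high, mu_low) + rnorm(length(states), 0, sd)
}

#' Generate one bimodal gene
#'
#' A two-component Gaussian mixture: each sample is "high" with probability
#' `frac_high` and draws from `N(mu_high, sd)`, otherwise from
#' `N(mu_low, sd)`. With the default 3-sd mode separation (means 2 and 5,
#' sd 0.5 on log2 scale) the StepMiner threshold lands between the modes.
#'
#' @param n Number of samples.
#' @param frac_high Probability of the high state (0 < frac_high < 1).
#' @param mu_low,mu_high Mixture component means (log2 scale).
#' @param sd Within-component standard deviation.
#' @param seed Optional integer seed (bit-identical regeneration).
#' @return Tibble `sample_id`, `value`, `state` (true binary state).
#' @export
make_bimodal_gene <- function(n, frac_high = 0.5,
                              mu_low = default_mu[["low"]],
                              mu_high = default_mu[["high"]],
                              sd = default_sd, seed = NULL) {
  stopifnot(n >= 1, frac_high > 0, frac_high < 1, sd > 0, mu_high > mu_low)
  gen <- function() {
    states <- rbinom(n, 1L, frac_high)
    tibble(sample_id = sample_ids(n),
           value = states_to_values(states, mu_low, mu_high, sd),
           state = states)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Plant a Boolean implication between binary state vectors
#'
#' Produces child states that satisfy the relationship's forbidden-quadrant
#' constraint against the parent, except at a small `violation_rate`:
#' * `EQUIVALENT` / `OPPOSITE`: child equals / negates the parent;
#' * `LOHI` (parent low => child high): parent-low samples are forced
#'   high, parent-high samples are free coin flips; analogously `LOLO`
#'   (forced low), `HIHI` (parent high => child high), `HILO`.
#' Violations flip the forced samples with the given probability.
#'
#' @param parent_states Binary vector.
#' @param relation One of the six relationship labels.
#' @param violation_rate Probability a constrained sample violates the
#'   relationship (default 0).
#' @param seed Optional integer seed.
#' @return Integer binary vector of child states.
#' @export
plant_relation <- function(parent_states,
                           relation = c("EQUIVALENT", "OPPOSITE", "LOHI",
                                        "LOLO", "HIHI", "HILO"),
                           violation_rate = 0, seed = NULL) {
  relation <- match.arg(relation)
  p <- as.integer(parent_states)
  stopifnot(all(p %in% c(0L, 1L)))
  gen <- function() {
    child <- switch(relation,
      EQUIVALENT = p,
      OPPOSITE = 1L - p,
      LOHI = ifelse(p == 0L, 1L, rbinom(length(p), 1L, 0.5)),
      LOLO = ifelse(p == 0L, 0L, rbinom(length(p), 1L, 0.5)),
      HIHI = ifelse(p == 1L, 1L, rbinom(length(p), 1L, 0.5)),
      HILO = ifelse(p == 1L, 0L, rbinom(length(p), 1L, 0.5)))
    forced <- switch(relation,
      EQUIVALENT = , OPPOSITE = rep(TRUE, length(p)),
      LOHI = , LOLO = p == 0L,
      HIHI = , HILO = p == 1L)
    if (!any(forced)) {
      abort(sprintf("impossible marginals: no parent sample in the state %s conditions on",
                    relation))
    }
    if (violation_rate > 0) {
      flip <- forced & runif(length(p)) < violation_rate
      child[flip] <- 1L - child[flip]
    }
    child
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Bimodal null matrix
#'
#' Independent bimodal genes with per-gene high fractions drawn uniformly
#' from `frac_high` — the null input for the permutation FDR diagnostic.
#'
#' @param n_genes,n_samples Dimensions.
#' @param mu_low,mu_high,sd Mixture parameters (see [make_bimodal_gene()]).
#' @param frac_high Length-2 range the per-gene high fraction is drawn from.
#' @param seed Integer seed.
#' @return Expression tibble.
#' @export
make_bimodal_matrix <- function(n_genes, n_samples,
                                mu_low = default_mu[["low"]],
                                mu_high = default_mu[["high"]],
                                sd = default_sd,
                                frac_high = c(0.2, 0.8), seed = 1L) {
  withr::with_seed(seed, {
    fh <- runif(n_genes, frac_high[1], frac_high[2])
    m <- t(vapply(fh, function(f) {
      states <- rbinom(n_samples, 1L, f)
      states_to_values(states, mu_low, mu_high, sd)
    }, numeric(n_samples)))
    dimnames(m) <- list(gene_ids(n_genes), sample_ids(n_samples))
    as_expr_tbl(m)
  })
}

#' Equivalence-clique matrix with planted partition
#'
#' `k_cliques` groups of `clique_size` genes each share one latent bimodal
#' state (so every within-group pair is EQUIVALENT), embedded among
#' `n_null` independent bimodal genes.
#'
#' @param k_cliques,clique_size,n_null,n_samples Design sizes.
#' @param frac_high High fraction of each latent state.
#' @param mu_low,mu_high,sd Mixture parameters.
#' @param seed Integer seed.
#' @return List: `expr` (expression tibble) and `truth` (tibble `gene_id`,
#'   `clique`; clique 0 = null gene).
#' @export
make_clique_matrix <- function(k_cliques = 4L, clique_size = 10L,
                               n_null = 20L, n_samples = 150L,
                               frac_high = 0.5,
                               mu_low = default_mu[["low"]],
                               mu_high = default_mu[["high"]],
                               sd = default_sd, seed = 1L) {
  withr::with_seed(seed, {
    n_genes <- k_cliques * clique_size + n_null
    ids <- gene_ids(n_genes)
    clique <- c(rep(seq_len(k_cliques), each = clique_size),
                rep(0L, n_null))
    m <- matrix(NA_real_, n_genes, n_samples,
                dimnames = list(ids, sample_ids(n_samples)))
    for (k in seq_len(k_cliques)) {
      states <- rbinom(n_samples, 1L, frac_high)
      for (i in which(clique == k)) {
        m[i, ] <- states_to_values(states, mu_low, mu_high, sd)
      }
    }
    for (i in which(clique == 0L)) {
      states <- rbinom(n_samples, 1L, runif(1, 0.2, 0.8))
      m[i, ] <- states_to_values(states, mu_low, mu_high, sd)
    }
    list(expr = as_expr_tbl(m),
         truth = tibble(gene_id = ids, clique = as.integer(clique)))
  })
}

#' Case/control training trio with planted signature genes
#'
#' Generates `n_datasets` labeled cohorts sharing the same planted up- and
#' down-regulated genes with independent noise: planted up genes sit at
#' `mu_low` in controls and `mu_low + effect * sd` in cases, planted down
#' genes mirror that, and the remaining genes are independent bimodal nulls.
#' With the default 3-sd effect the planted genes are strongly bimodal by
#' class (single-gene AUC near 1) and form equivalence cliques, emulating
#' multi-cohort disease training data.
#'
#' @param n_datasets Number of cohorts (default 3).
#' @param n_genes Genes per cohort (planted + null).
#' @param n_per_class Samples per class per cohort.
#' @param n_up,n_down Planted gene counts per direction.
#' @param effect Case shift in units of `sd`.
#' @param mu_low,sd Baseline mixture parameters.
#' @param seed Integer seed.
#' @return List: `datasets` (list of `list(expr, labels)`) and `truth`
#'   (list with `up`, `down` gene ids, `effect`, `seed`).
#' @export
make_case_control_trio <- function(n_datasets = 3L, n_genes = 500L,
                                   n_per_class = 100L, n_up = 30L,
                                   n_down = 30L, effect = 3,
                                   mu_low = default_mu[["low"]],
                                   sd = default_sd, seed = 1L) {
  stopifnot(n_up >= 1, n_down >= 1, n_up + n_down <= n_genes)
  ids <- gene_ids(n_genes)
  up <- ids[seq_len(n_up)]
  down <- ids[n_up + seq_len(n_down)]
  mu_high_eff <- mu_low + effect * sd
  withr::with_seed(seed, {
    datasets <- lapply(seq_len(n_datasets), function(d) {
      n <- 2L * n_per_class
      y <- rep(c(0L, 1L), each = n_per_class)
      m <- matrix(NA_real_, n_genes, n,
                  dimnames = list(ids, sample_ids(n)))
      for (g in up) m[g, ] <- states_to_values(y, mu_low, mu_high_eff, sd)
      for (g in down) m[g, ] <- states_to_values(1L - y, mu_low, mu_high_eff, sd)
      null_ids <- setdiff(ids, c(up, down))
      for (g in null_ids) {
        states <- rbinom(n, 1L, runif(1, 0.2, 0.8))
        m[g, ] <- states_to_values(states, default_mu[["low"]],
                                   default_mu[["high"]], sd)
      }
      list(expr = as_expr_tbl(m),
           labels = tibble(sample_id = colnames(m), label = y))
    })
    list(datasets = datasets,
         truth = list(up = up, down = down, effect = effect, seed = seed))
  })
}
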