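test_that("co-membership graphs join genes sharing a set", {
  g <- build_graph(list(s1 = c("A", "B"), s2 = c("B", "C")))
  expect_identical(g$adjacency["A", "B"], 1)
  expect_identical(g$adjacency["B", "C"], 1)
  expect_identical(g$adjacency["A", "C"], 0)
  expect_identical(sum(diag(g$adjacency)), 0)

  single <- build_graph(list(s = "A"))
  expect_identical(single$nodes, "A")
  expect_identical(sum(single$adjacency), 0)
})

test_that("the unnormalized Laplacian has zero row sums (oracle build)", {
  set.seed(9)
  sets <- lapply(1:6, function(i) sample(LETTERS[1:12], sample(2:5, 1)))
  names(sets) <- paste0("s", 1:6)
  g <- build_graph(sets)
  expect_equal(unname(rowSums(g$laplacian)), rep(0, length(g$nodes)),
               tolerance = 1e-12)
  # oracle: D - A from the adjacency directly
  expect_equal(g$laplacian, diag(rowSums(g$adjacency)) - g$adjacency,
               ignore_attr = TRUE)
  ev <- eigen(g$laplacian_norm, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("at lambda2 = 0 the fit matches an independent L1 solver", {
  set.seed(4)
  n <- 30; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("g", 1:p)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - X[, 2]))
  for (lam in c(0.02, 0.05, 0.1)) {
    fit <- fit_graph_logistic(X, y, graph = NULL, lambda1 = lam,
                              lambda2 = 0, tol = 1e-13, max_iter = 20000)
    ref <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                          standardize = FALSE, thresh = 1e-15)
    expect_lt(max(abs(fit$beta - as.numeric(coef(ref))[-1])), 1e-4)
    expect_lt(abs(fit$intercept - as.numeric(coef(ref))[1]), 1e-4)
  }
})

test_that("a strong Laplacian penalty fuses duplicated linked predictors", {
  set.seed(6)
  n <- 60
  x <- rnorm(n)
  X <- cbind(g1 = x, g2 = x, g3 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x))
  graph <- build_graph(list(s = c("g1", "g2")))
  fit <- fit_graph_logistic(scale(X), y, graph, lambda1 = 0.01,
                            lambda2 = 10, tol = 1e-12, max_iter = 5000)
  expect_lt(abs(fit$beta["g1"] - fit$beta["g2"]), 1e-6)
})

test_that("a large L1 penalty zeroes every coefficient", {
  set.seed(2)
  X <- scale(matrix(rnorm(40 * 4), 40, 4))
  colnames(X) <- paste0("g", 1:4)
  y <- rbinom(40, 1, 0.5)
  fit <- fit_graph_logistic(X, y, NULL, lambda1 = 10, lambda2 = 0)
  expect_true(all(fit$beta == 0))
})

test_that("coordinate descent never increases the objective", {
  set.seed(13)
  X <- scale(matrix(rnorm(50 * 8), 50, 8))
  colnames(X) <- paste0("g", 1:8)
  y <- rbinom(50, 1, plogis(X[, 1]))
  graph <- build_graph(list(s = c("g1", "g2", "g3")))
  fit <- fit_graph_logistic(X, y, graph, lambda1 = 0.05, lambda2 = 0.5)
  expect_true(all(diff(fit$objective) <= 1e-12))
  expect_true(fit$converged)
  expect_error(fit_graph_logistic(X, rep(1, 50), NULL), "single class")
})

test_that("a separable informative gene is selected in every model", {
  set.seed(30)
  n_per <- 30
  groups <- rep(c("TNBC", "non-TNBC"), each = n_per)
  ids <- sprintf("s%02d", seq_along(groups))
  vals <- matrix(rnorm(3 * length(ids), sd = 0.05), nrow = 3,
                 dimnames = list(c("inf", "n1", "n2"), ids))
  vals["inf", groups == "TNBC"] <- vals["inf", groups == "TNBC"] + 5
  em <- expression_matrix(vals, "toy")
  st <- sample_table(ids, groups, "toy")
  graph <- build_graph(list(s = c("inf", "n1", "n2")))
  rm <- repeated_models(em, st, graph, n_models = 10, seed = 3)
  expect_identical(unname(rm$counts["inf"]), 10L)
  expect_true(all(rm$models$sensitivity == 1))
  expect_true(all(rm$models$specificity == 1))

  rm2 <- repeated_models(em, st, graph, n_models = 10, seed = 3)
  expect_identical(rm, rm2)
})

test_that("held-out metrics are near chance under permuted labels", {
  sens <- c(); spec <- c()
  for (seed in 1:5) {
    set.seed(seed + 100)
    groups <- sample(rep(c("TNBC", "non-TNBC"), each = 30))
    ids <- sprintf("s%02d", seq_along(groups))
    vals <- matrix(rnorm(10 * length(ids)), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10), ids))
    em <- expression_matrix(vals, "toy")
    st <- sample_table(ids, groups, "toy")
    graph <- build_graph(list(s = sprintf("g%02d", 1:10)))
    rm <- repeated_models(em, st, graph, n_models = 5, seed = seed)
    sens <- c(sens, rm$models$sensitivity)
    spec <- c(spec, rm$models$specificity)
  }
  expect_lt(abs(mean(sens) - 0.5), 0.15)
  expect_lt(abs(mean(spec) - 0.5), 0.15)
})

test_that("metrics are invariant to predictor column order", {
  cfg <- small_pathway_config(seed = 23, n_per_group = 30, n_genes = 20,
                              n_null_sets = 4)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  graph <- build_graph(sim$gene_sets)
  genes <- intersect(graph$nodes, rownames(co$expression))
  r1 <- repeated_models(co$expression, co$samples, graph, genes = genes,
                        n_models = 3, seed = 7)
  r2 <- repeated_models(co$expression, co$samples, graph, genes = rev(genes),
                        n_models = 3, seed = 7)
  expect_equal(r1$models$sensitivity, r2$models$sensitivity)
  expect_equal(r1$models$specificity, r2$models$specificity)
  expect_equal(r1$counts[sort(names(r1$counts))],
               r2$counts[sort(names(r2$counts))])
})

test_that("the predictive rule keeps genes selected in >= 2 datasets", {
  mk <- function(counts, ds) {
    structure(list(counts = counts, models = data.frame(), n_models = 10,
                   dataset_id = ds), class = "selection_summary")
  }
  s <- list(mk(c(a = 1, b = 0, c = 2), "d1"),
            mk(c(a = 1, b = 0, c = 0), "d2"),
            mk(c(a = 1, b = 0, c = 1), "d3"))
  expect_identical(predictive_gene_rule(s), c("a", "c"))
  # selected twice but in a single dataset only: excluded
  s2 <- list(mk(c(x = 2), "d1"), mk(c(x = 0), "d2"), mk(c(x = 0), "d3"))
  expect_identical(predictive_gene_rule(s2), character(0))
})
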