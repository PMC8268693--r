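# Criterion three: a gene co-membership graph built from the enriched gene
# sets regularizes sparse logistic classification of TNBC vs non-TNBC:
#
#   minimize  (1/n) sum_i log(1 + exp(-y_i (b0 + x_i' b)))
#             + lambda1 ||b||_1 + lambda2 b' L b
#
# where L is the (normalized) graph Laplacian.  The problem is solved by
# proximal coordinate descent with a 1/4 curvature majorant for the logistic
# loss, which makes every sweep decrease the objective.  lambda2 = 0
# recovers plain L1-penalized logistic regression.  Genes are summarized by
# how often they carry nonzero coefficients across repeated stratified
# train/test splits, and the predictive-gene rule retains genes selected at
# least once in at least two datasets.

#' Build the gene co-membership graph of a gene-set collection
#'
#' Nodes are genes, and two genes are joined when they share at least one
#' set.  Both the unnormalized Laplacian `L = D - A` and the
#' degree-normalized Laplacian `I - D^{-1/2} A D^{-1/2}` (isolated nodes:
#' zero row) are stored.
#'
#' @param enriched_sets A `gene_sets` collection (or plain named list).
#' @return A `comembership_graph` list with `nodes`, `adjacency`,
#'   `laplacian` (unnormalized) and `laplacian_norm`.
#' @export
build_graph <- function(enriched_sets) {
  if (!length(enriched_sets)) abort("empty gene-set collection")
  nodes <- sort(unique(unlist(enriched_sets)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in enriched_sets) {
    members <- intersect(unique(s), nodes)
    if (length(members) > 1) A[members, members] <- 1
  }
  diag(A) <- 0
  d <- rowSums(A)
  L <- diag(d, nrow = n) - A
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Lnorm <- diag(as.numeric(d > 0), nrow = n) - (inv_sqrt %o% inv_sqrt) * A
  dimnames(L) <- dimnames(Lnorm) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = A, laplacian = L,
                 laplacian_norm = Lnorm),
            class = "comembership_graph")
}

#' Graph-Laplacian-penalized objective value
#' @noRd
graph_logistic_objective <- function(X, y01, b0, beta, L, lambda1, lambda2) {
  eta <- b0 + drop(X %*% beta)
  loss <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y01 * eta)
  loss + lambda1 * sum(abs(beta)) + lambda2 * drop(crossprod(beta, L %*% beta))
}

#' Fit a graph-regularized sparse logistic model
#'
#' Coordinate descent on the L1- and Laplacian-penalized logistic objective.
#' Predictors should be standardized by the caller (see
#' [repeated_models()]); the intercept is unpenalized.
#'
#' @param X Numeric matrix, samples x genes (column names = gene symbols).
#' @param y Binary response: logical, 0/1, or a factor/character vector
#'   whose first sorted level is coded 0.
#' @param graph A `comembership_graph`; genes absent from the graph get
#'   zero Laplacian rows (pure L1 behaviour).  `NULL` for no graph.
#' @param lambda1 L1 penalty weight.
#' @param lambda2 Laplacian penalty weight.
#' @param normalized Use the degree-normalized Laplacian (default) or the
#'   unnormalized one.
#' @param max_iter,tol Sweep limit and relative objective-change tolerance.
#' @param init Optional warm start: list with `intercept` and `beta`.
#' @return List with `intercept`, `beta` (named), `objective` (per-sweep
#'   trace), `converged`.
#' @export
fit_graph_logistic <- function(X, y, graph = NULL, lambda1 = 0.01,
                               lambda2 = 0, normalized = TRUE,
                               max_iter = 1000, tol = 1e-9, init = NULL) {
  X <- as.matrix(X)
  y01 <- if (is.logical(y)) as.numeric(y) else if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1))); y
  } else as.numeric(factor(y)) - 1
  if (length(unique(y01)) < 2) abort("response has a single class")
  n <- nrow(X)
  p <- ncol(X)
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("V", seq_len(p))
  L <- matrix(0, p, p, dimnames = list(genes, genes))
  if (!is.null(graph)) {
    Lg <- if (normalized) graph$laplacian_norm else graph$laplacian
    shared <- intersect(genes, rownames(Lg))
    L[shared, shared] <- Lg[shared, shared]
  }
  b0 <- if (is.null(init)) 0 else init$intercept
  beta <- if (is.null(init)) rep(0, p) else unname(init$beta)
  res <- .cpp_graph_logistic(X, y01, L, lambda1, lambda2, b0, beta,
                             as.integer(max_iter), tol)
  list(intercept = res$intercept,
       beta = stats::setNames(res$beta, genes),
       objective = res$objective, converged = res$converged)
}

#' Stratified train/test split indices
#' @noRd
stratified_split <- function(y, test_frac = 0.2) {
  test <- integer()
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1, round(test_frac * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' Cross-validated penalty choice (1-SE rule) for the graph-logistic model
#' @noRd
cv_graph_logistic <- function(X, y01, graph, lambda1_grid, lambda2_grid,
                              nfolds = 3, normalized = TRUE) {
  n <- nrow(X)
  folds <- sample(rep(seq_len(nfolds), length.out = n))
  best <- NULL
  ord <- order(lambda1_grid, decreasing = TRUE)  # path from sparse to dense
  for (l2 in lambda2_grid) {
    cv_dev <- matrix(NA_real_, nfolds, length(lambda1_grid))
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) next
      warm <- NULL
      for (li in ord) {
        fit <- fit_graph_logistic(X[tr, , drop = FALSE], y01[tr], graph,
                                  lambda1 = lambda1_grid[li], lambda2 = l2,
                                  normalized = normalized, max_iter = 200,
                                  tol = 1e-7, init = warm)
        warm <- fit
        eta <- fit$intercept + drop(X[!tr, , drop = FALSE] %*% fit$beta)
        # mean binomial deviance on the held-out fold
        cv_dev[f, li] <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) -
                                y01[!tr] * eta)
      }
    }
    m <- colMeans(cv_dev, na.rm = TRUE)
    se <- apply(cv_dev, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(0)
      sd(v) / sqrt(length(v))
    })
    i_min <- which.min(m)
    # 1-SE rule: the largest (sparsest) lambda1 within one SE of the minimum
    ok <- which(m <= m[i_min] + se[i_min])
    i_1se <- ok[which.max(lambda1_grid[ok])]
    if (is.null(best) || m[i_min] < best$dev_min) {
      best <- list(lambda1 = lambda1_grid[i_1se], lambda2 = l2,
                   dev_min = m[i_min])
    }
  }
  best
}

#' Repeated graph-logistic models with held-out performance
#'
#' Fits `n_models` graph-regularized sparse logistic classifiers of TNBC vs
#' non-TNBC on stratified 80/20 train/test splits.  On each training split,
#' `lambda1` is chosen by internal cross-validation with the 1-SE rule and
#' `lambda2` from a small fixed grid by the same CV; held-out sensitivity
#' and specificity use a 0.5 probability threshold.  A gene counts as
#' selected in a model when its coefficient is nonzero.
#'
#' @param expr Expression matrix (genes x samples) of one dataset.
#' @param samples Its `sample_table`.
#' @param graph A `comembership_graph` from [build_graph()].
#' @param genes Genes to use as predictors (default: graph nodes present in
#'   the matrix).
#' @param n_models Number of repeated splits.
#' @param test_frac Held-out fraction per split.
#' @param lambda1_grid,lambda2_grid Penalty grids for internal CV.
#' @param seed RNG seed (split + CV folds).
#' @return A `selection_summary` list: `counts` (times selected per gene),
#'   `models` (per-model sensitivity, specificity, lambdas, n selected),
#'   `n_models`, `dataset_id`.
#' @export
repeated_models <- function(expr, samples, graph, genes = NULL,
                            n_models = 10, test_frac = 0.2,
                            lambda1_grid = exp(seq(log(0.2), log(0.002),
                                                   length.out = 12)),
                            lambda2_grid = c(0, 0.1), seed = 1) {
  if (is.null(genes)) genes <- intersect(graph$nodes, rownames(expr))
  if (!length(genes)) abort("no predictor gene present in the matrix")
  idx <- match(colnames(expr), samples$sample_id)
  grp <- samples$group[idx]
  keep <- grp %in% c("TNBC", "non-TNBC")
  if (min(table(grp[keep])) < 5) abort("need >= 5 samples per group")
  X_all <- t(expr[genes, keep, drop = FALSE])
  y <- as.numeric(grp[keep] == "TNBC")

  set.seed(seed)
  counts <- stats::setNames(rep(0L, length(genes)), genes)
  models <- data.frame()
  for (m in seq_len(n_models)) {
    test <- stratified_split(y, test_frac)
    tr <- setdiff(seq_along(y), test)
    mu_tr <- colMeans(X_all[tr, , drop = FALSE])
    sd_tr <- apply(X_all[tr, , drop = FALSE], 2, sd)
    sd_tr[sd_tr == 0] <- 1
    Xtr <- scale(X_all[tr, , drop = FALSE], mu_tr, sd_tr)
    Xte <- scale(X_all[test, , drop = FALSE], mu_tr, sd_tr)
    pick <- cv_graph_logistic(Xtr, y[tr], graph, lambda1_grid, lambda2_grid)
    fit <- fit_graph_logistic(Xtr, y[tr], graph, lambda1 = pick$lambda1,
                              lambda2 = pick$lambda2, max_iter = 500,
                              tol = 1e-8)
    prob <- plogis(fit$intercept + drop(Xte %*% fit$beta))
    pred <- as.numeric(prob > 0.5)
    # exactly at the decision boundary (e.g. an intercept-only model on
    # balanced classes) a fair coin keeps null models at chance instead of
    # collapsing onto one class
    tie <- abs(prob - 0.5) < 1e-8
    if (any(tie)) pred[tie] <- rbinom(sum(tie), 1, 0.5)
    sens <- mean(pred[y[test] == 1] == 1)
    spec <- mean(pred[y[test] == 0] == 0)
    sel <- names(fit$beta)[fit$beta != 0]
    counts[sel] <- counts[sel] + 1L
    models <- rbind(models, data.frame(
      model = m, sensitivity = sens, specificity = spec,
      lambda1 = pick$lambda1, lambda2 = pick$lambda2,
      n_selected = length(sel)))
  }
  structure(list(counts = counts, models = models, n_models = n_models,
                 dataset_id = attr(expr, "dataset_id")),
            class = "selection_summary")
}

#' Predictive-gene rule across datasets
#'
#' Retains every gene selected at least `min_times` times in at least
#' `min_datasets` dataset summaries.  The default (once in two datasets)
#' covers both reported tiers: genes selected in all datasets and genes
#' selected in two.
#'
#' @param summaries List of `selection_summary` objects, one per dataset.
#' @param min_times Minimum selection count within a dataset.
#' @param min_datasets Minimum number of qualifying datasets.
#' @return Character vector of criterion-3 genes.
#' @export
predictive_gene_rule <- function(summaries, min_times = 1,
                                 min_datasets = 2) {
  if (length(summaries) < 2) abort("need >= 2 dataset summaries")
  genes <- unique(unlist(lapply(summaries, function(s) names(s$counts))))
  n_hit <- vapply(genes, function(g) {
    sum(vapply(summaries, function(s) {
      !is.na(s$counts[g]) && isTRUE(s$counts[g] >= min_times)
    }, logical(1)))
  }, numeric(1))
  sort(genes[n_hit >= min_datasets])
}
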