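# ChIP-evidence-constrained TF-gene network inference.  ChIP peaks within
# +/- 2 kb of a gene's TSS define the TF search space per gene; per gene and
# sample group an L1 (LASSO) regression of expression on bound-TF expression
# (with the gene's own CNA and DM as always-in covariates) is refit on 100
# random 80% subsamples; TFs are kept by selection frequency at a threshold
# chosen to maximize cross-validated predictive R^2 of an OLS refit.  The
# retained edges per group form bipartite networks whose set difference
# (TNBC minus non-TNBC) is the TNBC-specific network, ranked into master
# regulators by differential target count.

#' Annotate TF binding from ChIP peaks around gene TSSs
#'
#' A (TF, gene) pair is included when at least one of the TF's peak
#' intervals overlaps the window `[tss - window, tss + window)` by >= 1 bp
#' (all coordinates 0-based half-open; the window is symmetric regardless
#' of strand).
#'
#' @param peaks A `genomic_intervals` peak set (BED4 semantics).
#' @param tss A `tss_table`.
#' @param window Half-width of the promoter window in bp (default 2000).
#' @return A `binding_map`: named list mapping each TF to its candidate
#'   target genes.
#' @export
annotate_binding <- function(peaks, tss, window = 2000) {
  if (!nrow(peaks) || !nrow(tss)) return(structure(list(), class = "binding_map"))
  hits <- list()
  windows <- IRanges::IRanges(start = tss$tss - window,
                              end = tss$tss + window - 1L)
  for (chr in unique(tss$chrom)) {
    ti <- which(tss$chrom == chr)
    pi <- which(peaks$chrom == chr)
    if (!length(pi)) next
    # BED half-open [start, end) -> closed IRanges [start, end - 1]
    pk <- IRanges::IRanges(start = peaks$start[pi], end = peaks$end[pi] - 1L)
    ov <- IRanges::findOverlaps(pk, windows[ti])
    if (!length(ov)) next
    hits[[chr]] <- data.frame(
      tf = peaks$tf[pi][S4Vectors::queryHits(ov)],
      gene = tss$gene_symbol[ti][S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(structure(list(), class = "binding_map"))
  edges <- unique(do.call(rbind, hits))
  map <- split(edges$gene, edges$tf)
  map <- lapply(map, unique)
  structure(map[order(names(map))], class = "binding_map")
}

#' Candidate TFs bound at a gene
#' @param map A `binding_map`.
#' @param gene Gene symbol.
#' @return Character vector of TFs with a peak in the gene's window.
#' @export
bound_tfs <- function(map, gene) {
  names(map)[vapply(map, function(g) gene %in% g, logical(1))]
}

#' Stability selection of TF regulators for one gene
#'
#' Repeats an L1-penalized regression of the gene's expression on the
#' expression of its ChIP-bound TFs `n_rep` times on random subsamples
#' (fraction `subsample`, without replacement), with the gene's own CNA and
#' DM values included as unpenalized covariates so TF selection is
#' conditional on them.  The penalty is chosen by internal cross-validation
#' on each subsample.  A TF's selection frequency is the fraction of
#' repetitions in which its coefficient is nonzero.
#'
#' @param gene Target gene symbol.
#' @param expr Expression matrix containing the gene.
#' @param tf_expr TF expression matrix (TFs x samples).
#' @param cna,dm CNA / DM matrices containing the gene's row (or `NULL` to
#'   omit the covariate).
#' @param samples A `sample_table`.
#' @param group Sample group to model (`"TNBC"` or `"non-TNBC"`).
#' @param binding A `binding_map` restricting the TF search space.
#' @param n_rep Number of subsample repetitions.
#' @param subsample Subsample fraction.
#' @param penalize_covariates Penalize CNA/DM like the TFs instead of
#'   keeping them always in.
#' @param cv_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @param seed RNG seed; results are deterministic given it.
#' @return A `stability_profile` list: `gene`, `group`, `frequency` (named
#'   per TF), `n_rep`.  Empty frequency (with a message) when the gene has
#'   no bound TFs.
#' @export
stability_select <- function(gene, expr, tf_expr, cna = NULL, dm = NULL,
                             samples, group = "TNBC", binding,
                             n_rep = 100, subsample = 0.8,
                             penalize_covariates = FALSE,
                             cv_rule = "lambda.1se", seed = 1) {
  tfs <- bound_tfs(binding, gene)
  tfs <- intersect(tfs, rownames(tf_expr))
  if (!length(tfs)) {
    message(sprintf("gene %s has no ChIP-bound TF; empty profile", gene))
    return(structure(list(gene = gene, group = group,
                          frequency = stats::setNames(numeric(), character()),
                          n_rep = n_rep),
                     class = "stability_profile"))
  }
  idx <- match(colnames(expr), samples$sample_id)
  cols <- colnames(expr)[samples$group[idx] == group]
  cols <- intersect(cols, colnames(tf_expr))
  if (length(cols) < 10) abort("need >= 10 samples in group %s", group)
  y_all <- expr[gene, cols]
  X_all <- t(tf_expr[tfs, cols, drop = FALSE])
  covars <- NULL
  if (!is.null(cna) && gene %in% rownames(cna)) {
    covars <- cbind(covars, CNA = cna[gene, cols])
  }
  if (!is.null(dm) && gene %in% rownames(dm)) {
    covars <- cbind(covars, DM = dm[gene, cols])
  }
  X_full <- cbind(X_all, covars)
  pen <- c(rep(1, length(tfs)),
           rep(if (penalize_covariates) 1 else 0, ncol(X_full) - length(tfs)))
  n <- length(cols)
  n_sub <- max(10, floor(subsample * n))
  hit <- stats::setNames(rep(0L, length(tfs)), tfs)
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    take <- sample(n, n_sub)
    Xs <- X_full[take, , drop = FALSE]
    ys <- y_all[take]
    keep_col <- apply(Xs, 2, sd) > 0
    if (sum(keep_col[seq_along(tfs)]) == 0 || sd(ys) == 0) next
    cvfit <- glmnet::cv.glmnet(Xs[, keep_col, drop = FALSE], ys,
                               family = "gaussian", nfolds = 3,
                               nlambda = 30, standardize = TRUE,
                               penalty.factor = pen[keep_col])
    b <- coef(cvfit, s = cv_rule)[-1, 1]
    sel <- names(b)[b != 0]
    sel <- intersect(sel, tfs)
    hit[sel] <- hit[sel] + 1L
  }
  structure(list(gene = gene, group = group, frequency = hit / n_rep,
                 n_rep = n_rep),
            class = "stability_profile")
}

#' Choose a selection-frequency threshold by predictive performance
#'
#' Scans a threshold grid; at each value, TFs with frequency >= threshold
#' (plus the CNA/DM covariates) are refit by ordinary least squares and
#' scored by 5-fold cross-validated R^2 on the group samples.  The smallest
#' R^2-maximizing model wins: ties go to the larger (sparser) threshold.
#' Thresholds retaining no TF are ineligible; if every threshold retains
#' nothing the gene is excluded (returns `NULL`).
#'
#' @param profile A `stability_profile`.
#' @param expr,tf_expr,cna,dm,samples As in [stability_select()].
#' @param grid Threshold grid (default 0.1 to 0.9 by 0.1).
#' @param nfolds CV folds.
#' @param seed RNG seed for fold assignment.
#' @return List with `threshold`, `retained` (TFs), `r2` per grid value; or
#'   `NULL` when no threshold retains a TF.
#' @export
choose_threshold <- function(profile, expr, tf_expr, cna = NULL, dm = NULL,
                             samples, grid = seq(0.1, 0.9, by = 0.1),
                             nfolds = 5, seed = 1) {
  freq <- profile$frequency
  if (!length(freq) || all(freq < min(grid))) return(NULL)
  gene <- profile$gene
  idx <- match(colnames(expr), samples$sample_id)
  cols <- colnames(expr)[samples$group[idx] == profile$group]
  cols <- intersect(cols, colnames(tf_expr))
  y <- expr[gene, cols]
  covars <- NULL
  if (!is.null(cna) && gene %in% rownames(cna)) {
    covars <- cbind(covars, CNA = cna[gene, cols])
  }
  if (!is.null(dm) && gene %in% rownames(dm)) {
    covars <- cbind(covars, DM = dm[gene, cols])
  }
  set.seed(seed)
  folds <- sample(rep(seq_len(nfolds), length.out = length(cols)))
  r2 <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    tfs <- names(freq)[freq >= grid[i]]
    if (!length(tfs)) next
    X <- cbind(t(tf_expr[tfs, cols, drop = FALSE]), covars)
    press <- 0
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      df_tr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
      fit <- lm(y ~ ., data = df_tr)
      pred <- predict(fit, newdata = data.frame(X[!tr, , drop = FALSE]))
      press <- press + sum((y[!tr] - pred)^2)
    }
    r2[i] <- 1 - press / sum((y - mean(y))^2)
  }
  if (all(is.na(r2))) return(NULL)
  best <- max(which(r2 >= max(r2, na.rm = TRUE) - 1e-12))
  list(threshold = grid[best], retained = names(freq)[freq >= grid[best]],
       r2 = stats::setNames(r2, grid))
}

#' Build the TF-gene network of one sample group
#'
#' Runs [stability_select()] and [choose_threshold()] for each gene and
#' collects the retained TF edges, annotated with selection frequency.
#'
#' @param genes Candidate genes to model.
#' @param expr,tf_expr,cna,dm,samples Input layers.
#' @param binding A `binding_map`.
#' @param group Sample group.
#' @param n_rep,subsample,seed Passed to [stability_select()].
#' @param ... Further arguments to [stability_select()].
#' @return A `bipartite_network` for the group.
#' @export
build_group_network <- function(genes, expr, tf_expr, cna = NULL, dm = NULL,
                                samples, binding, group = "TNBC",
                                n_rep = 100, subsample = 0.8, seed = 1, ...) {
  tf_e <- character(); gene_e <- character(); freq_e <- numeric()
  for (g in genes) {
    prof <- stability_select(g, expr, tf_expr, cna, dm, samples,
                             group = group, binding = binding,
                             n_rep = n_rep, subsample = subsample,
                             seed = child_seed(seed, "stab", group, g), ...)
    if (!length(prof$frequency)) next
    ch <- choose_threshold(prof, expr, tf_expr, cna, dm, samples,
                           seed = child_seed(seed, "thr", group, g))
    if (is.null(ch)) next
    tf_e <- c(tf_e, ch$retained)
    gene_e <- c(gene_e, rep(g, length(ch$retained)))
    freq_e <- c(freq_e, unname(prof$frequency[ch$retained]))
  }
  bipartite_network(tf_e, gene_e, freq_e, group = group)
}

#' Differential network: edges specific to the TNBC network
#'
#' Subtracts the non-TNBC network from the TNBC network as pure edge-set
#' difference: a TNBC edge survives when its (TF, gene) pair is absent from
#' the non-TNBC network, regardless of frequencies.  With
#' `min_freq_gap > 0`, a TNBC edge also survives when present in both but
#' with a selection-frequency excess of at least the gap (non-default).
#'
#' @param tnbc,non_tnbc `bipartite_network` objects for the two groups.
#' @param min_freq_gap Frequency-difference mode (0 = pure subtraction).
#' @return A `differential_network` list: `edges` (TNBC-specific), plus the
#'   per-TF target counts in `tf_counts`.
#' @export
differential_network <- function(tnbc, non_tnbc, min_freq_gap = 0) {
  key_t <- paste(tnbc$edges$tf, tnbc$edges$gene, sep = "\r")
  key_n <- paste(non_tnbc$edges$tf, non_tnbc$edges$gene, sep = "\r")
  specific <- !(key_t %in% key_n)
  if (min_freq_gap > 0) {
    both <- match(key_t, key_n)
    gap <- tnbc$edges$frequency - non_tnbc$edges$frequency[both]
    specific <- specific | (!is.na(gap) & gap >= min_freq_gap)
  }
  edges <- tnbc$edges[specific, , drop = FALSE]
  rownames(edges) <- NULL
  counts <- sort(table(edges$tf), decreasing = TRUE)
  structure(list(edges = edges,
                 tf_counts = stats::setNames(as.integer(counts),
                                             names(counts))),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("TNBC-specific network: %d TFs, %d edges\n",
              length(x$tf_counts), nrow(x$edges)))
  invisible(x)
}

#' Master regulators of the differential network
#'
#' TFs whose TNBC-specific target count reaches `min_targets`, sorted by
#' count (descending) then TF name.
#'
#' @param report A `differential_network` (or `bipartite_network`).
#' @param min_targets Minimum number of distinct targets.
#' @return Data frame `tf`, `n_targets`, `targets` (comma-separated).
#' @export
master_regulators <- function(report, min_targets = 4) {
  edges <- report$edges
  if (is.null(edges) || !nrow(edges)) {
    return(data.frame(tf = character(), n_targets = integer(),
                      targets = character(), stringsAsFactors = FALSE))
  }
  tgt <- lapply(split(edges$gene, edges$tf), unique)
  n <- vapply(tgt, length, integer(1))
  keep <- names(tgt)[n >= min_targets]
  ord <- keep[order(-n[keep], keep)]
  data.frame(tf = ord, n_targets = unname(n[ord]),
             targets = vapply(tgt[ord], paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}
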