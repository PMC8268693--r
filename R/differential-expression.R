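# Criterion one: per-dataset moderated-t differential expression for the two
# contrasts (TNBC vs non-TNBC, TNBC vs normal), direction-concordance
# filtering within and across datasets, and top-50% selection.
#
# The moderated t shrinks per-gene sample variances s_g^2 toward a prior
# s0^2 with prior degrees of freedom d0, both estimated by method of moments
# on log s_g^2 (scaled-inverse-chi-square hierarchical model):
#   s_tilde_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)
#   t_g = log2FC_g / (s_tilde_g * sqrt(1/n1 + 1/n2)),  df = d0 + d_g.

#' Inverse of the trigamma function (Newton iteration)
#' @noRd
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Estimate the variance prior (s0^2, d0) by method of moments on log s^2
#'
#' Fits the scaled F sampling model for observed gene variances: given
#' residual df `df_resid`, `log(s2)` has known excess variance
#' `trigamma(df/2)`; the remaining spread identifies the prior df `d0` and
#' the location identifies `s0^2`.  `d0 = Inf` when the observed spread is
#' no larger than the sampling spread (complete shrinkage).
#'
#' @param s2 Per-gene sample variances (positive).
#' @param df_resid Residual degrees of freedom (scalar or per gene).
#' @return List with `s0_sq` and `d0`.
#' @export
estimate_variance_prior <- function(s2, df_resid) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  df_resid <- rep_len(df_resid, length(ok))[ok]
  if (!length(s2)) abort("no positive finite variances to moderate")
  z <- log(s2)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  e_bar <- mean(e)
  n <- length(e)
  if (n < 2) return(list(s0_sq = exp(e_bar), d0 = Inf))
  v_e <- mean((e - e_bar)^2) * n / (n - 1) - mean(trigamma(df_resid / 2))
  if (v_e <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_bar)
  } else {
    d0 <- 2 * trigamma_inverse(v_e)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(s0_sq = s0_sq, d0 = d0)
}

#' Moderated two-sample t table for one contrast
#'
#' Computes, per gene, the log2 fold change between the two contrast arms,
#' an empirical-Bayes moderated t statistic, raw and BH-adjusted p-values,
#' and a direction call (`"up"`/`"down"` by the sign of the fold change).
#' Genes with more than 20% missing values in the contrast samples are
#' dropped with a warning; genes with zero residual df are excluded.
#'
#' @param expr Expression matrix (genes x samples, log2 scale) from
#'   [expression_matrix()].
#' @param samples A `sample_table` covering the matrix columns.
#' @param contrast Length-2 character vector `c(test_group, ref_group)`;
#'   log2FC is `mean(test) - mean(ref)`.
#' @param prior_df Override for the prior df `d0`: `NULL` (estimate),
#'   `0` (no shrinkage; ordinary pooled t) or `Inf` (complete shrinkage).
#' @param prior_var Override for `s0^2` (used when `prior_df` is forced).
#' @param max_missing Maximum tolerated fraction of missing values per gene.
#' @return A `de_table` data frame with columns `gene`, `contrast`,
#'   `log2fc`, `t`, `df`, `p`, `fdr`, `direction`, `dataset_id`.
#' @export
moderated_t_table <- function(expr, samples, contrast = c("TNBC", "non-TNBC"),
                              prior_df = NULL, prior_var = NULL,
                              max_missing = 0.2) {
  stopifnot(length(contrast) == 2)
  dataset_id <- attr(expr, "dataset_id")
  if (is.null(dataset_id)) dataset_id <- "dataset"
  idx <- match(colnames(expr), samples$sample_id)
  if (anyNA(idx)) abort("sample %s missing from sample table",
                        colnames(expr)[which(is.na(idx))[1]])
  grp <- samples$group[idx]
  a <- which(grp == contrast[1])
  b <- which(grp == contrast[2])
  if (!length(a) || !length(b)) {
    abort("empty contrast arm '%s'", contrast[if (!length(a)) 1 else 2])
  }
  if (length(a) < 2 || length(b) < 2) {
    abort("need >= 2 samples per contrast arm")
  }
  sub <- expr[, c(a, b), drop = FALSE]
  miss_frac <- rowMeans(is.na(sub))
  if (any(miss_frac > max_missing)) {
    drop <- rownames(sub)[miss_frac > max_missing]
    warn("dropping %d gene(s) with > %d%% missing values (%s%s)",
         length(drop), round(100 * max_missing), paste(head(drop, 3),
         collapse = ", "), if (length(drop) > 3) ", ..." else "")
    sub <- sub[miss_frac <= max_missing, , drop = FALSE]
  }
  arm <- rep(c(TRUE, FALSE), c(length(a), length(b)))

  n1 <- rowSums(!is.na(sub[, arm, drop = FALSE]))
  n2 <- rowSums(!is.na(sub[, !arm, drop = FALSE]))
  m1 <- rowMeans(sub[, arm, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(sub[, !arm, drop = FALSE], na.rm = TRUE)
  v1 <- apply(sub[, arm, drop = FALSE], 1, var, na.rm = TRUE)
  v2 <- apply(sub[, !arm, drop = FALSE], 1, var, na.rm = TRUE)
  df_resid <- n1 + n2 - 2
  keep <- df_resid > 0 & n1 >= 1 & n2 >= 1
  if (!all(keep)) {
    warn("excluding %d gene(s) with zero residual df", sum(!keep))
    sub <- sub[keep, , drop = FALSE]
    n1 <- n1[keep]; n2 <- n2[keep]; m1 <- m1[keep]; m2 <- m2[keep]
    v1 <- v1[keep]; v2 <- v2[keep]; df_resid <- df_resid[keep]
  }
  s2 <- (ifelse(n1 > 1, (n1 - 1) * v1, 0) +
         ifelse(n2 > 1, (n2 - 1) * v2, 0)) / df_resid

  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2[s2 > 0], df_resid[s2 > 0])
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    d0 <- prior_df
    s0_sq <- if (is.null(prior_var)) {
      if (is.finite(d0) && d0 > 0) {
        estimate_variance_prior(s2[s2 > 0], df_resid[s2 > 0])$s0_sq
      } else if (!is.finite(d0)) {
        exp(mean(log(s2[s2 > 0])))
      } else 0
    } else prior_var
  }
  s_tilde2 <- if (!is.finite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  }
  log2fc <- m1 - m2
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  tstat <- log2fc / se
  df_total <- if (is.finite(d0)) d0 + df_resid else Inf
  p <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  out <- data.frame(
    gene = rownames(sub),
    contrast = paste(contrast, collapse = "_vs_"),
    log2fc = log2fc, t = tstat, df = rep_len(df_total, nrow(sub)), p = p,
    fdr = bh_adjust(p),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA)),
    dataset_id = dataset_id, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Run both study contrasts on one dataset
#'
#' @inheritParams moderated_t_table
#' @param ref_groups Reference groups; each is contrasted against `"TNBC"`.
#' @return A `de_table` with both contrasts stacked.
#' @export
run_de <- function(expr, samples,
                   ref_groups = c("non-TNBC", "normal"), ...) {
  tabs <- lapply(ref_groups, function(ref) {
    moderated_t_table(expr, samples, contrast = c("TNBC", ref), ...)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Direction-concordant differentially expressed genes
#'
#' A gene passes when it reaches `fdr < fdr_threshold` in *both* contrasts
#' and is regulated in the same direction in both.  Genes with an ambiguous
#' direction (zero fold change) are excluded.
#'
#' @param de A `de_table` containing two contrasts for one dataset.
#' @param fdr_threshold Significance threshold on the BH-adjusted p.
#' @return Named character vector: directions (`"up"`/`"down"`) named by
#'   gene symbol.
#' @export
concordant_de <- function(de, fdr_threshold = 0.05) {
  contrasts <- unique(de$contrast)
  if (length(contrasts) != 2) {
    abort("concordant_de expects exactly 2 contrasts, got %d",
          length(contrasts))
  }
  t1 <- de[de$contrast == contrasts[1], ]
  t2 <- de[de$contrast == contrasts[2], ]
  common <- intersect(t1$gene, t2$gene)
  i1 <- match(common, t1$gene)
  i2 <- match(common, t2$gene)
  pass <- t1$fdr[i1] < fdr_threshold & t2$fdr[i2] < fdr_threshold &
    !is.na(t1$direction[i1]) & !is.na(t2$direction[i2]) &
    t1$direction[i1] == t2$direction[i2]
  pass[is.na(pass)] <- FALSE
  stats::setNames(t1$direction[i1][pass], common[pass])
}

#' Intersect direction-annotated DE gene sets across datasets
#'
#' Keeps genes called in every dataset with the same direction everywhere;
#' genes with conflicting directions are dropped with a message.
#'
#' @param per_dataset_sets List of named direction vectors as returned by
#'   [concordant_de()], one per dataset.
#' @return Named direction vector of the common genes.
#' @export
cross_dataset_intersection <- function(per_dataset_sets) {
  if (length(per_dataset_sets) < 2) abort("need >= 2 datasets to intersect")
  common <- Reduce(intersect, lapply(per_dataset_sets, names))
  if (!length(common)) return(stats::setNames(character(), character()))
  dirs <- vapply(per_dataset_sets, function(s) s[common], character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  agree <- apply(dirs, 1, function(d) length(unique(d)) == 1)
  if (any(!agree)) {
    message(sprintf("dropping %d gene(s) with conflicting direction across datasets: %s",
                    sum(!agree), paste(common[!agree], collapse = ", ")))
  }
  stats::setNames(dirs[agree, 1], common[agree])
}

#' Select the top half of common DE genes by moderated-t magnitude
#'
#' Genes are ranked by the mean absolute moderated t across all contrasts
#' and datasets; the top `ceiling(n/2)` are returned.  Ties are broken by
#' smaller mean FDR, then lexicographic gene symbol.
#'
#' @param common_genes Character vector (or named direction vector) of genes
#'   common across datasets.
#' @param de_tables List of `de_table` objects (all datasets).
#' @return Character vector of selected genes (criterion-1 list).
#' @export
top_half <- function(common_genes, de_tables) {
  genes <- if (!is.null(names(common_genes))) names(common_genes)
           else as.character(common_genes)
  if (!length(genes)) abort("empty common gene list")
  all_de <- do.call(rbind, lapply(de_tables, as.data.frame))
  all_de <- all_de[all_de$gene %in% genes, ]
  score <- tapply(abs(all_de$t), all_de$gene, mean)
  mean_fdr <- tapply(all_de$fdr, all_de$gene, mean)
  score <- score[genes]
  mean_fdr <- mean_fdr[genes]
  ord <- order(-score, mean_fdr, genes)
  k <- ceiling(length(genes) / 2)
  sort(genes[ord][seq_len(k)])
}
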