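# Criterion two: ensemble gene-set enrichment.  Two base methods — exact
# hypergeometric over-representation and a Wilcoxon rank-sum on member-gene
# moderated t statistics — are combined by mean rank and Fisher's method,
# BH-adjusted across sets.  A set's direction is the sign of the mean
# moderated t of its members.  Sets must be enriched with the same direction
# in both contrasts of every dataset to pass; criterion-2 genes are members
# of passing glycosylation sets whose own DE direction matches the set's.

#' Exact hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a DE gene list and a gene set, drawn without replacement from the
#' universe.
#'
#' @param de_genes Character vector of differential genes (subset of
#'   `universe`).
#' @param gene_set Character vector of set members (subset of `universe`).
#' @param universe Character vector of background genes.
#' @return `P(X >= overlap)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
ora_test <- function(de_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  de_genes <- unique(intersect(de_genes, universe))
  gene_set <- unique(intersect(gene_set, universe))
  k <- length(intersect(de_genes, gene_set))
  N <- length(universe)
  K <- length(gene_set)
  n <- length(de_genes)
  # P(X >= k); k = 0 gives 1 by convention
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank-sum enrichment of member-gene t statistics
#'
#' Two-sided Wilcoxon rank-sum comparing moderated t statistics of set
#' members against non-members; the exact null is used for small member
#' counts, the tie-corrected normal approximation otherwise.  The direction
#' is the sign of the mean member t.
#'
#' @param t_stats Named numeric vector of per-gene moderated t statistics.
#' @param gene_set Character vector of member symbols.
#' @param exact_max Largest member count for which the exact null is used.
#' @return List with `p` and `direction` (`"up"`/`"down"`, or `NA` with a
#'   warning when all statistics are identical).
#' @export
rank_test <- function(t_stats, gene_set, exact_max = 10) {
  member <- names(t_stats) %in% gene_set
  x <- t_stats[member]
  y <- t_stats[!member]
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    abort("rank_test needs >= 1 member and >= 1 non-member with finite t")
  }
  if (length(unique(c(x, y))) == 1) {
    warn("all t statistics identical; set dropped from rank test")
    return(list(p = 1, direction = NA_character_))
  }
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = length(x) <= exact_max, correct = FALSE))
  list(p = res$p.value, direction = if (mean(x) > 0) "up" else "down")
}

#' Combine base-method results into an ensemble score
#'
#' Per-method p-values are converted to within-method ranks (1 = most
#' enriched; ties resolved deterministically by set name), averaged into an
#' ensemble rank, and combined by Fisher's method; the combined p-values are
#' BH-adjusted across sets.
#'
#' @param per_method_p Named list (one element per base method) of numeric
#'   vectors of p-values, each named by gene set.  Sets missing from any
#'   method are excluded with a message.
#' @return Data frame with `set`, per-method ranks, `ensemble_rank`,
#'   `combined_p`, `fdr`.
#' @export
ensemble_combine <- function(per_method_p) {
  if (length(per_method_p) < 2) abort("need >= 2 base methods to combine")
  sets <- Reduce(intersect, lapply(per_method_p, names))
  dropped <- setdiff(unique(unlist(lapply(per_method_p, names))), sets)
  if (length(dropped)) {
    message(sprintf("excluding %d set(s) missing from some method: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (!length(sets)) abort("no gene set scored by every method")
  pmat <- vapply(per_method_p, function(p) p[sets], numeric(length(sets)))
  pmat <- matrix(pmat, nrow = length(sets),
                 dimnames = list(sets, names(per_method_p)))
  ranks <- apply(pmat, 2, function(p) {
    r <- integer(length(p))
    r[order(p, sets)] <- seq_along(p)
    r
  })
  ranks <- matrix(ranks, nrow = length(sets),
                  dimnames = list(sets, colnames(pmat)))
  fisher_stat <- -2 * rowSums(log(pmax(pmat, 1e-300)))
  combined_p <- pchisq(fisher_stat, df = 2 * ncol(pmat), lower.tail = FALSE)
  out <- data.frame(set = sets, stringsAsFactors = FALSE)
  for (m in colnames(ranks)) out[[paste0("rank_", m)]] <- ranks[, m]
  out$ensemble_rank <- rowMeans(ranks)
  out$combined_p <- combined_p
  out$fdr <- bh_adjust(combined_p)
  rownames(out) <- NULL
  out
}

#' Ensemble enrichment of a gene-set collection for one contrast
#'
#' Runs both base methods against the DE results of one dataset/contrast
#' and combines them.  The DE gene list for the over-representation test is
#' taken at `fdr < de_fdr` within the contrast.
#'
#' @param de_contrast One-contrast slice of a `de_table`.
#' @param collection A `gene_sets` collection.
#' @param universe Background genes; default all genes in the DE table.
#' @param de_fdr FDR cut defining the DE list for the ORA component.
#' @return An enrichment table (data frame) with per-set ensemble scores,
#'   `direction`, plus `contrast` and `dataset_id` columns.
#' @export
enrich_contrast <- function(de_contrast, collection, universe = NULL,
                            de_fdr = 0.05) {
  stopifnot(length(unique(de_contrast$contrast)) == 1)
  t_stats <- stats::setNames(de_contrast$t, de_contrast$gene)
  if (is.null(universe)) universe <- de_contrast$gene
  de_genes <- de_contrast$gene[de_contrast$fdr < de_fdr]
  p_ora <- vapply(collection, function(s) ora_test(de_genes, s, universe),
                  numeric(1))
  rank_res <- lapply(collection, function(s) {
    members <- intersect(s, names(t_stats))
    if (!length(members) || length(members) == length(t_stats)) {
      return(list(p = NA_real_, direction = NA_character_))
    }
    rank_test(t_stats, members)
  })
  p_rank <- vapply(rank_res, `[[`, numeric(1), "p")
  direction <- vapply(rank_res, `[[`, character(1), "direction")
  ok <- !is.na(p_rank) & !is.na(direction)
  if (!any(ok)) abort("no scorable gene set for this contrast")
  comb <- ensemble_combine(list(ora = p_ora[ok], ranksum = p_rank[ok]))
  comb$direction <- direction[comb$set]
  comb$contrast <- unique(de_contrast$contrast)
  comb$dataset_id <- unique(de_contrast$dataset_id)
  comb
}

#' Enrichment across both contrasts of every dataset
#'
#' @param de_tables List of `de_table` objects, one per dataset (each with
#'   both contrasts).
#' @param collection A `gene_sets` collection (identical across datasets).
#' @param ... Passed to [enrich_contrast()].
#' @return Stacked enrichment table across datasets and contrasts.
#' @export
run_enrichment <- function(de_tables, collection, ...) {
  out <- list()
  for (de in de_tables) {
    for (ct in unique(de$contrast)) {
      out[[length(out) + 1]] <-
        enrich_contrast(de[de$contrast == ct, ], collection, ...)
    }
  }
  do.call(rbind, out)
}

#' Sets enriched with a concordant direction everywhere
#'
#' A set passes when it reaches `fdr < threshold` with the same direction in
#' both contrasts of every dataset.
#'
#' @param enrichment Stacked enrichment table from [run_enrichment()].
#' @param fdr Significance threshold.
#' @return Named direction vector of passing sets.
#' @export
concordant_enriched_sets <- function(enrichment, fdr = 0.05) {
  n_cells <- length(unique(paste(enrichment$dataset_id,
                                 enrichment$contrast)))
  keep <- character()
  dir_out <- character()
  for (s in unique(enrichment$set)) {
    rows <- enrichment[enrichment$set == s, ]
    if (nrow(rows) < n_cells) next
    if (all(rows$fdr < fdr) && !anyNA(rows$direction) &&
        length(unique(rows$direction)) == 1) {
      keep <- c(keep, s)
      dir_out <- c(dir_out, rows$direction[1])
    }
  }
  stats::setNames(dir_out, keep)
}

#' Criterion-2 genes: members concordant with their enriched set
#'
#' Member genes of the passing glycosylation sets are retained when their
#' own DE direction (sign of the moderated t) equals the set's direction in
#' every dataset and contrast.
#'
#' @param enriched_sets Named direction vector from
#'   [concordant_enriched_sets()].
#' @param collection The `gene_sets` collection.
#' @param de_tables List of `de_table` objects across datasets.
#' @return Character vector of selected genes.
#' @export
criterion2_genes <- function(enriched_sets, collection, de_tables) {
  if (!length(enriched_sets)) return(character())
  all_de <- do.call(rbind, lapply(de_tables, as.data.frame))
  selected <- character()
  for (s in names(enriched_sets)) {
    want <- enriched_sets[[s]]
    for (g in collection[[s]]) {
      rows <- all_de[all_de$gene == g, ]
      if (!nrow(rows)) next
      dirs <- ifelse(rows$t > 0, "up", "down")
      if (all(dirs == want)) selected <- c(selected, g)
    }
  }
  sort(unique(selected))
}
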