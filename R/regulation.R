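# Regulatory attribution to copy number and methylation.  Per-group Spearman
# correlation between expression and each regulator layer, strength classes
# on |rho| (strong >= 0.450, moderate 0.300-0.449, weak 0.100-0.299, low/no
# < 0.100), the differential-correlation statistic
#   deltaCor = |Cor(g, reg)_TNBC - Cor(g, reg)_nonTNBC|
# and Mann-Whitney testing of per-gene correlation distributions between the
# two tumour groups, per pathway, BH-adjusted.

#' Per-group Spearman correlation of expression with a regulator layer
#'
#' Correlates each gene's expression with its own value in the regulator
#' matrix (CNA copy ratios or DM beta values), within each sample group of
#' interest plus the pooled `"all"` group (TNBC + non-TNBC).  Pairs with
#' missing values are excluded pairwise; genes with fewer than `min_pairs`
#' complete pairs or a constant vector get a missing entry with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param layer Regulator matrix sharing gene/sample indices.
#' @param samples A `sample_table`.
#' @param regulator Label stored in the output (`"CNA"` or `"DM"`).
#' @param genes Genes to correlate (default: all shared genes).
#' @param min_pairs Minimum complete pairs per correlation.
#' @return A `correlation_table` data frame: `gene`, `group`, `regulator`,
#'   `rho`, `n`, `class`.
#' @export
spearman_by_group <- function(expr, layer, samples, regulator = "CNA",
                              genes = NULL, min_pairs = 3) {
  shared_samples <- intersect(colnames(expr), colnames(layer))
  if (!length(shared_samples)) abort("no shared samples between layers")
  if (is.null(genes)) genes <- intersect(rownames(expr), rownames(layer))
  idx <- match(shared_samples, samples$sample_id)
  if (anyNA(idx)) abort("sample %s missing from sample table",
                        shared_samples[which(is.na(idx))[1]])
  grp <- samples$group[idx]
  groups <- list(all = grp %in% c("TNBC", "non-TNBC"),
                 TNBC = grp == "TNBC", `non-TNBC` = grp == "non-TNBC")
  out <- list()
  n_degenerate <- 0
  for (gname in names(groups)) {
    cols <- shared_samples[groups[[gname]]]
    for (g in genes) {
      x <- expr[g, cols]
      y <- layer[g, cols]
      ok <- is.finite(x) & is.finite(y)
      rho <- NA_real_
      if (sum(ok) >= min_pairs && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        rho <- cor(x[ok], y[ok], method = "spearman")
      } else {
        n_degenerate <- n_degenerate + 1
      }
      out[[length(out) + 1]] <- data.frame(
        gene = g, group = gname, regulator = regulator, rho = rho,
        n = sum(ok), class = classify_strength(rho)$class,
        stringsAsFactors = FALSE)
    }
  }
  if (n_degenerate > 0) {
    warn("%d gene/group correlation(s) undefined (constant or < %d pairs)",
         n_degenerate, min_pairs)
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Classify regulatory strength from a Spearman coefficient
#'
#' Classes on the absolute coefficient: strong (>= 0.450), moderate
#' (0.300 to 0.449), weak (0.100 to 0.299) and low/no (< 0.100).  For
#' methylation the sign matters biologically: a `dm_sign_consistent` flag
#' marks negative coefficients (methylation represses expression), while
#' magnitude classes are reported for both signs.
#'
#' @param rho Spearman coefficient(s); `NA` allowed.
#' @param regulator `"CNA"` or `"DM"` (controls the sign flag only).
#' @return List with `class` (character vector) and `dm_sign_consistent`
#'   (logical vector; `NA` unless `regulator == "DM"`).
#' @export
classify_strength <- function(rho, regulator = "CNA") {
  a <- abs(rho)
  cls <- ifelse(is.na(a), NA_character_,
         ifelse(a >= 0.450, "strong",
         ifelse(a >= 0.300, "moderate",
         ifelse(a >= 0.100, "weak", "low/no"))))
  flag <- if (identical(regulator, "DM")) rho < 0 else rep(NA, length(rho))
  list(class = cls, dm_sign_consistent = flag)
}

#' Differential correlation between tumour groups
#'
#' `deltaCor = |rho_TNBC - rho_nonTNBC|` per gene and regulator; entries
#' with either group correlation missing are reported missing.
#'
#' @param table A `correlation_table` from [spearman_by_group()] (may stack
#'   several regulators).
#' @return Data frame `gene`, `regulator`, `rho_tnbc`, `rho_non_tnbc`,
#'   `delta_cor`.
#' @export
delta_cor <- function(table) {
  key <- unique(table[, c("gene", "regulator")])
  out <- list()
  for (i in seq_len(nrow(key))) {
    rows <- table[table$gene == key$gene[i] &
                    table$regulator == key$regulator[i], ]
    r_t <- rows$rho[rows$group == "TNBC"]
    r_n <- rows$rho[rows$group == "non-TNBC"]
    r_t <- if (length(r_t)) r_t[1] else NA_real_
    r_n <- if (length(r_n)) r_n[1] else NA_real_
    out[[i]] <- data.frame(gene = key$gene[i], regulator = key$regulator[i],
                           rho_tnbc = r_t, rho_non_tnbc = r_n,
                           delta_cor = abs(r_t - r_n),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (anyNA(res$delta_cor)) {
    message(sprintf("%d deltaCor entr(ies) missing a group correlation",
                    sum(is.na(res$delta_cor))))
  }
  res
}

#' Mann-Whitney test of differential regulation per pathway
#'
#' For each grouping of genes (a pathway, or all genes), compares the
#' distribution of per-gene correlations in TNBC against non-TNBC with the
#' two-sided Mann-Whitney(-Wilcoxon) rank-sum test — exact null when the
#' combined sample is small, tie-corrected normal approximation otherwise —
#' or the paired signed-rank variant.  P-values are BH-adjusted across
#' groupings.
#'
#' @param table A `correlation_table` restricted to one regulator.
#' @param groupings Named list of gene vectors (e.g. pathway memberships);
#'   `NULL` runs one test over all genes.
#' @param paired Use the paired signed-rank variant (pairs genes across the
#'   two groups).
#' @param exact_max Largest combined sample size for the exact null.
#' @return Data frame `grouping`, `n_genes`, `statistic`, `p`, `fdr`.
#' @export
test_differential_regulation <- function(table, groupings = NULL,
                                         paired = FALSE, exact_max = 12) {
  stopifnot(length(unique(table$regulator)) == 1)
  if (is.null(groupings)) groupings <- list(all = unique(table$gene))
  out <- list()
  for (nm in names(groupings)) {
    genes <- intersect(groupings[[nm]], unique(table$gene))
    rows <- table[table$gene %in% genes, ]
    x <- rows$rho[rows$group == "TNBC"][match(genes,
           rows$gene[rows$group == "TNBC"])]
    y <- rows$rho[rows$group == "non-TNBC"][match(genes,
           rows$gene[rows$group == "non-TNBC"])]
    if (paired) {
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
    } else {
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
    }
    if (length(x) < 2 || length(y) < 2) {
      message(sprintf("skipping grouping '%s' with < 2 usable genes", nm))
      next
    }
    if (sd(c(x, y)) == 0) {
      # every correlation identical: no evidence either way
      out[[length(out) + 1]] <- data.frame(
        grouping = nm, n_genes = length(genes),
        statistic = length(x) * length(y) / 2, p = 1,
        stringsAsFactors = FALSE)
      next
    }
    exact <- (length(x) + length(y)) <= exact_max
    res <- suppressWarnings(
      wilcox.test(x, y, paired = paired, alternative = "two.sided",
                  exact = exact, correct = !exact))
    out[[length(out) + 1]] <- data.frame(
      grouping = nm, n_genes = length(genes),
      statistic = unname(res$statistic), p = res$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(grouping = character(), n_genes = integer(),
                      statistic = numeric(), p = numeric(), fdr = numeric()))
  }
  res <- do.call(rbind, out)
  res$fdr <- bh_adjust(res$p)
  res
}

#' Top genes by differential correlation
#'
#' @param dcor Output of [delta_cor()].
#' @param n Number of genes to report per regulator.
#' @return Data frame of the strongest differentially regulated genes.
#' @export
top_delta_cor <- function(dcor, n = 10) {
  out <- list()
  for (reg in unique(dcor$regulator)) {
    rows <- dcor[dcor$regulator == reg & !is.na(dcor$delta_cor), ]
    rows <- rows[order(-rows$delta_cor, rows$gene), ]
    out[[reg]] <- head(rows, n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
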