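# Synthetic multi-cohort multi-omic generator with planted ground truth.
#
# Generative model for gene g in sample s of group G:
#   expr(g,s) = mu_g + Delta_g * 1[G == TNBC]
#             + alpha_g * cna(g,s) + beta_g * dm(g,s)
#             + sum_t w[t,g,G] * tf(t,s) + eps,   eps ~ N(0, noise_sd^2)
# DM beta values are logistic-transformed Gaussians (always in [0,1]); CNA
# values are Normal copy ratios with a TNBC-specific location shift for
# CNA-driven genes so that copy number carries group information.  DM acts
# negatively on expression (beta_g < 0) for DM-driven genes, matching the
# expectation that promoter methylation silences transcription.

#' Build a simulation configuration
#'
#' Defines the study conditions for the synthetic multi-omic cohorts: three
#' independent cohorts sharing one planted truth (differential genes, an
#' up-regulated pathway, CNA- and DM-driven genes, and group-specific TF
#' edges), emulating a discovery cohort plus two validation cohorts.
#'
#' @param n_genes Number of glycogenes in the catalog.
#' @param n_tfs Number of transcription factors.
#' @param n_per_group Samples per group (TNBC / non-TNBC / normal) per cohort.
#' @param n_cohorts Number of independent cohorts (default 3).
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param de_effect Planted log2 fold change for DE genes (TNBC vs others).
#' @param pathways List of planted pathway definitions, each a list with
#'   `name`, `genes` (indices or symbols), `direction` (`"up"`/`"down"`) and
#'   `effect` (log2FC added to member genes in TNBC).
#' @param n_null_sets Number of additional random (null) gene sets.
#' @param null_set_size Member count for each null set.
#' @param cna_driven Gene indices/symbols whose expression is CNA-coupled.
#' @param cna_alpha Coupling coefficient alpha (per unit copy ratio).
#' @param dm_driven Gene indices/symbols whose expression is DM-coupled.
#' @param dm_beta Coupling coefficient beta; must be negative (methylation
#'   represses expression).
#' @param tf_edges Data frame with columns `tf`, `gene`, `group`, `w`
#'   describing group-specific TF regulation (group `"both"` applies the
#'   weight in TNBC and non-TNBC).  `NULL` for none.
#' @param noise_sd Residual standard deviation of expression noise.
#' @param anabolic_fraction Fraction of catalog genes flagged
#'   anabolic/catabolic.
#' @param seed Base seed; all generated layers are deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 120, n_tfs = 25, n_per_group = 100,
                              n_cohorts = 3, de_fraction = 0.1,
                              de_effect = 2, pathways = NULL,
                              n_null_sets = 20, null_set_size = 8,
                              cna_driven = integer(), cna_alpha = 1,
                              dm_driven = integer(), dm_beta = -4,
                              tf_edges = NULL, noise_sd = 1,
                              anabolic_fraction = 0.7, seed = 1) {
  stopifnot(n_genes > 0, n_tfs > 0, n_per_group > 0, n_cohorts > 0,
            is.finite(de_effect), noise_sd >= 0,
            de_fraction >= 0, de_fraction <= 1)
  if (length(dm_driven) && dm_beta >= 0) {
    abort("dm_beta must be negative: methylation represses expression")
  }
  n_de <- round(de_fraction * n_genes)
  if (length(cna_driven) > n_genes || length(dm_driven) > n_genes ||
      n_de > n_genes) {
    abort("more driven genes requested than n_genes = %d", n_genes)
  }
  cfg <- list(n_genes = n_genes, n_tfs = n_tfs, n_per_group = n_per_group,
              n_cohorts = n_cohorts, de_fraction = de_fraction,
              de_effect = de_effect, pathways = pathways,
              n_null_sets = n_null_sets, null_set_size = null_set_size,
              cna_driven = cna_driven, cna_alpha = cna_alpha,
              dm_driven = dm_driven, dm_beta = dm_beta,
              tf_edges = tf_edges, noise_sd = noise_sd,
              anabolic_fraction = anabolic_fraction, seed = seed)
  class(cfg) <- "simulation_config"
  cfg
}

gene_names <- function(n) sprintf("G%03d", seq_len(n))
tf_names <- function(n) sprintf("TF%02d", seq_len(n))

resolve_genes <- function(x, genes) {
  if (is.numeric(x)) return(genes[as.integer(x)])
  x <- as.character(x)
  miss <- setdiff(x, genes)
  if (length(miss)) abort("unknown gene in config: %s", miss[1])
  x
}

#' Simulate multi-omic cohorts with planted truth
#'
#' Generates `n_cohorts` independent cohorts sharing the same planted truth:
#' per cohort an expression matrix, a CNA copy-ratio matrix, a methylation
#' beta matrix, a TF expression matrix and a sample table; plus a shared
#' gene catalog, gene-set collection, TSS table and ChIP peak set.
#'
#' @param config A [simulation_config()].
#' @return List with elements `cohorts` (list of cohort lists), `truth`
#'   (planted DE genes with directions, enriched pathways, CNA-/DM-driven
#'   sets, per-group TF edges), `catalog`, `gene_sets`, `tss`, `peaks`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- gene_names(config$n_genes)
  tfs <- tf_names(config$n_tfs)

  set.seed(child_seed(config$seed, "truth"))
  n_de <- round(config$de_fraction * config$n_genes)
  de_genes <- if (n_de) sort(sample(genes, n_de)) else character()
  de_dir <- if (n_de) {
    stats::setNames(sample(c("up", "down"), n_de, replace = TRUE), de_genes)
  } else stats::setNames(character(), character())
  delta <- stats::setNames(rep(0, config$n_genes), genes)
  delta[de_genes] <- ifelse(de_dir == "up", config$de_effect,
                            -config$de_effect)

  # planted pathways add their effect on top for member genes
  pw <- lapply(config$pathways, function(p) {
    list(name = p$name, genes = resolve_genes(p$genes, genes),
         direction = p$direction,
         effect = if (is.null(p$effect)) config$de_effect else p$effect)
  })
  for (p in pw) {
    delta[p$genes] <- delta[p$genes] +
      ifelse(p$direction == "up", p$effect, -p$effect)
  }

  cna_driven <- resolve_genes(config$cna_driven, genes)
  dm_driven <- resolve_genes(config$dm_driven, genes)
  alpha <- stats::setNames(rep(0, config$n_genes), genes)
  alpha[cna_driven] <- config$cna_alpha
  beta <- stats::setNames(rep(0, config$n_genes), genes)
  beta[dm_driven] <- config$dm_beta

  edges <- config$tf_edges
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), gene = character(),
                        group = character(), w = numeric())
  }
  edges$gene <- resolve_genes(edges$gene, genes)
  bad_tf <- setdiff(edges$tf, tfs)
  if (length(bad_tf)) abort("unknown TF in config edges: %s", bad_tf[1])

  mu <- stats::setNames(rnorm(config$n_genes, mean = 8, sd = 1), genes)
  catalog_flags <- runif(config$n_genes) < config$anabolic_fraction
  pathway_lists <- lapply(genes, function(g) {
    unlist(lapply(pw, function(p) if (g %in% p$genes) p$name else NULL))
  })
  pathway_lists <- lapply(pathway_lists, function(x) {
    if (is.null(x)) character() else x
  })
  catalog <- gene_catalog(genes, pathway_lists, catalog_flags)

  # gene-set collection: planted pathways + random null sets
  sets <- lapply(pw, `[[`, "genes")
  names(sets) <- vapply(pw, `[[`, character(1), "name")
  if (config$n_null_sets > 0) {
    null_sets <- lapply(seq_len(config$n_null_sets), function(i) {
      sample(genes, min(config$null_set_size, config$n_genes))
    })
    names(null_sets) <- sprintf("null_set_%02d", seq_len(config$n_null_sets))
    sets <- c(sets, null_sets)
  }
  collection <- if (length(sets)) gene_sets(sets) else NULL

  # toy contig: genes every 10 kb on chr1
  tss <- tss_table(genes, "chr1", 5000L + 10000L * (seq_along(genes) - 1L),
                   rep(c("+", "-"), length.out = length(genes)))

  truth <- list(de_genes = de_genes, de_directions = de_dir, delta = delta,
                enriched_pathways = stats::setNames(
                  vapply(pw, `[[`, character(1), "direction"),
                  vapply(pw, `[[`, character(1), "name")),
                cna_driven = cna_driven, dm_driven = dm_driven,
                tf_edges = edges)

  groups_per_sample <- rep(SAMPLE_GROUPS, each = config$n_per_group)
  cohorts <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    set.seed(child_seed(config$seed, "cohort", k))
    ds <- sprintf("cohort%d", k)
    n_samp <- length(groups_per_sample)
    ids <- sprintf("%s_S%03d", ds, seq_len(n_samp))
    samples <- sample_table(ids, groups_per_sample, ds)

    tf_expr <- matrix(rnorm(config$n_tfs * n_samp), nrow = config$n_tfs,
                      dimnames = list(tfs, ids))

    cna <- matrix(rnorm(config$n_genes * n_samp, sd = 0.3),
                  nrow = config$n_genes, dimnames = list(genes, ids))
    is_tnbc <- groups_per_sample == "TNBC"
    # CNA-driven genes gain copies specifically in TNBC
    cna[cna_driven, is_tnbc] <- cna[cna_driven, is_tnbc] + 0.5

    dm_raw <- matrix(rnorm(config$n_genes * n_samp, sd = 1),
                     nrow = config$n_genes, dimnames = list(genes, ids))
    dm_raw[dm_driven, is_tnbc] <- dm_raw[dm_driven, is_tnbc] - 1
    dm <- plogis(dm_raw)

    expr <- matrix(mu, nrow = config$n_genes, ncol = n_samp,
                   dimnames = list(genes, ids))
    expr <- expr + delta %o% as.numeric(is_tnbc)
    expr <- expr + alpha * cna + beta * dm
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        grp <- edges$group[e]
        in_grp <- if (grp == "both") {
          groups_per_sample %in% c("TNBC", "non-TNBC")
        } else groups_per_sample == grp
        expr[edges$gene[e], in_grp] <- expr[edges$gene[e], in_grp] +
          edges$w[e] * tf_expr[edges$tf[e], in_grp]
      }
    }
    if (config$noise_sd > 0) {
      expr <- expr + matrix(rnorm(config$n_genes * n_samp,
                                  sd = config$noise_sd),
                            nrow = config$n_genes)
    }
    cohorts[[k]] <- list(
      expression = expression_matrix(expr, ds),
      cna = expression_matrix(cna, ds),
      dm = expression_matrix(dm, ds),
      tf_expression = expression_matrix(tf_expr, ds),
      samples = samples, dataset_id = ds)
  }

  peaks <- make_binding_peaks(truth, tss, decoy_rate = 0.5,
                              tf_universe = tfs,
                              seed = child_seed(config$seed, "peaks"))
  list(cohorts = cohorts, truth = truth, catalog = catalog,
       gene_sets = collection, tss = tss, peaks = peaks)
}

#' Generate ChIP-evidence peaks for planted TF edges plus decoys
#'
#' Every true TF-gene edge receives at least one peak whose midpoint lies
#' within 2 kb of the target gene's TSS, so that ChIP annotation recovers
#' the regulatory search space.  Decoy peaks are added both inside promoter
#' windows of non-target genes (non-functional binding) and far outside any
#' window.
#'
#' @param truth Truth record with a `tf_edges` data frame (`tf`, `gene`).
#' @param tss A `tss_table` covering every target gene.
#' @param decoy_rate Expected number of decoy peaks per true edge (>= 0).
#' @param tf_universe TFs eligible to emit decoy peaks; defaults to the TFs
#'   present in `truth$tf_edges`.
#' @param seed RNG seed.
#' @return A `genomic_intervals` peak set.
#' @export
make_binding_peaks <- function(truth, tss, decoy_rate = 0.5,
                               tf_universe = NULL, seed = 1) {
  edges <- unique(truth$tf_edges[, c("tf", "gene")])
  miss <- setdiff(edges$gene, tss$gene_symbol)
  if (length(miss)) abort("gene absent from TSS table: %s", miss[1])
  if (is.null(tf_universe)) tf_universe <- unique(edges$tf)
  set.seed(seed)
  tss_of <- stats::setNames(tss$tss, tss$gene_symbol)
  width <- 200L
  rec <- list()
  for (e in seq_len(nrow(edges))) {
    # midpoint within +/- 2000 of the TSS by construction
    mid <- tss_of[edges$gene[e]] + sample(-1800:1800, 1)
    rec[[length(rec) + 1]] <- data.frame(
      chrom = tss$chrom[match(edges$gene[e], tss$gene_symbol)],
      start = as.integer(mid - width / 2), end = as.integer(mid + width / 2),
      tf = edges$tf[e], stringsAsFactors = FALSE)
  }
  n_decoy <- round(decoy_rate * max(nrow(edges), 1))
  if (n_decoy > 0 && length(tf_universe)) {
    for (i in seq_len(n_decoy)) {
      tf <- sample(tf_universe, 1)
      if (runif(1) < 0.5) {
        # inside a random gene's promoter window: non-functional binding
        g <- sample(tss$gene_symbol, 1)
        mid <- tss_of[g] + sample(-1800:1800, 1)
        chrom <- tss$chrom[match(g, tss$gene_symbol)]
      } else {
        # intergenic, outside every +/-2 kb window (genes are 10 kb apart)
        g <- sample(tss$gene_symbol, 1)
        mid <- tss_of[g] + sample(c(-3500:-2500, 2500:3500), 1)
        chrom <- tss$chrom[match(g, tss$gene_symbol)]
      }
      rec[[length(rec) + 1]] <- data.frame(
        chrom = chrom, start = as.integer(mid - width / 2),
        end = as.integer(mid + width / 2), tf = tf, stringsAsFactors = FALSE)
    }
  }
  if (!length(rec)) {
    return(genomic_intervals(character(), integer(), integer(), character()))
  }
  df <- do.call(rbind, rec)
  genomic_intervals(df$chrom, df$start, df$end, df$tf)
}
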