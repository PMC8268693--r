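# Criterion combination and phase-A orchestration.  The final candidate set
# is the union of the three selection criteria intersected with the
# anabolic/catabolic catalog flag (criterion four); the pipeline runs
# simulation (or loading), differential expression, enrichment, the network
# predictor and the combination, writing every intermediate with a manifest.

#' Combine the four selection criteria into a candidate report
#'
#' `final = (c1 u c2 u c3) n {genes flagged anabolic/catabolic}`.
#'
#' @param c1_genes,c2_genes,c3_genes Gene vectors from criteria 1-3 (named
#'   direction vectors accepted; names are used).
#' @param catalog A `gene_catalog` covering every listed gene.
#' @param directions Optional named direction vector (e.g. the
#'   cross-dataset DE directions) to annotate the report.
#' @return A `candidate_report` data frame with per-gene criterion flags
#'   `c1`..`c4`, `direction`, `pathways` and `final_selected`.
#' @export
apply_criteria <- function(c1_genes, c2_genes, c3_genes, catalog,
                           directions = NULL) {
  as_genes <- function(x) if (!is.null(names(x))) names(x) else as.character(x)
  c1 <- as_genes(c1_genes); c2 <- as_genes(c2_genes); c3 <- as_genes(c3_genes)
  all_genes <- sort(unique(c(c1, c2, c3)))
  miss <- setdiff(all_genes, catalog$gene_symbol)
  if (length(miss)) abort("gene absent from catalog: %s", miss[1])
  ci <- match(all_genes, catalog$gene_symbol)
  flag4 <- catalog$is_anabolic_or_catabolic[ci]
  dir <- if (is.null(directions)) rep(NA_character_, length(all_genes)) else
    unname(directions[all_genes])
  out <- data.frame(
    gene = all_genes,
    c1 = all_genes %in% c1, c2 = all_genes %in% c2, c3 = all_genes %in% c3,
    c4 = flag4, direction = dir,
    pathways = vapply(catalog$pathways[ci], paste, character(1),
                      collapse = ";"),
    stringsAsFactors = FALSE)
  out$final_selected <- out$c4 & (out$c1 | out$c2 | out$c3)
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Selected candidates of a report
#' @param report A `candidate_report`.
#' @return Character vector of finally selected genes.
#' @export
candidate_genes <- function(report) report$gene[report$final_selected]

#' Run the full candidate-discovery pipeline on simulated cohorts
#'
#' Orchestrates phase A end to end: cohort simulation, per-dataset
#' two-contrast moderated-t differential expression, direction-concordance
#' filtering and cross-dataset intersection with top-50% selection
#' (criterion 1), ensemble enrichment and concordant-member extraction
#' (criterion 2), graph-regularized repeated classification models
#' (criterion 3), and the catalog filter (criterion 4).  Every stage output
#' is written under `out_dir` and listed in `manifest.json`.
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed).
#' @param fdr_threshold FDR cut for DE and enrichment significance.
#' @param n_models Repeated classification models per dataset.
#' @return Invisibly, a list with `report`, `c1`, `c2`, `c3`, `de_tables`,
#'   `enrichment`, `summaries`, `sim`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("glycoreg_run_"),
                         fdr_threshold = 0.05, n_models = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) file.path(out_dir, name)
  manifest <- list()
  note <- function(stage_name, path) {
    manifest[[stage_name]] <<- basename(path)
  }

  sim <- tryCatch(simulate_cohorts(config),
                  error = function(e) abort("stage simulate: %s",
                                            conditionMessage(e)))
  for (k in seq_along(sim$cohorts)) {
    write_expression_matrix(sim$cohorts[[k]]$expression,
                            stage(sprintf("expression_cohort%d.tsv", k)))
  }
  note("simulate", stage("expression_cohort1.tsv"))

  de_tables <- lapply(sim$cohorts, function(co) {
    tryCatch(run_de(co$expression, co$samples),
             error = function(e) abort("stage de: %s", conditionMessage(e)))
  })
  de_all <- do.call(rbind, lapply(de_tables, as.data.frame))
  write.table(de_all, stage("de_tables.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("de", stage("de_tables.tsv"))

  per_ds <- lapply(de_tables, concordant_de, fdr_threshold = fdr_threshold)
  common <- cross_dataset_intersection(per_ds)
  c1 <- if (length(common)) top_half(common, de_tables) else character()
  writeLines(c1, stage("criterion1_genes.txt"))
  note("criterion1", stage("criterion1_genes.txt"))

  enrichment <- tryCatch(run_enrichment(de_tables, sim$gene_sets),
                         error = function(e) abort("stage enrich: %s",
                                                   conditionMessage(e)))
  write.table(enrichment, stage("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("enrich", stage("enrichment.tsv"))

  enriched <- concordant_enriched_sets(enrichment, fdr = fdr_threshold)
  # restrict to catalog pathways (glycosylation sets), not null filler sets
  glyco_sets <- enriched[names(enriched) %in%
                           unique(unlist(sim$catalog$pathways))]
  c2 <- criterion2_genes(glyco_sets, sim$gene_sets, de_tables)
  writeLines(c2, stage("criterion2_genes.txt"))
  note("criterion2", stage("criterion2_genes.txt"))

  graph_sets <- sim$gene_sets[names(enriched)]
  summaries <- NULL
  c3 <- character()
  if (length(graph_sets)) {
    graph <- build_graph(graph_sets)
    summaries <- lapply(seq_along(sim$cohorts), function(k) {
      co <- sim$cohorts[[k]]
      tryCatch(
        repeated_models(co$expression, co$samples, graph,
                        n_models = n_models,
                        seed = child_seed(config$seed, "models", k)),
        error = function(e) abort("stage predict: %s", conditionMessage(e)))
    })
    sel <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(dataset_id = s$dataset_id, gene = names(s$counts),
                 times_selected = as.integer(s$counts),
                 stringsAsFactors = FALSE)
    }))
    write.table(sel, stage("selection_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    c3 <- predictive_gene_rule(summaries)
  } else {
    write.table(data.frame(dataset_id = character(), gene = character(),
                           times_selected = integer()),
                stage("selection_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  note("predict", stage("selection_summary.tsv"))

  report <- apply_criteria(c1, c2, c3, sim$catalog, directions = common)
  write.table(report, stage("candidates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("select", stage("candidates.tsv"))

  jsonlite::write_json(manifest, stage("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(report = report, c1 = c1, c2 = c2, c3 = c3,
                 de_tables = de_tables, enrichment = enrichment,
                 summaries = summaries, sim = sim, manifest = manifest,
                 out_dir = out_dir))
}
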