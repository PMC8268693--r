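# Readers, writers and the shared data model: expression/CNA/DM matrices as
# genes x samples TSV, gene sets as GMT, ChIP peaks as BED4, TSS tables and
# bipartite networks as TSV edge lists.  All genomic coordinates are 0-based
# half-open (BED convention); gene identifiers are case-sensitive symbols.

#' Construct a gene catalog
#'
#' The catalog declares the analysis universe of glycosylation-related genes
#' ("glycogenes"), the biosynthetic/degradative pathway(s) each belongs to,
#' and whether the gene has an anabolic or catabolic function.  The final
#' candidate-selection criterion retains anabolic/catabolic genes only.
#'
#' @param gene_symbol Character vector of unique gene symbols.
#' @param pathways List of character vectors, one per gene (possibly empty),
#'   naming the pathways the gene belongs to.
#' @param is_anabolic_or_catabolic Logical vector, one flag per gene.
#' @return A `gene_catalog` data frame with a list-column `pathways`.
#' @export
gene_catalog <- function(gene_symbol, pathways = NULL,
                         is_anabolic_or_catabolic = TRUE) {
  gene_symbol <- as.character(gene_symbol)
  if (anyDuplicated(gene_symbol)) {
    abort("duplicate gene symbol in catalog: %s",
          gene_symbol[duplicated(gene_symbol)][1])
  }
  n <- length(gene_symbol)
  if (is.null(pathways)) pathways <- rep(list(character()), n)
  if (!is.list(pathways) || length(pathways) != n) {
    abort("'pathways' must be a list with one entry per gene")
  }
  pathways <- lapply(pathways, as.character)
  if (any(vapply(pathways, function(p) any(!nzchar(p)), logical(1)))) {
    abort("empty pathway name in catalog")
  }
  flag <- rep_len(as.logical(is_anabolic_or_catabolic), n)
  out <- data.frame(gene_symbol = gene_symbol, stringsAsFactors = FALSE)
  out$pathways <- pathways
  out$is_anabolic_or_catabolic <- flag
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Construct a validated expression (or CNA/DM) matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample IDs).  `NA` marks missing cells.
#' @param dataset_id Dataset identifier carried as an attribute.
#' @return The matrix with unique dimnames and a `dataset_id` attribute.
#' @export
expression_matrix <- function(values, dataset_id = "dataset") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix requires gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene symbol: %s",
          rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample ID: %s",
          colnames(values)[duplicated(colnames(values))][1])
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) abort("non-finite (infinite) expression value")
  attr(values, "dataset_id") <- as.character(dataset_id)
  values
}

#' Construct a sample table
#'
#' @param sample_id Character vector of sample IDs.
#' @param group Group label per sample; one of `"TNBC"`, `"non-TNBC"`,
#'   `"normal"`.
#' @param dataset_id Dataset identifier (scalar or per sample).
#' @return A `sample_table` data frame.
#' @export
sample_table <- function(sample_id, group, dataset_id = "dataset") {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (anyDuplicated(sample_id)) {
    abort("duplicate sample ID: %s", sample_id[duplicated(sample_id)][1])
  }
  bad <- setdiff(unique(group), SAMPLE_GROUPS)
  if (length(bad)) {
    abort("unknown sample group '%s'; allowed: %s", bad[1],
          paste(SAMPLE_GROUPS, collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id, group = group,
                    dataset_id = rep_len(as.character(dataset_id),
                                         length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Read a genes-by-samples matrix from TSV
#'
#' Expects a header row of sample IDs and gene symbols in the first column.
#' Cells that are empty or `NA` are kept as missing values, never coerced to
#' zero.  Used for log2 expression, gene-level copy-ratio (CNA) and
#' methylation beta matrices alike.
#'
#' @param path Path to the TSV file.
#' @param dataset_id Dataset identifier to attach.
#' @return A validated matrix as from [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dataset_id = "dataset") {
  lines <- readLines(path)
  if (!length(lines)) abort("empty matrix file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != width)
  if (length(ragged)) {
    abort("ragged row in %s at line %d (expected %d fields)",
          path, ragged[1], width)
  }
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  genes <- vapply(body, `[[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    cell <- body[[i]][-1]
    cell[cell %in% c("NA", "")] <- NA
    vals[i, ] <- suppressWarnings(as.numeric(cell))
  }
  expression_matrix(vals, dataset_id = dataset_id)
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param mat Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table from TSV
#'
#' Columns: `sample_id`, `group`, `dataset_id`.
#' @param path Path to the TSV file.
#' @return A `sample_table` data frame.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "dataset_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("sample table missing column(s): %s",
                          paste(miss, collapse = ", "))
  sample_table(df$sample_id, df$group, df$dataset_id)
}

#' Write a sample table as TSV
#' @param samples A `sample_table`.
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line — name, description, then member genes,
#' tab-separated.  Descriptions are preserved as an attribute but unused.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (class `gene_sets`), with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short)) {
    abort("GMT line %d has no member genes", short[1])
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort("duplicate gene-set name: %s", names_[duplicated(names_)][1])
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  gene_sets(sets, descriptions = desc)
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of descriptions.
#' @return The validated collection (class `gene_sets`).
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set needs a non-empty name")
  }
  if (anyDuplicated(names(sets))) {
    abort("duplicate gene-set name: %s",
          names(sets)[duplicated(names(sets))][1])
  }
  if (any(lengths(sets) == 0)) {
    abort("empty member list for set '%s'", names(sets)[lengths(sets) == 0][1])
  }
  sets <- lapply(sets, as.character)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "descriptions") <- descriptions
  class(sets) <- "gene_sets"
  sets
}

#' Write gene sets to a GMT file
#' @param sets A `gene_sets` collection (or plain named list).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read TF ChIP peaks from a BED4 file
#'
#' BED coordinates are 0-based half-open; the name column carries the TF.
#'
#' @param path Path to the BED file.
#' @return A `genomic_intervals` data frame with columns `chrom`, `start`,
#'   `end`, `tf`.
#' @export
read_peaks <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) abort("BED4 required: chrom, start, end, name(TF)")
  genomic_intervals(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' Construct a genomic interval set (0-based half-open)
#' @param chrom,start,end,tf Record fields.
#' @return A `genomic_intervals` data frame.
#' @export
genomic_intervals <- function(chrom, start, end, tf) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  bad <- which(start >= end)
  if (length(bad)) {
    abort("interval record %d has start >= end (%d >= %d)",
          bad[1], start[bad[1]], end[bad[1]])
  }
  if (any(!nzchar(chrom))) abort("empty chromosome name")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    tf = as.character(tf), stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write peaks as BED4
#' @param peaks A `genomic_intervals` data frame.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end", "tf")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcription start site table
#'
#' TSV columns: `gene_symbol`, `chrom`, `tss` (0-based position), `strand`
#' (`+` or `-`).
#'
#' @param path Path to the TSV file.
#' @return A `tss_table` data frame.
#' @export
read_tss <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("TSS table missing column(s): %s",
                          paste(miss, collapse = ", "))
  tss_table(df$gene_symbol, df$chrom, df$tss, df$strand)
}

#' Construct a TSS table
#' @param gene_symbol,chrom,tss,strand Per-gene fields; `tss` is 0-based.
#' @return A `tss_table` data frame.
#' @export
tss_table <- function(gene_symbol, chrom, tss, strand) {
  strand <- as.character(strand)
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad)) {
    abort("invalid strand '%s'; allowed strands: +, -", bad[1])
  }
  gene_symbol <- as.character(gene_symbol)
  if (anyDuplicated(gene_symbol)) {
    abort("duplicate TSS row for gene %s",
          gene_symbol[duplicated(gene_symbol)][1])
  }
  out <- data.frame(gene_symbol = gene_symbol, chrom = as.character(chrom),
                    tss = as.integer(tss), strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("tss_table", "data.frame")
  out
}

#' Write a TSS table as TSV
#' @param tss A `tss_table`.
#' @param path Output path.
#' @export
write_tss <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a TF-gene bipartite network
#'
#' Edges connect transcription factors to target genes, each annotated with
#' the stability-selection frequency that produced it.
#'
#' @param tf,gene Edge endpoints (character vectors of equal length).
#' @param frequency Selection frequency per edge, in `[0, 1]`.
#' @param group Group label of the network (e.g. `"TNBC"`).
#' @return A `bipartite_network` object.
#' @export
bipartite_network <- function(tf = character(), gene = character(),
                              frequency = numeric(), group = "all") {
  edges <- data.frame(tf = as.character(tf), gene = as.character(gene),
                      frequency = as.numeric(frequency),
                      stringsAsFactors = FALSE)
  key <- paste(edges$tf, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate edge %s -> %s", edges$tf[duplicated(key)][1],
          edges$gene[duplicated(key)][1])
  }
  if (nrow(edges) && any(edges$frequency < 0 | edges$frequency > 1)) {
    abort("selection frequency outside [0, 1]")
  }
  structure(list(edges = edges, group = as.character(group)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite TF-gene network [%s]: %d edges, %d TFs, %d genes\n",
              x$group, nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$gene))))
  invisible(x)
}

#' Write a bipartite network as a TSV edge list
#'
#' Columns: `tf`, `gene`, `frequency`, `group`.  [read_edge_list()] restores
#' the identical edge set.
#'
#' @param network A `bipartite_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  df <- network$edges
  df$group <- rep_len(network$group, nrow(df))
  if (!nrow(df)) {
    df <- data.frame(tf = character(), gene = character(),
                     frequency = numeric(), group = character())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bipartite network from a TSV edge list
#' @param path Path written by [write_edge_list()].
#' @return A `bipartite_network`.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(tf = "character", gene = "character"))
  group <- if (nrow(df)) unique(df$group)[1] else "all"
  bipartite_network(df$tf, df$gene, df$frequency, group = group)
}
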