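#' Read an abundance table from TSV
#'
#' Canonical layout is MetaPhlAn merged-table style: first column holds taxon
#' identifiers, remaining columns are samples (`taxa_by_samples`). The
#' transposed layout (`samples_by_taxa`: first column sample ids, remaining
#' columns taxa) yields an identical in-memory table.
#'
#' @param path TSV file of abundances ('.' decimal, UTF-8, header row)
#' @param metadata_path TSV with columns `sample_id`, `subject_id`,
#'   `cohort_id`, `timepoint`, `day` and optionally `group`
#' @param layout `"taxa_by_samples"` (default) or `"samples_by_taxa"`
#' @param normalize renormalize sample columns to sum 1 (default TRUE)
#' @return an [abundance_table()]
#' @export
read_abundance_table <- function(path, metadata_path,
                                 layout = c("taxa_by_samples", "samples_by_taxa"),
                                 normalize = TRUE) {
  layout <- match.arg(layout)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("abundance TSV needs an id column plus data columns")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (layout == "samples_by_taxa") m <- t(m)
  metadata <- read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  abundance_table(m, metadata, normalize = normalize)
}

#' Write an abundance table (and its metadata) to TSV
#'
#' @param table an [abundance_table()]
#' @param path abundance TSV path (taxa-by-samples layout, id column `taxon`)
#' @param metadata_path optional metadata TSV path
#' @return invisibly, `path`
#' @export
write_abundance_table <- function(table, path, metadata_path = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(taxon = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read a gene-content matrix from TSV
#'
#' @param path TSV, first column taxon identifiers, remaining columns gene
#'   families
#' @return a [gene_content()]
#' @export
read_gene_content <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  gene_content(m)
}

#' Write a gene-content matrix to TSV
#' @param gcn a [gene_content()]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_gene_content <- function(gcn, path) {
  stopifnot(inherits(gcn, "gene_content"))
  df <- data.frame(taxon = rownames(gcn$values), gcn$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network to GraphML
#'
#' Nodes carry a `degree` attribute; edges carry `rho` and `p_value`.
#' Re-reading with [read_conet_graphml()] reproduces node and edge sets and
#' attribute values exactly.
#'
#' @param network a `conet` object from [build_conet()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "conet"))
  g <- network$graph
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a co-occurrence network from GraphML
#' @param path GraphML file written by [write_graphml()]
#' @return a `conet` object
#' @export
read_conet_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id))
    igraph::V(g)$name <- igraph::V(g)$id
  structure(list(graph = g), class = "conet")
}

#' Export a co-occurrence network as an edge-list TSV
#'
#' Columns: `source`, `target`, `rho`, `p`.
#'
#' @inheritParams write_graphml
#' @return invisibly, `path`
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "conet"))
  g <- network$graph
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   rho = if (igraph::ecount(g)) igraph::E(g)$rho else numeric(0),
                   p = if (igraph::ecount(g)) igraph::E(g)$p_value else numeric(0))
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
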