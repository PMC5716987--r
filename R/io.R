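## io_formats: readers and writers for the formats the pipeline touches.
## OTU tables and metadata are TSV, trees are Newick, networks are GraphML
## plus a mirrored TSV edge list. No science lives here.

#' Validate an OTU count matrix
#'
#' Canonical orientation is samples as rows, OTUs as columns. Counts must be
#' non-negative integers; sample and OTU identifiers must be unique; at
#' least one sample and two OTUs are required for downstream phylogenetic
#' metrics.
#'
#' @param counts numeric matrix.
#' @return the validated integer matrix (invisibly the same object).
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts)) stopf("OTU table must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("OTU table must carry sample (row) and OTU (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate OTU identifiers: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts)) stopf("counts must be numeric and non-missing")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be integers")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stopf("need at least 1 sample and 2 OTUs")
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table from TSV
#'
#' @param path file path. Tab-separated with a header row; the first column
#'   holds identifiers.
#' @param samples_as_rows logical flag stating the orientation on disk
#'   (`TRUE`: first column is the sample id; `FALSE`: first column is the
#'   OTU id and the table is transposed on read). Orientation is never
#'   guessed from the data.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, samples_as_rows = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stopf("malformed OTU table: fewer than 2 columns in %s", path)
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  if (anyDuplicated(names(body)))
    stopf("duplicate column identifiers in %s", path)
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (anyNA(num)) stopf("non-numeric counts in %s", path)
  m <- matrix(num, nrow = nrow(raw),
              dimnames = list(ids, names(body)))
  if (!samples_as_rows) m <- t(m)
  validate_otu_table(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts samples x OTUs integer matrix.
#' @param path output path.
#' @param samples_as_rows orientation on disk; see [read_otu_table()].
#' @param id_column name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path, samples_as_rows = TRUE,
                            id_column = if (samples_as_rows) "sample_id" else "otu_id") {
  m <- if (samples_as_rows) counts else t(counts)
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `group`, and any number of numeric
#' covariates (e.g. pH, SOC, TN, AP, AK, Ivt, MC, yield).
#'
#' @param path file path.
#' @param otu_table optional OTU matrix; if given, every sample in the table
#'   must have a metadata row.
#' @return data.frame with character `sample_id`, character `group`, and
#'   numeric covariate columns.
#' @export
read_sample_metadata <- function(path, otu_table = NULL) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md)))
    stopf("metadata must contain 'sample_id' and 'group' columns")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample_id in metadata")
  if (!is.null(otu_table)) {
    missing <- setdiff(rownames(otu_table), md$sample_id)
    if (length(missing))
      stopf("samples missing from metadata: %s", paste(missing, collapse = ", "))
  }
  md
}

#' Write sample metadata to TSV
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Quoted labels are supported; internal node labels are ignored. Missing
#' branch lengths default to 0 with a warning.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_tree_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stopf("could not parse Newick file %s", path)
  if (anyDuplicated(tree$tip.label)) stopf("duplicate tip labels in %s", path)
  n_edge <- nrow(tree$edge) %||% 0L
  if (is.null(tree$edge.length) && n_edge > 0L) {
    warnf("tree in %s has no branch lengths; defaulting to 0", path)
    tree$edge.length <- rep(0, n_edge)
  } else if (!is.null(tree$edge.length) && anyNA(tree$edge.length)) {
    warnf("missing branch lengths in %s set to 0", path)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree$node.label <- NULL
  tree
}

#' Write a tree to Newick
#' @param tree `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a co-occurrence network to GraphML
#'
#' Nodes carry `otu_id` (the vertex name), `degree`, and `phylum` when
#' present; edges carry `rho`, `p` and `sign`. The file is readable by
#' Gephi and by [read_network_graphml()].
#'
#' @param network an igraph graph as built by [build_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- network
  igraph::V(g)$otu_id <- igraph::V(g)$name
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back into igraph
#' @param path GraphML file.
#' @return igraph graph.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::vertex_attr(g, "otu_id")))
    igraph::V(g)$name <- igraph::V(g)$otu_id
  g
}

#' Write a network edge list as TSV
#'
#' Mirrors the GraphML export: columns `from`, `to`, `rho`, `p`, `sign`.
#' An empty network yields a header-only file.
#'
#' @param network igraph graph with `rho`, `p`, `sign` edge attributes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  if (igraph::ecount(network) == 0L) {
    el <- data.frame(from = character(), to = character(),
                     rho = numeric(), p = numeric(), sign = character())
  } else {
    ends <- igraph::as_edgelist(network)
    el <- data.frame(from = ends[, 1L], to = ends[, 2L],
                     rho = igraph::E(network)$rho,
                     p = igraph::E(network)$p,
                     sign = igraph::E(network)$sign,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
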