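## network_topology: thresholded co-occurrence networks and the topology
## panel (nodes, edges, degree, clustering, path length, diameter,
## modularity, cumulative degree distribution).

#' Build a co-occurrence network from SparCC results
#'
#' Undirected edges connect OTU pairs whose correlation is strong
#' (`|rho| > rho_thresh`) and significant (`p < p_thresh`) — both
#' inequalities strict. Edge sign is the sign of rho.
#'
#' @param sparcc a `sparcc_result` with `pvals` filled in, or a list with
#'   `rho` and `pvals` matrices.
#' @param rho_thresh correlation-magnitude threshold (default 0.85).
#' @param p_thresh significance threshold (default 0.01).
#' @param drop_isolated drop nodes with no edges (default TRUE).
#' @param phylum optional named vector of phylum labels per OTU, attached
#'   as a vertex attribute.
#' @return igraph graph with vertex attribute `name` (OTU id, plus
#'   `phylum` if given) and edge attributes `rho`, `p`, `sign`.
#' @export
build_network <- function(sparcc, rho_thresh = 0.85, p_thresh = 0.01,
                          drop_isolated = TRUE, phylum = NULL) {
  rho <- sparcc$rho
  p <- sparcc$pvals
  if (is.null(p)) stopf("sparcc result has no p-values; run sparcc_pvalues() first")
  stopifnot(all(dim(rho) == dim(p)))
  ids <- colnames(rho)
  keep <- abs(rho) > rho_thresh & p < p_thresh
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      rho = rho[idx], p = p[idx],
                      sign = ifelse(rho[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(phylum)) igraph::V(g)$phylum <- unname(phylum[ids])
  if (drop_isolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g
}

#' Topology metrics of a co-occurrence network
#'
#' Clustering coefficient is the mean local clustering over all nodes
#' (0 for nodes of degree < 2); average path length and diameter are taken
#' over connected vertex pairs only (the Gephi convention); modularity is
#' the best of `n_restarts` seeded Louvain runs at resolution 1. The
#' cumulative degree distribution is attached as attribute
#' `degree_distribution`.
#'
#' @param network igraph graph (edge attribute `sign` used for the
#'   positive/negative edge counts when present).
#' @param seed optional integer seed for the modularity restarts.
#' @param n_restarts Louvain restarts (default 10).
#' @return one-row data.frame of class `topology_record`: `n_nodes`,
#'   `n_edges`, `n_positive`, `n_negative`, `average_degree`,
#'   `average_clustering_coefficient`, `average_path_length`, `diameter`,
#'   `modularity`, `n_modules`, `n_components`, `flag`.
#' @export
topology_metrics <- function(network, seed = NULL, n_restarts = 10L) {
  nv <- igraph::vcount(network)
  ne <- igraph::ecount(network)
  if (nv == 0L) {
    out <- data.frame(n_nodes = 0L, n_edges = 0L, n_positive = 0L,
                      n_negative = 0L, average_degree = 0,
                      average_clustering_coefficient = 0,
                      average_path_length = 0, diameter = 0,
                      modularity = 0, n_modules = 0L, n_components = 0L,
                      flag = "empty network", stringsAsFactors = FALSE)
    attr(out, "degree_distribution") <- numeric(0)
    class(out) <- c("topology_record", class(out))
    return(out)
  }
  sgn <- igraph::edge_attr(network, "sign")
  n_pos <- if (is.null(sgn)) ne else sum(sgn == "positive")
  n_neg <- ne - n_pos
  loc <- igraph::transitivity(network, type = "local", isolates = "zero")
  avg_clust <- mean(loc)
  apl <- if (ne > 0L) igraph::mean_distance(network, unconnected = TRUE) else 0
  diam <- if (ne > 0L) igraph::diameter(network, unconnected = TRUE) else 0
  if (ne > 0L) {
    best <- NULL
    for (i in seq_len(n_restarts)) {
      cl <- with_seed_or_not(
        if (is.null(seed)) NULL else derive_seed(seed, i),
        igraph::cluster_louvain(network, resolution = 1))
      if (is.null(best) || igraph::modularity(cl) > igraph::modularity(best))
        best <- cl
    }
    q <- igraph::modularity(best)
    n_mod <- length(unique(igraph::membership(best)))
  } else {
    q <- 0
    n_mod <- nv
  }
  comp <- igraph::components(network)$no
  out <- data.frame(n_nodes = nv, n_edges = ne, n_positive = n_pos,
                    n_negative = n_neg, average_degree = 2 * ne / nv,
                    average_clustering_coefficient = avg_clust,
                    average_path_length = apl, diameter = diam,
                    modularity = q, n_modules = as.integer(n_mod),
                    n_components = as.integer(comp), flag = "",
                    stringsAsFactors = FALSE)
  deg <- igraph::degree(network)
  cd <- rev(cumsum(rev(tabulate(deg + 1L) / nv)))
  names(cd) <- seq_along(cd) - 1L
  attr(out, "degree_distribution") <- cd
  class(out) <- c("topology_record", class(out))
  out
}

#' Compare topology records across networks
#'
#' Stacks per-network topology records, sorts by a chosen metric, and
#' annotates networks with modularity above 0.4 as module-structured (the
#' conventional threshold for meaningful community structure).
#'
#' @param records named list of `topology_record`s (names become the
#'   `network` column) or a data.frame of stacked records.
#' @param by metric column to sort by (default `"n_edges"`).
#' @param decreasing sort order.
#' @return data.frame with a `network` column, the metrics, and a logical
#'   `module_structured` column.
#' @export
compare_networks <- function(records, by = "n_edges", decreasing = TRUE) {
  if (is.data.frame(records)) {
    tab <- records
  } else {
    if (length(records) < 2L) stopf("need at least 2 records to compare")
    tab <- do.call(rbind, lapply(records, as.data.frame))
    tab <- data.frame(network = names(records), tab,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!by %in% names(tab)) stopf("unknown metric '%s'", by)
  tab <- tab[order(tab[[by]], tab$network, decreasing = decreasing), , drop = FALSE]
  tab$module_structured <- tab$modularity > 0.4
  rownames(tab) <- NULL
  tab
}
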