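#' Topological importance classification of network nodes
#'
#' Computes, for every node of a simple graph, four topological metrics
#' and flags the top fraction of each:
#' \describe{
#'   \item{hub}{degree}
#'   \item{central}{betweenness centrality (unweighted)}
#'   \item{gnpn}{global network perturbation: drop in global efficiency of
#'     the graph when the node is removed (unreachable pairs contribute
#'     1/d = 0, so disconnected graphs are handled)}
#'   \item{lnpn}{local network perturbation: drop in the mean local
#'     clustering coefficient of the node's former neighbors when the
#'     node is removed}
#' }
#' For each category the top `quantile` fraction of nodes is flagged
#' (at least one node; ties at the threshold value are all included).
#'
#' @param g An `igraph` graph or `layered_network` (PPI layer used).
#' @param quantiles Named numeric vector of top fractions in (0, 1) for
#'   `hub`, `central`, `gnpn`, `lnpn`; a single number recycles to all
#'   four. Default 0.10.
#' @return data.frame of class `topology_classification` with columns
#'   `node`, the four metric values (`degree`, `betweenness`,
#'   `global_eff_delta`, `local_clust_delta`), and logical flags `hub`,
#'   `central`, `gnpn`, `lnpn`.
#' @export
classify_topology <- function(g, quantiles = 0.10) {
  if (inherits(g, "layered_network")) g <- ppi_graph(g)
  n <- igraph::vcount(g)
  if (n < 3) stop("topology classification needs >= 3 nodes")
  if (length(quantiles) == 1L)
    quantiles <- stats::setNames(rep(quantiles, 4),
                                 c("hub", "central", "gnpn", "lnpn"))
  if (any(quantiles <= 0 | quantiles >= 1)) stop("quantiles must lie in (0, 1)")

  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)

  eff0 <- global_efficiency_safe(g)
  clus0 <- local_clustering(g)
  gd <- numeric(n); ld <- numeric(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_len(n)) {
    gi <- igraph::delete_vertices(g, i)
    gd[i] <- eff0 - global_efficiency_safe(gi)
    nb <- ids[as.integer(adj[[i]])]
    if (length(nb)) {
      clus1 <- local_clustering(gi)
      ld[i] <- mean(clus0[nb]) - mean(clus1[nb])
    }
  }

  top_flag <- function(x, q) {
    k <- max(1L, floor(q * length(x)))
    thr <- sort(x, decreasing = TRUE)[k]
    x >= thr
  }
  out <- data.frame(node = ids, degree = deg, betweenness = btw,
                    global_eff_delta = gd, local_clust_delta = ld,
                    hub = top_flag(deg, quantiles[["hub"]]),
                    central = top_flag(btw, quantiles[["central"]]),
                    gnpn = top_flag(gd, quantiles[["gnpn"]]),
                    lnpn = top_flag(ld, quantiles[["lnpn"]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("topology_classification", "data.frame")
  out
}

# Mean of 1/shortest-path-distance over ordered pairs; unreachable -> 0.
global_efficiency_safe <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# Per-node local clustering coefficient; degree < 2 counts as 0.
local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  stats::setNames(cc, igraph::V(g)$name)
}

#' Select important interacting nodes (IINs)
#'
#' A node is an IIN when it is topologically important in at least
#' `min_categories` of the four categories (hub, central, GNPN, LNPN).
#'
#' @param cls A `topology_classification` from [classify_topology()].
#' @param min_categories Minimum number of true flags (default 2).
#' @return Character vector of IIN node ids.
#' @export
select_iins <- function(cls, min_categories = 2) {
  stopifnot(inherits(cls, "topology_classification"))
  nflag <- rowSums(cls[, c("hub", "central", "gnpn", "lnpn")])
  cls$node[nflag >= min_categories]
}

#' Write the topology report as TSV
#' @param cls A `topology_classification`.
#' @param path Output path.
#' @param min_categories IIN rule passed to [select_iins()].
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(cls, path, min_categories = 2) {
  cls$iin <- cls$node %in% select_iins(cls, min_categories)
  write_tsv(cls, path)
}
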