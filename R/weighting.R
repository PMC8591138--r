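#' Mean normalized tumor expression per gene
#'
#' Scales every sample to a common library size (total-sum scaling to the
#' mean column total), then averages the scaled values across tumor
#' samples only.
#'
#' @param expr An [expression_matrix()] with >= 1 tumor sample.
#' @return Named numeric vector of per-gene mean normalized abundance.
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  tot <- colSums(expr$values)
  if (any(tot == 0)) stop("all-zero sample(s): ",
                          paste(colnames(expr$values)[tot == 0], collapse = ", "))
  target <- mean(tot)
  scaled <- sweep(expr$values, 2, tot, "/") * target
  tum <- expr$labels == "tumor"
  if (!any(tum)) stop("no tumor samples")
  rowMeans(scaled[, tum, drop = FALSE])
}

#' Mass-action transition probabilities over a network
#'
#' For every ordered adjacent pair (i, j), the probability that
#' information at node i moves to neighbor j is the mass-action
#' interaction probability conditioned on i's neighborhood:
#' p_ij = x_j / sum over k in N(i) of x_k, where x is the mean normalized
#' tumor abundance. Highly expressed interactors therefore attract the
#' flow. If all of i's neighbors have zero abundance the row falls back
#' to uniform 1/|N(i)|.
#'
#' @param g An `igraph` graph or `layered_network` (PPI layer used).
#' @param xbar Named abundance vector covering every node of `g`;
#'   must be non-negative.
#' @return Object of class `transition_model`: list with `edges`
#'   (data.frame `from`, `to`, `p`), `xbar`, and `neighbors` (adjacency
#'   list by node id).
#' @export
transition_probabilities <- function(g, xbar) {
  if (inherits(g, "layered_network")) g <- ppi_graph(g)
  ids <- igraph::V(g)$name
  missing <- setdiff(ids, names(xbar))
  if (length(missing))
    stop("abundance missing for node(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(xbar < 0)) stop("negative abundance")
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) ids[as.integer(v)])
  names(adj) <- ids
  rows <- lapply(ids, function(i) {
    nb <- adj[[i]]
    if (!length(nb)) return(NULL)
    x <- xbar[nb]
    tot <- sum(x)
    p <- if (tot > 0) unname(x) / tot else rep(1 / length(nb), length(nb))
    data.frame(from = i, to = nb, p = p, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, xbar = xbar[ids], neighbors = adj),
            class = "transition_model")
}

#' Local signaling entropy per node
#'
#' Shannon entropy (natural log) of a node's outgoing transition
#' distribution: S_i = -sum_j p_ij log p_ij. A node that interacts
#' promiscuously with equally expressed partners has maximal entropy
#' log(k); a node whose flow is channeled into one dominant partner has
#' entropy near 0. Degree-0/1 nodes get 0.
#'
#' @param tm A [transition_probabilities()] model.
#' @param normalized If `TRUE`, divide by log(degree) (degree >= 2).
#' @return Named numeric vector S_i over the model's nodes.
#' @export
local_entropy <- function(tm, normalized = FALSE) {
  stopifnot(inherits(tm, "transition_model"))
  ids <- names(tm$neighbors)
  s <- stats::setNames(numeric(length(ids)), ids)
  by_from <- split(tm$edges$p, tm$edges$from)
  for (i in names(by_from)) {
    p <- by_from[[i]]
    p <- p[p > 0]
    h <- -sum(p * log(p))
    if (normalized && length(tm$neighbors[[i]]) >= 2)
      h <- h / log(length(tm$neighbors[[i]]))
    s[i] <- h
  }
  s
}

#' Seven-property node weights
#'
#' Evaluates the seven binary node properties — differential expression
#' (dEXP), rate-limiting enzyme (RLE), signaling cross-talk (SC), hub,
#' central (CP), global network perturbing (GNPP) and local network
#' perturbing (LNPP) — and the node weight W: 1 when at least one
#' property holds, else 0 (or, with `mode = "fraction"`, the fraction of
#' true properties).
#'
#' Nodes missing from an input table simply take FALSE for the
#' corresponding properties.
#'
#' @param ids Character vector of node ids to weight.
#' @param calls A `regulation_calls` table (dEXP = status UP/DOWN).
#' @param annotations data.frame `node_id`, `rle`, `sc` (see
#'   [read_node_annotations()]); may be `NULL`.
#' @param topology A `topology_classification` (hub/central/gnpn/lnpn
#'   flags); may be `NULL`.
#' @param mode `"binary"` (default) or `"fraction"` (count / 7).
#' @return data.frame of class `node_weights`: `node`, the seven logical
#'   columns (`dexp`, `rle`, `sc`, `hub`, `cp`, `gnpp`, `lnpp`) and `w`.
#' @export
node_weight_vector <- function(ids, calls, annotations = NULL,
                               topology = NULL, mode = c("binary", "fraction")) {
  mode <- match.arg(mode)
  st <- status_lookup(calls, ids)
  dexp <- st %in% c("UP", "DOWN")
  rle <- sc <- rep(FALSE, length(ids))
  if (!is.null(annotations)) {
    m <- match(ids, annotations$node_id)
    rle <- !is.na(m) & annotations$rle[ifelse(is.na(m), 1L, m)]
    sc <- !is.na(m) & annotations$sc[ifelse(is.na(m), 1L, m)]
  }
  hub <- cp <- gnpp <- lnpp <- rep(FALSE, length(ids))
  if (!is.null(topology)) {
    m <- match(ids, topology$node)
    pick <- function(col) !is.na(m) & col[ifelse(is.na(m), 1L, m)]
    hub <- pick(topology$hub); cp <- pick(topology$central)
    gnpp <- pick(topology$gnpn); lnpp <- pick(topology$lnpn)
  }
  props <- cbind(dexp, rle, sc, hub, cp, gnpp, lnpp)
  w <- if (mode == "binary") as.numeric(rowSums(props) > 0) else
    rowSums(props) / 7
  out <- data.frame(node = ids, dexp = dexp, rle = rle, sc = sc, hub = hub,
                    cp = cp, gnpp = gnpp, lnpp = lnpp, w = w,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("node_weights", "data.frame")
  out
}

#' Effect-on-node statistic
#'
#' Quantifies the weighted influence of a node's first and second
#' neighborhood: effs(s) = sum over neighbors j of s of
#' [ sum over neighbors i of j of w_i * n_i  +  w_j * n_j ],
#' where n_x is the degree of x and w_x its node weight. An isolated
#' node has effs = 0.
#'
#' @param g An `igraph` graph or `layered_network` (PPI layer used).
#' @param w Named numeric weight vector covering the graph's nodes
#'   (typically the `w` column of [node_weight_vector()]).
#' @param nodes Ids to evaluate (default: all graph nodes).
#' @return Named numeric vector of effs values.
#' @export
effect_on_node <- function(g, w, nodes = NULL) {
  if (inherits(g, "layered_network")) g <- ppi_graph(g)
  ids <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- ids
  missing <- setdiff(ids, names(w))
  if (length(missing))
    stop("weight missing for node(s): ", paste(utils::head(missing, 5),
                                               collapse = ", "))
  deg <- stats::setNames(igraph::degree(g), ids)
  wn <- w[ids] * deg                       # w_x * n_x per node
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) ids[as.integer(v)])
  names(adj) <- ids
  inner <- vapply(ids, function(j) sum(wn[adj[[j]]]), numeric(1))  # sum_i w_i n_i over N(j)
  effs <- vapply(nodes, function(s) {
    if (!s %in% ids) return(0)
    nb <- adj[[s]]
    if (!length(nb)) return(0)
    sum(inner[nb] + wn[nb])
  }, numeric(1))
  stats::setNames(effs, nodes)
}

# Min-max normalization to [0, 1]; a constant vector maps to all 1 so a
# degenerate context never zeroes out emission probabilities.
minmax_unit <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || r[2] - r[1] == 0) return(stats::setNames(rep(1, length(x)), names(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Assemble per-node weight records for a context network
#'
#' Convenience wrapper that runs [normalize_expression()],
#' [transition_probabilities()], [local_entropy()],
#' [node_weight_vector()] and [effect_on_node()] over a context network
#' and returns one table with the min-max normalized effs and entropy
#' used as emission ingredients.
#'
#' @param ctx A `context_network` (or `layered_network`).
#' @param expr An `expr_matrix` covering the network's protein nodes.
#' @param calls A `regulation_calls` table.
#' @param annotations,topology As in [node_weight_vector()];
#'   `topology = NULL` computes it from the context PPI graph when the
#'   graph has >= 3 nodes.
#' @param quantiles Passed to [classify_topology()].
#' @param w_mode Passed to [node_weight_vector()].
#' @return List of class `weighting` with `tm` (transition model),
#'   `records` (data.frame: node, xbar, entropy, seven flags, w, effs,
#'   eff_norm, entropy_norm) and `topology`.
#' @export
compute_weighting <- function(ctx, expr, calls, annotations = NULL,
                              topology = NULL, quantiles = 0.10,
                              w_mode = "binary", entropy_by_degree = TRUE) {
  net <- if (inherits(ctx, "context_network")) ctx$network else ctx
  g <- ppi_graph(net)
  ids <- igraph::V(g)$name
  xbar_all <- normalize_expression(expr)
  xbar <- stats::setNames(rep(0, length(ids)), ids)
  hit <- intersect(ids, names(xbar_all))
  xbar[hit] <- xbar_all[hit]
  tm <- transition_probabilities(g, xbar)
  s_i <- local_entropy(tm)
  s_emis <- if (entropy_by_degree) local_entropy(tm, normalized = TRUE) else s_i
  if (is.null(topology) && length(ids) >= 3)
    topology <- classify_topology(g, quantiles)
  nw <- node_weight_vector(ids, calls, annotations, topology, mode = w_mode)
  effs <- effect_on_node(g, stats::setNames(nw$w, nw$node))
  records <- cbind(nw[, "node", drop = FALSE],
                   xbar = unname(xbar[nw$node]),
                   entropy = unname(s_i[nw$node]),
                   nw[, c("dexp", "rle", "sc", "hub", "cp", "gnpp", "lnpp", "w")],
                   effs = unname(effs[nw$node]))
  records$eff_norm <- unname(minmax_unit(stats::setNames(records$effs, records$node)))
  records$entropy_norm <- unname(minmax_unit(s_emis[records$node]))
  structure(list(tm = tm, records = records, topology = topology),
            class = "weighting")
}
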