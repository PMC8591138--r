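# Independent reference implementations used as oracles. These are kept
# deliberately naive (nested loops, hand-rolled recursion) and share no
# code with the package internals they check.

# step-up FDR adjustment computed from the definition
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (r in n:1) {
    i <- ord[r]
    val <- min(p[i] * n / r, prev, 1)
    adj[i] <- val
    prev <- val
  }
  adj
}

# all simple paths from `from` ending at any node of `to`, with at most
# max_edges edges, by plain recursion over an adjacency list
dfs_paths <- function(adj, from, to, max_edges, banned_interior = character()) {
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (length(path) > 1L && cur %in% to)
      out[[length(out) + 1L]] <<- path
    if (length(path) - 1L >= max_edges) return()
    for (nxt in adj[[cur]]) {
      if (nxt %in% path) next
      # a banned node may terminate a path but not continue it
      if (nxt %in% banned_interior && !nxt %in% to) next
      walk(c(path, nxt))
    }
  }
  # banned nodes may appear as interiors only if they are also targets;
  # enforce the stricter rule by filtering afterwards
  walk(from)
  keep <- vapply(out, function(p) {
    interior <- if (length(p) > 2L) p[2:(length(p) - 1L)] else character()
    !any(interior %in% banned_interior)
  }, logical(1))
  out[keep]
}

# adjacency list (by node id) of an undirected PPI edge table
ppi_adjacency <- function(ppi, nodes = NULL) {
  ids <- unique(c(ppi$protein_a, ppi$protein_b, nodes))
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(ppi))) {
    a <- ppi$protein_a[i]; b <- ppi$protein_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# brute-force enumeration mirroring the module path grammar
enum_oracle <- function(net, sources, destinations, module, max_int = 3) {
  adj <- ppi_adjacency(net$ppi, net$nodes$id)
  out <- character()
  if (module == "S") {
    for (s in intersect(sources, names(adj))) {
      for (p in dfs_paths(adj, s, setdiff(destinations, s), max_int + 1L))
        out <- c(out, paste(p, collapse = "|"))
    }
  } else {
    reg <- if (module == "TF") net$tf else net$mir
    reg <- reg[reg$source %in% sources, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      src <- reg$source[i]; tg <- reg$target[i]
      if (tg %in% destinations) out <- c(out, paste(src, tg, sep = "|"))
      if (!tg %in% names(adj)) next
      for (p in dfs_paths(adj, tg, setdiff(destinations, c(tg, src)),
                          max_int + 1L, banned_interior = src))
        out <- c(out, paste(c(src, p), collapse = "|"))
    }
  }
  sort(unique(out))
}

# effs by the definition: for each neighbor j of s, add w_j*deg_j plus the
# sum of w_i*deg_i over i in N(j)
effs_oracle <- function(ppi, w, node) {
  adj <- ppi_adjacency(ppi)
  if (!node %in% names(adj)) return(0)
  deg <- vapply(adj, length, integer(1))
  tot <- 0
  for (j in adj[[node]]) {
    inner <- 0
    for (i in adj[[j]]) inner <- inner + w[[i]] * deg[[i]]
    tot <- tot + inner + w[[j]] * deg[[j]]
  }
  tot
}

# global efficiency via Floyd-Warshall on the adjacency matrix
global_efficiency_oracle <- function(ppi, nodes) {
  n <- length(nodes)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(ppi))) {
    a <- ppi$protein_a[i]; b <- ppi$protein_b[i]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# local clustering coefficient of one node by triangle counting
clustering_oracle <- function(ppi, node) {
  adj <- ppi_adjacency(ppi)
  nb <- adj[[node]]
  k <- length(nb)
  if (k < 2) return(0)
  links <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
  2 * links / (k * (k - 1))
}

# random small layered network for property tests
random_layered_net <- function(seed, n_nodes = NULL, n_edges = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(10:40, 1)
  if (is.null(n_edges)) n_edges <- sample(n_nodes:min(80, n_nodes * 2), 1)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  a <- sample(ids, n_edges * 2, replace = TRUE)
  b <- sample(ids, n_edges * 2, replace = TRUE)
  keep <- a != b
  ppi <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    confidence = round(stats::runif(sum(keep)), 3),
                    stringsAsFactors = FALSE)[seq_len(min(n_edges, sum(keep))), ]
  tfs <- sample(ids, 3)
  tf <- data.frame(source = rep(tfs, each = 2),
                   target = sample(ids, 6, replace = TRUE),
                   stringsAsFactors = FALSE)
  tf <- tf[tf$source != tf$target, , drop = FALSE]
  mir <- data.frame(source = rep(c("miR1", "miR2"), each = 3),
                    target = sample(ids, 6, replace = TRUE),
                    stringsAsFactors = FALSE)
  suppressWarnings(layered_network(ppi = ppi, tf = tf, mir = mir,
                                   extra_nodes = ids))
}

# regulation calls with random statuses over a node set
random_calls <- function(ids, seed) {
  set.seed(seed)
  regulation_calls(ids, sample(c("UP", "DOWN", "NEUTRAL", "ABSENT"),
                               length(ids), replace = TRUE,
                               prob = c(0.3, 0.2, 0.4, 0.1)))
}
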