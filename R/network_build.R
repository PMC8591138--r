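#' Filter the base PPI network by interaction confidence
#'
#' Retains PPI edges whose confidence is greater than or equal to the
#' cutoff (inclusive boundary) and drops nodes left without any edge.
#' Regulatory layers are passed through unchanged.
#'
#' @param net A [layered_network()].
#' @param min_confidence Confidence cutoff in [0, 1] (default 0.7).
#' @return A `layered_network` whose PPI layer is the filtered edge set.
#' @export
build_hppin <- function(net, min_confidence = 0.7) {
  stopifnot(inherits(net, "layered_network"))
  if (!nrow(net$ppi)) stop("PPI layer is empty")
  keep <- net$ppi$confidence >= min_confidence
  if (!any(keep)) warning("no PPI edge passes the confidence cutoff")
  layered_network(ppi = net$ppi[keep, , drop = FALSE], tf = net$tf,
                  mir = net$mir)
}

#' Build a context-specific (cancer-specific) network
#'
#' Restricts a base layered network to the molecular context defined by a
#' set of regulation calls, expanding interactions up to the second level:
#'
#' \describe{
#'   \item{mode "ppin"}{level 1 keeps PPI edges with at least one UP/DOWN
#'     endpoint whose partner is UP/DOWN/NEUTRAL; level 2 adds PPI edges
#'     from any level-1 node to additional UP/DOWN/NEUTRAL neighbors (one
#'     extra hop).}
#'   \item{mode "tf"}{keeps TF->target edges where both TF and target are
#'     UP/DOWN, then attaches the targets' PPI neighborhood up to the
#'     second level among UP/DOWN/NEUTRAL partners.}
#'   \item{mode "mir"}{same as "tf" with miRNA->target edges; miRNA status
#'     is taken from the same calls table (miRNA entity ids).}
#' }
#' ABSENT nodes never enter the context network.
#'
#' @param base A [layered_network()].
#' @param calls A `regulation_calls` data.frame; nodes it does not cover
#'   are treated as ABSENT.
#' @param mode One of `"ppin"`, `"tf"`, `"mir"`.
#' @return Object of class `context_network`: list with `network` (the
#'   restricted `layered_network`), `status` (named vector over its
#'   nodes), `edge_level` (per-PPI-edge "level1"/"level2"; regulatory
#'   edges are level1), and `mode`.
#' @export
build_context_network <- function(base, calls, mode = c("ppin", "tf", "mir")) {
  stopifnot(inherits(base, "layered_network"))
  mode <- match.arg(mode)
  st <- status_lookup(calls, base$nodes$id)
  ok <- c("UP", "DOWN", "NEUTRAL")
  dereg <- c("UP", "DOWN")
  ppi <- base$ppi
  sa <- st[ppi$protein_a]; sb <- st[ppi$protein_b]
  present <- sa %in% ok & sb %in% ok

  if (mode == "ppin") {
    lvl1 <- present & (sa %in% dereg | sb %in% dereg)
    seeds <- unique(c(ppi$protein_a[lvl1], ppi$protein_b[lvl1]))
    reg_tf <- base$tf[0, ]; reg_mir <- base$mir[0, ]
  } else {
    reg <- if (mode == "tf") base$tf else base$mir
    src_st <- st[reg$source]
    tgt_st <- st[reg$target]
    reg_keep <- src_st %in% dereg & tgt_st %in% dereg
    reg <- reg[reg_keep, , drop = FALSE]
    seeds <- unique(reg$target)
    lvl1 <- present & (ppi$protein_a %in% seeds | ppi$protein_b %in% seeds)
    seeds <- unique(c(seeds, ppi$protein_a[lvl1], ppi$protein_b[lvl1]))
    if (mode == "tf") { reg_tf <- reg; reg_mir <- base$mir[0, ] }
    else { reg_tf <- base$tf[0, ]; reg_mir <- reg }
  }
  lvl2 <- present & !lvl1 &
    (ppi$protein_a %in% seeds | ppi$protein_b %in% seeds)

  keep <- lvl1 | lvl2
  ctx_ppi <- ppi[keep, , drop = FALSE]
  level <- ifelse(lvl1[keep], "level1", "level2")
  net <- layered_network(ppi = ctx_ppi, tf = reg_tf, mir = reg_mir)
  structure(list(network = net,
                 status = st[net$nodes$id],
                 edge_level = level,
                 mode = mode),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf("<context_network mode=%s> ", x$mode))
  print(x$network)
  invisible(x)
}

#' Empirical degree distribution P(k) = n_k / N
#'
#' @param g An `igraph` graph (or a `layered_network`, whose PPI layer is
#'   used).
#' @return data.frame with columns `k`, `n_k`, `p_k`; fractions sum to 1.
#' @export
degree_distribution_table <- function(g) {
  if (inherits(g, "layered_network")) g <- ppi_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)),
             n_k = as.integer(tab),
             p_k = as.integer(tab) / igraph::vcount(g))
}

# Least-squares fit of log10 P(k) on log10 k over k >= 1 with P(k) > 0.
# Returns slope and R^2; a scale-free network shows a steep negative
# slope with high R^2 relative to a G(n,m) ensemble.
heavy_tail_diagnostic <- function(dd) {
  dd <- dd[dd$k >= 1 & dd$p_k > 0, , drop = FALSE]
  if (nrow(dd) < 3) return(c(slope = NA_real_, r_squared = NA_real_))
  fit <- stats::lm(log10(p_k) ~ log10(k), data = dd)
  c(slope = unname(stats::coef(fit)[2L]),
    r_squared = summary(fit)$r.squared)
}

#' Compare a network with a uniform random ensemble
#'
#' Generates `n_random` Erdos-Renyi G(n, m) graphs with exactly the same
#' node and edge counts as the input, and returns each graph's degree
#' distribution together with a heavy-tail diagnostic: the slope and R^2
#' of the least-squares fit of log P(k) against log k (over degrees with
#' positive frequency).
#'
#' @param g An `igraph` graph or `layered_network`.
#' @param n_random Ensemble size (default 10).
#' @param seed Integer seed; the ensemble is reproducible.
#' @return List with `observed` (list: `distribution`, `diagnostic`) and
#'   `random` (list of the same per ensemble member).
#' @export
random_ensemble_compare <- function(g, n_random = 10, seed = 1) {
  if (inherits(g, "layered_network")) g <- ppi_graph(g)
  if (n_random < 1) stop("n_random must be >= 1")
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (m > n * (n - 1) / 2) stop("edge count exceeds maximum for simple graph")
  obs_dd <- degree_distribution_table(g)
  set.seed(seed)
  rand <- lapply(seq_len(n_random), function(i) {
    rg <- igraph::sample_gnm(n, m)
    dd <- degree_distribution_table(rg)
    list(distribution = dd, diagnostic = heavy_tail_diagnostic(dd),
         n = igraph::vcount(rg), m = igraph::ecount(rg))
  })
  list(observed = list(distribution = obs_dd,
                       diagnostic = heavy_tail_diagnostic(obs_dd),
                       n = n, m = m),
       random = rand)
}
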