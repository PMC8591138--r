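#' Sub-network spanned by a set of paths
#'
#' Builds the layered network formed by the union of the paths' edges:
#' consecutive PPI pairs keep their confidence from the base network, and
#' the leading TF->TG / miR->TG edge of regulatory paths goes to the
#' matching regulatory layer. This is the sub-network on which edge and
#' node weights are computed.
#'
#' @param paths A `cross_paths` data.frame.
#' @param base The base [layered_network()] the paths were enumerated on.
#' @return A `layered_network`.
#' @export
paths_subnetwork <- function(paths, base) {
  stopifnot(inherits(base, "layered_network"))
  if (!nrow(paths)) return(layered_network())
  conf <- stats::setNames(base$ppi$confidence,
                          paste0(base$ppi$protein_a, "\r", base$ppi$protein_b))
  ppi_a <- character(); ppi_b <- character()
  reg_src <- character(); reg_tgt <- character(); reg_mod <- character()
  node_lists <- strsplit(paths$nodes, "|", fixed = TRUE)
  for (i in seq_len(nrow(paths))) {
    nd <- node_lists[[i]]
    k <- length(nd)
    first_ppi <- 1L
    if (paths$module[i] != "S") {
      reg_src <- c(reg_src, nd[1L]); reg_tgt <- c(reg_tgt, nd[2L])
      reg_mod <- c(reg_mod, paths$module[i])
      first_ppi <- 2L
    }
    if (k - 1L >= first_ppi) {
      idx <- first_ppi:(k - 1L)
      ppi_a <- c(ppi_a, nd[idx]); ppi_b <- c(ppi_b, nd[idx + 1L])
    }
  }
  ppi <- NULL
  if (length(ppi_a)) {
    a <- pmin(ppi_a, ppi_b); b <- pmax(ppi_a, ppi_b)
    keep <- !duplicated(paste0(a, "\r", b))
    cf <- conf[paste0(a, "\r", b)][keep]
    cf[is.na(cf)] <- 1
    ppi <- data.frame(protein_a = a[keep], protein_b = b[keep],
                      confidence = unname(cf), stringsAsFactors = FALSE)
  }
  tf <- if (any(reg_mod == "TF"))
    unique(data.frame(source = reg_src[reg_mod == "TF"],
                      target = reg_tgt[reg_mod == "TF"],
                      stringsAsFactors = FALSE)) else NULL
  mir <- if (any(reg_mod == "miR"))
    unique(data.frame(source = reg_src[reg_mod == "miR"],
                      target = reg_tgt[reg_mod == "miR"],
                      stringsAsFactors = FALSE)) else NULL
  layered_network(ppi = ppi, tf = tf, mir = mir)
}

#' Default analysis configuration
#'
#' All tunable thresholds of the analysis with their defaults:
#' fold-change and adjusted-p cutoffs (1.5 / 0.05 for mRNA, 1.0 / 0.05
#' for miRNA), PPI confidence cutoff 0.7, topology top-fraction 0.10,
#' maximum 3 intermediate proteins per path, emission blend beta 0.5,
#' Model 1 z cutoff 1, Model 2 within-pair fraction 0.8, perturbation
#' key-node |z| cutoff 1.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
crossmet_config <- function(...) {
  cfg <- list(fc_threshold = 1.5, p_threshold = 0.05,
              mir_fc_threshold = 1.0, mir_p_threshold = 0.05,
              min_confidence = 0.7, quantiles = 0.10,
              max_intermediates = 3, beta = 0.5,
              z_cutoff = 1, frac = 0.8, key_z = 1,
              w_mode = "binary",
              exclude_sources_as_intermediates = FALSE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run one module of the analysis end to end
#'
#' Enumerates candidate paths on the base network, applies the
#' deregulation context filter, computes weights on the sub-network
#' spanned by the surviving paths (topology flags taken from the
#' mode-matched context network), scores the paths and applies Models 1
#' and 2.
#'
#' @param base Base [layered_network()] (confidence-filtered PPI plus
#'   regulatory layers).
#' @param expr An `expr_matrix` (tumor/normal) covering the protein
#'   universe.
#' @param calls `regulation_calls` covering proteins (and miRNAs for the
#'   miR module).
#' @param sources,destinations Source and destination id vectors.
#' @param module `"S"`, `"TF"` or `"miR"`.
#' @param config A [crossmet_config()] list.
#' @param annotations Optional node annotation table (RLE / SC flags).
#' @return List of class `module_result`: `paths` (scored), `pairs`
#'   (Model 1), `selected` (Model 2), `weighting`, `context`, `summary`.
#' @export
score_module <- function(base, expr, calls, sources, destinations,
                         module = c("S", "TF", "miR"),
                         config = crossmet_config(), annotations = NULL) {
  module <- match.arg(module)
  empty <- function() {
    p0 <- cross_paths_from_list(list(), module)
    s0 <- score_paths(p0, list(tm = NULL, records = data.frame(
      node = character(), eff_norm = numeric(), entropy_norm = numeric())))
    structure(list(paths = s0, pairs = model1_select_pairs(s0),
                   selected = s0, weighting = NULL, context = NULL,
                   summary = selection_summary(s0, model1_select_pairs(s0), s0)),
              class = "module_result")
  }
  cand <- enumerate_cross_paths(
    base, sources, destinations, module,
    max_intermediates = config$max_intermediates,
    exclude_sources_as_intermediates = config$exclude_sources_as_intermediates)
  kept <- context_filter_paths(cand, calls)
  if (!nrow(kept)) return(empty())
  sub <- paths_subnetwork(kept, base)
  mode <- c(S = "ppin", TF = "tf", miR = "mir")[[module]]
  ctx <- build_context_network(base, calls, mode)
  topo <- NULL
  gctx <- ppi_graph(ctx$network)
  if (igraph::vcount(gctx) >= 3)
    topo <- classify_topology(gctx, config$quantiles)
  # weights live on the context network extended by any path edge that
  # falls outside it, so every scored edge has a transition probability
  wnet <- layered_network(ppi = rbind(ctx$network$ppi, sub$ppi),
                          tf = sub$tf, mir = sub$mir)
  wt <- compute_weighting(wnet, expr, calls, annotations = annotations,
                          topology = topo, quantiles = config$quantiles,
                          w_mode = config$w_mode)
  scored <- score_paths(kept, wt, beta = config$beta)
  pairs <- model1_select_pairs(scored, z_cutoff = config$z_cutoff)
  selected <- model2_select_paths(pairs, scored, frac = config$frac)
  structure(list(paths = scored, pairs = pairs, selected = selected,
                 weighting = wt, context = ctx,
                 summary = selection_summary(scored, pairs, selected)),
            class = "module_result")
}

#' Remove a node from a layered network
#'
#' Drops the node and every PPI, TF and miRNA edge incident to it — the
#' single-node knockout used by the perturbation scan.
#'
#' @param net A `layered_network`.
#' @param node Node id.
#' @return A `layered_network` without the node.
#' @export
remove_node <- function(net, node) {
  stopifnot(inherits(net, "layered_network"))
  ppi <- net$ppi[net$ppi$protein_a != node & net$ppi$protein_b != node, ,
                 drop = FALSE]
  tf <- net$tf[net$tf$source != node & net$tf$target != node, , drop = FALSE]
  mir <- net$mir[net$mir$source != node & net$mir$target != node, ,
                 drop = FALSE]
  layered_network(ppi = ppi, tf = tf, mir = mir,
                  extra_nodes = setdiff(net$nodes$id[net$nodes$kind == "protein"],
                                        node))
}
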