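#' Multi-layer molecular interaction network
#'
#' Holds typed nodes (protein or miRNA) and three edge layers: undirected
#' protein-protein interactions with a confidence score in [0, 1], directed
#' TF-to-target edges, and directed miRNA-to-target edges. Self-loops are
#' dropped with a warning; duplicate edges within a layer (including the
#' two orientations of a PPI pair) are collapsed to one row.
#'
#' @param ppi data.frame with columns `protein_a`, `protein_b`,
#'   `confidence`.
#' @param tf data.frame with columns `source`, `target` (both proteins).
#' @param mir data.frame with columns `source` (miRNA id), `target`
#'   (protein).
#' @param extra_nodes Optional character vector of additional protein ids
#'   to register even if they touch no edge.
#' @return An object of class `layered_network`: list with `nodes`
#'   (data.frame `id`, `kind`), `ppi`, `tf`, `mir` edge tables.
#' @export
layered_network <- function(ppi = NULL, tf = NULL, mir = NULL,
                            extra_nodes = character()) {
  empty_ppi <- data.frame(protein_a = character(), protein_b = character(),
                          confidence = numeric(), stringsAsFactors = FALSE)
  empty_reg <- data.frame(source = character(), target = character(),
                          stringsAsFactors = FALSE)
  ppi <- if (is.null(ppi) || !nrow(ppi)) empty_ppi else
    data.frame(protein_a = as.character(ppi[[1L]]),
               protein_b = as.character(ppi[[2L]]),
               confidence = as.numeric(ppi[[3L]]), stringsAsFactors = FALSE)
  tf <- if (is.null(tf) || !nrow(tf)) empty_reg else
    data.frame(source = as.character(tf[[1L]]), target = as.character(tf[[2L]]),
               stringsAsFactors = FALSE)
  mir <- if (is.null(mir) || !nrow(mir)) empty_reg else
    data.frame(source = as.character(mir[[1L]]), target = as.character(mir[[2L]]),
               stringsAsFactors = FALSE)

  if (nrow(ppi)) {
    if (any(!is.finite(ppi$confidence)) ||
        any(ppi$confidence < 0) || any(ppi$confidence > 1))
      stop("PPI confidence must lie in [0, 1]")
    loop <- ppi$protein_a == ppi$protein_b
    if (any(loop)) {
      warning(sum(loop), " PPI self-loop(s) dropped")
      ppi <- ppi[!loop, , drop = FALSE]
    }
    # store each unordered pair once, lexicographically ordered
    a <- pmin(ppi$protein_a, ppi$protein_b)
    b <- pmax(ppi$protein_a, ppi$protein_b)
    ppi$protein_a <- a; ppi$protein_b <- b
    ppi <- ppi[!duplicated(paste0(a, "\r", b)), , drop = FALSE]
  }
  for (nm in c("tf", "mir")) {
    e <- get(nm)
    if (nrow(e)) {
      loop <- e$source == e$target
      if (any(loop)) {
        warning(sum(loop), " ", nm, " self-loop(s) dropped")
        e <- e[!loop, , drop = FALSE]
      }
      e <- e[!duplicated(paste0(e$source, "\r", e$target)), , drop = FALSE]
      assign(nm, e)
    }
  }
  proteins <- unique(c(ppi$protein_a, ppi$protein_b, tf$source, tf$target,
                       mir$target, extra_nodes))
  mirnas <- unique(mir$source)
  clash <- intersect(proteins, mirnas)
  if (length(clash))
    stop("id(s) used both as protein and miRNA: ", paste(clash, collapse = ", "))
  nodes <- data.frame(id = c(proteins, mirnas),
                      kind = rep(c("protein", "miRNA"),
                                 c(length(proteins), length(mirnas))),
                      stringsAsFactors = FALSE)
  rownames(ppi) <- rownames(tf) <- rownames(mir) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, ppi = ppi, tf = tf, mir = mir),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf(paste0("<layered_network> %d nodes (%d proteins, %d miRNAs); ",
                     "%d PPI / %d TF / %d miR edges\n"),
              nrow(x$nodes), sum(x$nodes$kind == "protein"),
              sum(x$nodes$kind == "miRNA"),
              nrow(x$ppi), nrow(x$tf), nrow(x$mir)))
  invisible(x)
}

#' Read the three interaction layers from TSV edge lists
#'
#' @param ppi_path TSV with header `protein_a`, `protein_b`, `confidence`.
#' @param tf_path TSV with header `source`, `target`; `NULL` for none.
#' @param mir_path TSV with header `source`, `target`; `NULL` for none.
#' @return A [layered_network()].
#' @export
read_interaction_tables <- function(ppi_path, tf_path = NULL, mir_path = NULL) {
  ppi <- read_tsv(ppi_path)
  need <- c("protein_a", "protein_b", "confidence")
  if (!all(need %in% colnames(ppi)))
    stop("PPI table must have columns: ", paste(need, collapse = ", "))
  tf <- if (!is.null(tf_path)) read_tsv(tf_path) else NULL
  mir <- if (!is.null(mir_path)) read_tsv(mir_path) else NULL
  layered_network(ppi = ppi[, need], tf = tf, mir = mir)
}

#' Write the three interaction layers as TSV edge lists
#'
#' @param net A `layered_network`.
#' @param ppi_path,tf_path,mir_path Output file paths (`NULL` to skip a
#'   layer).
#' @return Invisibly, the paths written.
#' @export
write_interaction_tables <- function(net, ppi_path, tf_path = NULL,
                                     mir_path = NULL) {
  stopifnot(inherits(net, "layered_network"))
  write_tsv(net$ppi, ppi_path)
  if (!is.null(tf_path)) write_tsv(net$tf, tf_path)
  if (!is.null(mir_path)) write_tsv(net$mir, mir_path)
  invisible(c(ppi_path, tf_path, mir_path))
}

#' Convert the PPI layer to an igraph object
#'
#' @param net A `layered_network` or a PPI edge data.frame.
#' @param all_nodes If `TRUE`, include isolated protein nodes.
#' @return An undirected simple `igraph` graph with a `confidence` edge
#'   attribute.
#' @export
ppi_graph <- function(net, all_nodes = FALSE) {
  if (inherits(net, "layered_network")) {
    ppi <- net$ppi
    verts <- if (all_nodes) net$nodes$id[net$nodes$kind == "protein"] else
      unique(c(ppi$protein_a, ppi$protein_b))
  } else {
    ppi <- net
    verts <- unique(c(ppi$protein_a, ppi$protein_b))
  }
  g <- igraph::graph_from_data_frame(
    ppi[, c("protein_a", "protein_b", "confidence")],
    directed = FALSE, vertices = data.frame(name = verts))
  g
}

#' Export a network as a SIF file
#'
#' Simple interaction format: source, relation, target per line. PPI edges
#' get relation `pp`, TF edges `tf`, miRNA edges `mir`.
#'
#' @param net A `layered_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "layered_network"))
  lines <- c(
    if (nrow(net$ppi)) paste(net$ppi$protein_a, "pp", net$ppi$protein_b, sep = "\t"),
    if (nrow(net$tf)) paste(net$tf$source, "tf", net$tf$target, sep = "\t"),
    if (nrow(net$mir)) paste(net$mir$source, "mir", net$mir$target, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
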