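#' Enumerate cross-pathway paths from regulators to metabolic enzymes
#'
#' Enumerates all simple paths linking each source (signaling protein, TF
#' or miRNA) to each destination (metabolic enzyme) under the path
#' grammar:
#' \describe{
#'   \item{module "S"}{PPI-only paths `S-M`, `S-P-M`, `S-P-P-M`,
#'     `S-P-P-P-M`: zero to `max_intermediates` intermediate proteins.}
#'   \item{module "TF"}{a regulatory edge TF->TG followed by zero to
#'     `max_intermediates` intermediates over PPIs: `TF-TG/M` (the target
#'     itself is a destination), `TF-TG/P-M`, ..., `TF-TG/P-P-P-P-M`.}
#'   \item{module "miR"}{same grammar with miRNA->TG edges
#'     (`miR-TG/M` ... `miR-TG/P-P-P-P-M`).}
#' }
#' Paths are simple (no repeated node) and deduplicated. A source that is
#' also a destination is skipped as a pair (but may still appear inside
#' other paths unless `exclude_sources_as_intermediates` is set).
#'
#' @param net A [layered_network()].
#' @param sources Character vector of source ids (signaling proteins for
#'   module S; TFs / miRNAs otherwise).
#' @param destinations Character vector of metabolic enzyme ids.
#' @param module `"S"`, `"TF"` or `"miR"`.
#' @param max_intermediates Maximum number of intermediate proteins
#'   between the entry protein and the destination (default 3).
#' @param exclude_sources_as_intermediates If `TRUE`, no member of
#'   `sources` may appear as an interior node.
#' @return data.frame of class `cross_paths` with columns `module`,
#'   `type_label`, `source`, `destination`, `nodes` (pipe-delimited id
#'   sequence) and `n_intermediates`.
#' @export
enumerate_cross_paths <- function(net, sources, destinations,
                                  module = c("S", "TF", "miR"),
                                  max_intermediates = 3,
                                  exclude_sources_as_intermediates = FALSE) {
  stopifnot(inherits(net, "layered_network"))
  module <- match.arg(module)
  if (!length(sources) || !length(destinations))
    stop("sources and destinations must be non-empty")
  g <- ppi_graph(net)
  gids <- igraph::V(g)$name
  dest <- intersect(unique(destinations), gids)
  banned <- if (exclude_sources_as_intermediates) unique(sources) else character()

  paths <- list()
  if (module == "S") {
    for (s in intersect(unique(sources), gids)) {
      for (p in simple_ppi_paths(g, s, setdiff(dest, s), max_intermediates,
                                 banned = setdiff(banned, s))) {
        paths[[length(paths) + 1L]] <- p
      }
    }
  } else {
    reg <- if (module == "TF") net$tf else net$mir
    reg <- reg[reg$source %in% sources, , drop = FALSE]
    if (!nrow(reg)) stop("regulatory layer has no edges from the given sources")
    for (r in seq_len(nrow(reg))) {
      src <- reg$source[r]; tg <- reg$target[r]
      # a source that is itself a destination contributes no self-pair,
      # but its pairs with other destinations are still enumerated
      if (tg %in% destinations) paths[[length(paths) + 1L]] <- c(src, tg)
      if (!tg %in% gids) next
      tails <- simple_ppi_paths(g, tg, setdiff(dest, c(tg, src)),
                                max_intermediates,
                                banned = union(setdiff(banned, tg), src))
      for (p in tails) paths[[length(paths) + 1L]] <- c(src, p)
    }
  }
  cross_paths_from_list(paths, module)
}

# All simple paths in g from `from` to any node of `to`, with at most
# max_int intermediate nodes (path length <= max_int + 1 edges), avoiding
# `banned` as interior nodes.
simple_ppi_paths <- function(g, from, to, max_int, banned = character()) {
  to <- setdiff(to, from)
  if (!length(to) || !from %in% igraph::V(g)$name) return(list())
  raw <- igraph::all_simple_paths(g, from = from, to = to,
                                  cutoff = max_int + 1L)
  out <- list()
  for (vp in raw) {
    ids <- igraph::V(g)$name[as.integer(vp)]
    k <- length(ids)
    # all_simple_paths returns every path ending at ANY `to` vertex; keep
    # only those whose interior avoids destinations-as-waypoints? No: a
    # destination may sit mid-path en route to another destination; such
    # prefixes are themselves emitted separately, so just keep paths whose
    # final node is a destination (guaranteed) and interior passes bans.
    interior <- if (k > 2) ids[2:(k - 1)] else character()
    if (length(intersect(interior, banned))) next
    out[[length(out) + 1L]] <- ids
  }
  out
}

cross_paths_from_list <- function(paths, module) {
  if (!length(paths)) {
    out <- data.frame(module = character(), type_label = character(),
                      source = character(), destination = character(),
                      nodes = character(), n_intermediates = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cross_paths", "data.frame")
    return(out)
  }
  keys <- vapply(paths, paste, character(1), collapse = "|")
  dup <- duplicated(keys)
  paths <- paths[!dup]; keys <- keys[!dup]
  len <- lengths(paths)
  src <- vapply(paths, `[`, character(1), 1L)
  dst <- vapply(paths, function(p) p[length(p)], character(1))
  n_int <- if (module == "S") len - 2L else len - 3L
  out <- data.frame(module = module,
                    type_label = path_type_label(module, len),
                    source = src, destination = dst, nodes = keys,
                    n_intermediates = pmax(n_int, 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cross_paths", "data.frame")
  out
}

#' Canonical path-type label
#'
#' Maps a module and node count to the field's path nomenclature:
#' `S-M` ... `S-P-P-P-M` for module S, `TF-TG/M` ... `TF-TG/P-P-P-P-M`
#' for module TF, and likewise `miR-...` for module miR.
#'
#' @param module `"S"`, `"TF"` or `"miR"`.
#' @param n_nodes Number of nodes in the path (vectorized).
#' @return Character vector of type labels.
#' @export
path_type_label <- function(module, n_nodes) {
  if (module == "S") {
    n_int <- n_nodes - 2L
    if (any(n_int < 0L)) stop("module S path needs >= 2 nodes")
    vapply(n_int, function(k)
      paste(c("S", rep("P", k), "M"), collapse = "-"), character(1))
  } else {
    pre <- if (module == "TF") "TF" else "miR"
    n_int <- n_nodes - 3L  # nodes beyond source, TG, destination
    if (any(n_int < -1L)) stop("regulatory path needs >= 2 nodes")
    vapply(n_int, function(k) {
      if (k == -1L) paste0(pre, "-TG/M")
      else paste0(pre, "-TG/", paste(rep("P", k + 1L), collapse = "-"), "-M")
    }, character(1))
  }
}

#' Filter paths by the deregulation context
#'
#' Keeps a path when its source and destination are deregulated (UP or
#' DOWN), the regulatory target (for TF/miR modules) is deregulated, and
#' every remaining interior node is UP, DOWN or NEUTRAL. Paths touching
#' an ABSENT node are removed; a node without any status is an error.
#'
#' @param paths A `cross_paths` data.frame.
#' @param calls A `regulation_calls` table covering every path node
#'   (including miRNA sources).
#' @return The retained subset of `paths` (same class).
#' @export
context_filter_paths <- function(paths, calls) {
  stopifnot(inherits(paths, "cross_paths"))
  if (!nrow(paths)) return(paths)
  node_lists <- strsplit(paths$nodes, "|", fixed = TRUE)
  all_nodes <- unique(unlist(node_lists))
  missing <- setdiff(all_nodes, calls$entity_id)
  if (length(missing))
    stop("node(s) without regulation status: ",
         paste(utils::head(missing, 5), collapse = ", "))
  st <- stats::setNames(calls$status[match(all_nodes, calls$entity_id)],
                        all_nodes)
  dereg <- c("UP", "DOWN")
  ok_mid <- c("UP", "DOWN", "NEUTRAL")
  keep <- vapply(seq_len(nrow(paths)), function(i) {
    nd <- node_lists[[i]]
    s <- st[nd]
    k <- length(nd)
    if (!s[1L] %in% dereg || !s[k] %in% dereg) return(FALSE)
    if (paths$module[i] != "S" && k >= 2L && !s[2L] %in% dereg) return(FALSE)
    all(s %in% ok_mid)
  }, logical(1))
  paths[keep, , drop = FALSE]
}

#' Cross-tabulate pathway connections of path terminals
#'
#' Counts, for every (source signaling pathway, destination metabolic
#' category) combination, how many path-terminal annotations fall in that
#' cell: each path contributes one count per combination of its source's
#' signaling pathways and its destination's metabolic categories.
#' Unannotated terminals are counted under `"unassigned"`.
#'
#' @param paths A `cross_paths` data.frame.
#' @param annot A [pathway_annotation()].
#' @return data.frame `source_pathway`, `dest_category`, `n_paths`.
#' @export
pathway_connection_counts <- function(paths, annot) {
  stopifnot(inherits(paths, "cross_paths"), inherits(annot, "pathway_annotation"))
  if (!nrow(paths))
    return(data.frame(source_pathway = character(), dest_category = character(),
                      n_paths = integer(), stringsAsFactors = FALSE))
  cells <- list()
  for (i in seq_len(nrow(paths))) {
    sp <- pathways_of(annot, paths$source[i], class = "signaling")
    if (!length(sp)) sp <- "unassigned"
    dp <- pathways_of(annot, paths$destination[i], class = "metabolic")
    dc <- if (length(dp))
      unique(vapply(dp, function(p) annot[[p]]$category, character(1)))
    else "unassigned"
    cells[[i]] <- expand.grid(source_pathway = sp, dest_category = dc,
                              stringsAsFactors = FALSE)
  }
  all_cells <- do.call(rbind, cells)
  agg <- stats::aggregate(list(n_paths = rep(1L, nrow(all_cells))),
                          all_cells, FUN = sum)
  agg <- agg[order(agg$source_pathway, agg$dest_category), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write paths as TSV
#' @param paths A `cross_paths` data.frame (optionally with score columns).
#' @param path Output file.
#' @param calls Optional `regulation_calls` to add terminal statuses.
#' @param comment_lines Optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path, calls = NULL, comment_lines = character()) {
  out <- as.data.frame(paths)
  if (!is.null(calls)) {
    st <- stats::setNames(calls$status, calls$entity_id)
    out$source_status <- unname(st[out$source])
    out$destination_status <- unname(st[out$destination])
  }
  write_tsv(out, path, comment_lines)
}
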