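#' In-silico single-node perturbation scan
#'
#' Knocks out candidate nodes one at a time from the base network,
#' re-runs the full path pipeline (enumeration, context filter,
#' weighting, Models 1 and 2) for each requested module, and records the
#' change in the mean selected-path log score:
#' perturbation score = mean score after - mean score before.
#' A knockout that wipes out every selected path is assigned the
#' epsilon log-floor log(1e-12) as its after-mean, so that destroying
#' the entire signal registers as maximally disruptive instead of
#' silently dropping out.
#'
#' @param base Base [layered_network()].
#' @param expr An `expr_matrix`.
#' @param calls `regulation_calls` over the node universe.
#' @param sources,destinations As in [score_module()]. For multi-module
#'   scans pass named lists keyed by module (e.g.
#'   `list(S = ..., TF = ...)`); a plain vector is used for all modules.
#' @param modules Character vector of modules to score (default `"S"`).
#' @param config A [crossmet_config()].
#' @param annotations Optional node annotation table.
#' @param nodes Nodes to knock out; default: every node appearing in a
#'   Model-2-selected path of the baseline run.
#' @return List of class `perturbation_result`: `table` (data.frame
#'   `node`, `score_before`, `score_after`, `perturbation_score`, `z`,
#'   `key`), `baseline` (the per-module baseline results), and `key_z`.
#' @export
perturbation_scan <- function(base, expr, calls, sources, destinations,
                              modules = "S", config = crossmet_config(),
                              annotations = NULL, nodes = NULL) {
  src_of <- function(m) if (is.list(sources)) sources[[m]] else sources
  dst_of <- function(m) if (is.list(destinations)) destinations[[m]] else destinations
  run_all <- function(net) {
    lapply(stats::setNames(modules, modules), function(m) {
      src <- intersect(src_of(m), net$nodes$id)
      dst <- intersect(dst_of(m), net$nodes$id)
      if (!length(src) || !length(dst)) return(NULL)
      res <- tryCatch(
        score_module(net, expr, calls, src, dst, module = m,
                     config = config, annotations = annotations),
        error = function(e) NULL)
      res
    })
  }
  mean_selected <- function(results) {
    logs <- unlist(lapply(results, function(r)
      if (!is.null(r)) r$selected$log_score else numeric()))
    if (!length(logs)) return(log(1e-12))
    mean(logs)
  }
  baseline <- run_all(base)
  before <- mean_selected(baseline)
  sel_nodes <- unique(unlist(lapply(baseline, function(r)
    if (!is.null(r) && nrow(r$selected))
      strsplit(r$selected$nodes, "|", fixed = TRUE) else NULL)))
  if (is.null(sel_nodes)) sel_nodes <- character()
  if (is.null(nodes)) nodes <- sel_nodes
  if (!length(nodes)) stop("no significant paths: nothing to perturb")

  rows <- lapply(nodes, function(nd) {
    touches <- nd %in% sel_nodes
    if (!touches && !node_in_any_subnetwork(baseline, nd)) {
      after <- before  # knockout cannot affect any scored object
    } else {
      after <- mean_selected(run_all(remove_node(base, nd)))
    }
    data.frame(node = nd, score_before = before, score_after = after,
               perturbation_score = after - before, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sdv <- if (nrow(tab) >= 3) stats::sd(tab$perturbation_score) else 0
  tab$z <- if (sdv > 0)
    (tab$perturbation_score - mean(tab$perturbation_score)) / sdv else 0
  tab$key <- abs(tab$z) >= config$key_z
  rownames(tab) <- NULL
  structure(list(table = tab, baseline = baseline, key_z = config$key_z),
            class = "perturbation_result")
}

# TRUE when the node participates in any scored sub-network or context
# network of the baseline run, i.e. its removal could move any score.
node_in_any_subnetwork <- function(baseline, nd) {
  any(vapply(baseline, function(r) {
    if (is.null(r)) return(FALSE)
    (!is.null(r$weighting) && nd %in% r$weighting$records$node) ||
      (!is.null(r$context) && nd %in% r$context$network$nodes$id)
  }, logical(1)))
}

#' Select key (effector) nodes from a perturbation scan
#'
#' Standardizes the perturbation scores across scanned nodes and flags
#' nodes whose z deviates from the mean by at least `key_z` in either
#' direction (|Z| >= 1 by default). With constant scores no node is key.
#'
#' @param results A `perturbation_result` or its `table` data.frame.
#' @param key_z Two-sided z cutoff (default 1).
#' @return Character vector of key node ids.
#' @export
select_key_nodes <- function(results, key_z = 1) {
  tab <- if (inherits(results, "perturbation_result")) results$table else results
  if (nrow(tab) < 3) stop("need >= 3 perturbation results for a meaningful z")
  sdv <- stats::sd(tab$perturbation_score)
  if (sdv == 0) return(character())
  z <- (tab$perturbation_score - mean(tab$perturbation_score)) / sdv
  tab$node[abs(z) >= key_z]
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> %d nodes scanned, %d key (|z| >= %g)\n",
              nrow(x$table), sum(x$table$key), x$key_z))
  invisible(x)
}
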