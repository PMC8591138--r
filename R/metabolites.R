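#' Map deregulated metabolites onto selected paths
#'
#' Joins the metabolite table to the paths on the terminal metabolic
#' enzyme: a path is metabolite-linked when at least one table row's
#' enzyme equals the path's destination. The join is purely descriptive
#' (enzyme direction, metabolite direction, substrate/product role); it
#' never alters path membership or scores.
#'
#' @param paths A `cross_paths` / `scored_paths` data.frame.
#' @param table A [metabolite_table()].
#' @param calls Optional `regulation_calls` to report the enzyme's own
#'   direction next to the metabolite's.
#' @return List with `annotations` (data.frame: path row index `path_id`,
#'   `destination`, `metabolite_id`, `metabolite_status`, `role`, and
#'   `enzyme_status` if `calls` given), `paths` (input with a logical
#'   `metabolite_linked` column) and `metabolite_summary` (paths per
#'   metabolite).
#' @export
map_metabolites <- function(paths, table, calls = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  paths <- as.data.frame(paths)
  hits <- list()
  if (nrow(paths)) {
    for (i in seq_len(nrow(paths))) {
      rows <- table[table$enzyme_id == paths$destination[i], , drop = FALSE]
      if (!nrow(rows)) next
      hits[[length(hits) + 1L]] <- data.frame(
        path_id = i, destination = paths$destination[i],
        metabolite_id = rows$metabolite_id,
        metabolite_status = rows$status, role = rows$role,
        stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(hits)) do.call(rbind, hits) else
    data.frame(path_id = integer(), destination = character(),
               metabolite_id = character(), metabolite_status = character(),
               role = character(), stringsAsFactors = FALSE)
  if (!is.null(calls) && nrow(ann)) {
    st <- stats::setNames(calls$status, calls$entity_id)
    ann$enzyme_status <- unname(st[ann$destination])
  }
  paths$metabolite_linked <- seq_len(nrow(paths)) %in% ann$path_id
  summary <- if (nrow(ann))
    stats::aggregate(list(n_paths = ann$path_id),
                     by = list(metabolite_id = ann$metabolite_id),
                     FUN = function(x) length(unique(x)))
  else data.frame(metabolite_id = character(), n_paths = integer())
  rownames(ann) <- NULL
  list(annotations = ann, paths = paths, metabolite_summary = summary)
}
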