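#' Run the full cross-pathway link-inference pipeline
#'
#' Orchestrates every stage from one configuration: differential
#' classification, confidence filtering, context networks, topology/IIN
#' report, path enumeration and context filtering, weighting, Model 1 and
#' Model 2 selection, optional perturbation scan, and metabolite mapping.
#' Per-stage TSV artifacts are written to `outdir` with a header comment
#' carrying the seed and a hash of the configuration, plus a run log and
#' a per-type selection summary. Identical configuration and seed
#' reproduce byte-identical outputs.
#'
#' The configuration is a named list (or a YAML file path) with:
#' \describe{
#'   \item{synthetic}{list of [generate_universe()] /
#'     [generate_expression()] parameters; when present the universe is
#'     simulated. Otherwise `inputs` must give file paths.}
#'   \item{inputs}{list of paths: `ppi`, `tf`, `mir`, `expression`,
#'     `sample_labels`, `pathways` (GMT), `node_annotations`,
#'     `metabolites`, `mir_status`.}
#'   \item{modules}{subset of `c("S", "TF", "miR")` (default all three
#'     that have a layer).}
#'   \item{thresholds}{overrides for [crossmet_config()] keys.}
#'   \item{perturb}{logical; run the knockout scan on the selected paths
#'     (default FALSE).}
#'   \item{seed}{integer seed (default 1).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param outdir Output directory.
#' @return List of class `crossmet_run` with all stage objects and the
#'   vector of files written.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  cfg <- do.call(crossmet_config, as.list(config$thresholds %||% list()))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # resolve inputs before any compute
  if (is.null(config$synthetic)) {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs either `synthetic` or `inputs`")
    for (key in c("ppi", "expression", "sample_labels")) {
      if (is.null(inp[[key]])) stop("config inputs missing required key: ", key)
      if (!file.exists(inp[[key]])) stop("input file not found: ", inp[[key]])
    }
    for (key in setdiff(names(inp), "")) {
      if (!is.null(inp[[key]]) && !file.exists(inp[[key]]))
        stop("input file not found: ", inp[[key]])
    }
  }

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  hdr <- c(paste0("config_hash=", cfg_hash), paste0("seed=", seed))
  files <- c(config = cfg_path)

  universe <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gen_args <- syn[intersect(names(syn), names(formals(generate_universe)))]
    gen_args$seed <- seed
    universe <- do.call(generate_universe, gen_args)
    exp_args <- syn[intersect(names(syn),
                              setdiff(names(formals(generate_expression)),
                                      c("universe", "seed")))]
    exp_args$universe <- universe
    exp_args$seed <- seed + 1L
    sim <- do.call(generate_expression, exp_args)
    base_raw <- universe$network
    expr <- sim$expr
    mir_calls <- sim$mir_calls
    pathways <- universe$pathways
    annotations <- universe$node_annotations
    metabolites <- universe$metabolites
    files["universe_dir"] <- file.path(outdir, "universe")
    write_universe(universe, files[["universe_dir"]], expr = expr)
  } else {
    inp <- config$inputs
    base_raw <- read_interaction_tables(inp$ppi, inp$tf, inp$mir)
    lab <- read_tsv(inp$sample_labels)
    expr <- read_expression_matrix(inp$expression,
                                   stats::setNames(lab$label, lab$sample_id))
    pathways <- if (!is.null(inp$pathways)) read_gmt(inp$pathways) else NULL
    annotations <- if (!is.null(inp$node_annotations))
      read_node_annotations(inp$node_annotations) else NULL
    metabolites <- if (!is.null(inp$metabolites))
      read_metabolite_table(inp$metabolites) else NULL
    mir_calls <- if (!is.null(inp$mir_status)) {
      ms <- read_tsv(inp$mir_status)
      regulation_calls(ms$entity_id, ms$status)
    } else NULL
  }

  # stage 1: differential classification
  calls <- classify_regulation(expr, cfg$fc_threshold, cfg$p_threshold)
  if (!is.null(mir_calls)) {
    mc <- mir_calls[, c("entity_id", "log2fc", "adj_p", "status")]
    calls <- rbind(calls, mc[!mc$entity_id %in% calls$entity_id, , drop = FALSE])
    class(calls) <- c("regulation_calls", "data.frame")
  }
  files["calls"] <- file.path(outdir, "regulation_calls.tsv")
  write_tsv(calls, files[["calls"]], hdr)

  # stage 2: confidence-filtered base network
  base <- build_hppin(base_raw, cfg$min_confidence)
  files["network"] <- file.path(outdir, "base_network_ppi.tsv")
  write_tsv(base$ppi, files[["network"]], hdr)

  # sources and destinations from pathway annotation
  if (is.null(pathways)) stop("a pathway annotation (GMT) is required")
  sources_s <- pathway_members(pathways, "signaling")
  destinations <- pathway_members(pathways, "metabolic")

  modules <- config$modules %||% c("S",
                                   if (nrow(base$tf)) "TF",
                                   if (nrow(base$mir)) "miR")
  modules <- intersect(c("S", "TF", "miR"), modules)

  results <- list()
  for (m in modules) {
    src <- switch(m, S = sources_s,
                  TF = unique(base$tf$source),
                  miR = unique(base$mir$source))
    res <- score_module(base, expr, calls, src, destinations, module = m,
                        config = cfg, annotations = annotations)
    results[[m]] <- res
    tag <- tolower(m)
    files[paste0("paths_", tag)] <- file.path(outdir, paste0("paths_", tag, ".tsv"))
    write_paths(res$paths, files[[paste0("paths_", tag)]], calls, hdr)
    files[paste0("pairs_", tag)] <- file.path(outdir, paste0("pairs_", tag, ".tsv"))
    write_tsv(res$pairs, files[[paste0("pairs_", tag)]], hdr)
    files[paste0("selected_", tag)] <- file.path(outdir,
                                                 paste0("selected_paths_", tag, ".tsv"))
    write_paths(res$selected, files[[paste0("selected_", tag)]], calls, hdr)
    if (!is.null(res$weighting)) {
      files[paste0("weights_", tag)] <- file.path(outdir,
                                                  paste0("node_weights_", tag, ".tsv"))
      write_tsv(res$weighting$records, files[[paste0("weights_", tag)]], hdr)
    }
    if (!is.null(res$weighting) && !is.null(res$weighting$topology)) {
      files[paste0("topology_", tag)] <- file.path(outdir,
                                                   paste0("topology_", tag, ".tsv"))
      write_topology_report(res$weighting$topology,
                            files[[paste0("topology_", tag)]])
    }
  }

  summary_tab <- do.call(rbind, lapply(names(results), function(m)
    cbind(module = m, results[[m]]$summary)))
  files["summary"] <- file.path(outdir, "selection_summary.tsv")
  write_tsv(summary_tab, files[["summary"]], hdr)

  perturb <- NULL
  if (isTRUE(config$perturb)) {
    any_selected <- any(vapply(results, function(r) nrow(r$selected) > 0,
                               logical(1)))
    if (any_selected) {
      perturb <- perturbation_scan(
        base, expr, calls,
        sources = list(S = sources_s, TF = unique(base$tf$source),
                       miR = unique(base$mir$source)),
        destinations = destinations, modules = names(results),
        config = cfg, annotations = annotations)
      files["perturbation"] <- file.path(outdir, "perturbation.tsv")
      write_tsv(perturb$table, files[["perturbation"]], hdr)
    }
  }

  metab <- NULL
  if (!is.null(metabolites)) {
    all_selected <- do.call(rbind, lapply(results, function(r)
      as.data.frame(r$selected)))
    metab <- map_metabolites(all_selected, metabolites, calls)
    files["metabolites"] <- file.path(outdir, "metabolite_annotations.tsv")
    write_tsv(metab$annotations, files[["metabolites"]], hdr)
  }

  files["log"] <- file.path(outdir, "run_log.txt")
  writeLines(c(paste0("crossmet ", as.character(utils::packageVersion("crossmet"))),
               paste0("R ", R.version$major, ".", R.version$minor),
               paste0("seed=", seed),
               paste0("config_hash=", cfg_hash),
               paste0("modules=", paste(names(results), collapse = ",")),
               paste0("stages=", paste(names(files), collapse = ","))),
             files[["log"]])

  structure(list(config = config, thresholds = cfg, seed = seed,
                 universe = universe, expr = expr, calls = calls,
                 base = base, pathways = pathways, results = results,
                 perturbation = perturb, metabolites = metab,
                 summary = summary_tab, files = files),
            class = "crossmet_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crossmet_run <- function(x, ...) {
  cat(sprintf("<crossmet_run seed=%d> modules: %s\n", x$seed,
              paste(names(x$results), collapse = ", ")))
  print(x$summary)
  invisible(x)
}
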