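#' Generate a seeded synthetic multi-omic universe
#'
#' Builds a complete synthetic input set with the statistical structure
#' the analysis assumes: a scale-free (preferential-attachment) PPI
#' backbone with confidence scores in [0.7, 1], TF->target and
#' miRNA->target regulatory layers, signaling and metabolic pathway
#' membership, per-node biological annotations (rate-limiting enzyme,
#' signaling cross-talk), a deregulated-metabolite table, and a set of
#' planted ground-truth source-to-enzyme paths whose edges are injected
#' into the PPI layer and whose terminals are destined to be
#' deregulated. All randomness flows from the single `seed`.
#'
#' @param n_proteins Number of protein nodes (>= 50; default 300).
#' @param attachment_m Edges attached per new node in the
#'   preferential-attachment backbone (default 2).
#' @param n_tfs,n_mirs Number of TFs / miRNAs (defaults 15 each).
#' @param n_signaling_pathways,n_metabolic_pathways Pathway counts
#'   (defaults 3 and 5).
#' @param n_planted Number of planted source-destination paths
#'   (default 10).
#' @param max_intermediates Maximum interior proteins per planted path
#'   (default 3; planted paths use 1..max_intermediates).
#' @param frac_background_dereg Fraction of non-planted proteins destined
#'   to be differentially expressed (default 0.2).
#' @param seed Integer seed (default 7).
#' @return Object of class `synthetic_universe`: list with `network`
#'   (layered_network), `pathways` (pathway_annotation),
#'   `node_annotations`, `metabolites` (metabolite_table), `mir_calls`
#'   (regulation_calls for miRNAs), `planted` (cross_paths),
#'   `true_status` (named intent vector over proteins), `sources`,
#'   `destinations`, and `params`.
#' @export
generate_universe <- function(n_proteins = 300, attachment_m = 2,
                              n_tfs = 15, n_mirs = 15,
                              n_signaling_pathways = 3,
                              n_metabolic_pathways = 5,
                              n_planted = 10, max_intermediates = 3,
                              frac_background_dereg = 0.25,
                              interior_status = "UP", seed = 7) {
  if (n_proteins < 50) stop("n_proteins must be >= 50")
  if (n_planted < 0) stop("n_planted must be >= 0")
  set.seed(seed)
  prot <- sprintf("P%04d", seq_len(n_proteins))

  # planted corridor interiors are dedicated nodes injected along with the
  # planted edges; the scale-free backbone covers the remaining proteins
  ks <- if (n_planted > 0) ((seq_len(n_planted) - 1L) %% max_intermediates) + 1L
        else integer()
  n_int <- sum(ks)
  n_backbone <- n_proteins - n_int
  if (n_backbone < 40) stop("not enough proteins for backbone plus interiors")
  backbone <- prot[seq_len(n_backbone)]
  interior_reserve <- prot[n_backbone + seq_len(n_int)]

  g <- igraph::sample_pa(n_backbone, power = 1, m = attachment_m,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi <- data.frame(protein_a = backbone[el[, 1L]],
                    protein_b = backbone[el[, 2L]],
                    confidence = stats::runif(nrow(el), 0.7, 1),
                    stringsAsFactors = FALSE)

  # disjoint signaling-source and metabolic-destination pools, drawn from
  # non-hub proteins: pathway-specific signaling proteins and metabolic
  # enzymes are rarely the network's core-machinery super-hubs, which
  # would otherwise dominate every degree-driven statistic
  n_sig_pool <- min(20 * n_signaling_pathways, floor(n_backbone / 4))
  n_met_pool <- min(15 * n_metabolic_pathways, floor(n_backbone / 4))
  deg <- stats::setNames(igraph::degree(g), backbone)
  non_hub <- backbone[deg <= stats::quantile(deg, 0.9)]
  pools <- sample(non_hub, n_sig_pool + n_met_pool)
  sig_pool <- pools[seq_len(n_sig_pool)]
  met_pool <- pools[n_sig_pool + seq_len(n_met_pool)]

  sig_names <- sprintf("sig_pathway_%02d", seq_len(n_signaling_pathways))
  met_names <- sprintf("met_pathway_%02d", seq_len(n_metabolic_pathways))
  met_categories <- c("nucleotide metabolism", "amino acid metabolism",
                      "lipid metabolism", "carbohydrate metabolism",
                      "cofactor metabolism", "energy metabolism")
  pw <- list()
  for (i in seq_len(n_signaling_pathways)) {
    pw[[sig_names[i]]] <- list(
      name = sig_names[i], class = "signaling", category = "signal transduction",
      members = sort(sample(sig_pool, min(20, length(sig_pool)))))
  }
  for (i in seq_len(n_metabolic_pathways)) {
    pw[[met_names[i]]] <- list(
      name = met_names[i], class = "metabolic",
      category = met_categories[((i - 1L) %% length(met_categories)) + 1L],
      members = sort(sample(met_pool, min(15, length(met_pool)))))
  }
  pathways <- pathway_annotation(pw)
  sources <- pathway_members(pathways, "signaling")
  destinations <- pathway_members(pathways, "metabolic")

  plain <- setdiff(backbone, c(sig_pool, met_pool))
  tfs <- sample(plain, n_tfs)
  plain <- setdiff(plain, tfs)
  tf_edges <- do.call(rbind, lapply(tfs, function(tf) {
    data.frame(source = tf,
               target = sample(setdiff(prot, tf), sample(3:8, 1)),
               stringsAsFactors = FALSE)
  }))
  mirs <- sprintf("miR%03d", seq_len(n_mirs))
  mir_edges <- do.call(rbind, lapply(mirs, function(mr) {
    data.frame(source = mr, target = sample(prot, sample(3:8, 1)),
               stringsAsFactors = FALSE)
  }))

  # planted source -> destination paths over fresh interior nodes
  planted_paths <- list()
  interiors_all <- character()
  if (n_planted > 0) {
    pair_src <- sample(sources, n_planted, replace = n_planted > length(sources))
    pair_dst <- sample(destinations, n_planted,
                       replace = n_planted > length(destinations))
    pool_int <- interior_reserve
    used <- 0L
    extra <- NULL
    for (p in seq_len(n_planted)) {
      # planted path lengths cycle over the allowed range so every
      # path-type stratum carries ground truth
      k <- ks[p]
      ints <- pool_int[used + seq_len(k)]
      used <- used + k
      nodes <- c(pair_src[p], ints, pair_dst[p])
      planted_paths[[p]] <- nodes
      interiors_all <- c(interiors_all, ints)
      a <- nodes[-length(nodes)]; b <- nodes[-1L]
      extra <- rbind(extra, data.frame(
        protein_a = a, protein_b = b,
        confidence = stats::runif(length(a), 0.85, 1),
        stringsAsFactors = FALSE))
    }
    ppi <- rbind(ppi, extra)
  }
  planted <- cross_paths_from_list(planted_paths, "S")

  net <- layered_network(ppi = ppi, tf = tf_edges, mir = mir_edges,
                         extra_nodes = prot)

  # intended differential status: planted terminals deregulated, planted
  # interiors neutral, plus random background deregulation
  # Planted links are high-expression routes: destinations are upregulated
  # enzymes (mass-action flow is directed toward abundant partners, so a
  # downregulated terminal cannot carry a high-probability path), sources
  # may be deregulated either way (a source's own abundance does not enter
  # its outgoing transition probabilities), and interiors are neutral or
  # upregulated.
  true_status <- stats::setNames(rep("NEUTRAL", n_proteins), prot)
  if (n_planted > 0) {
    true_status[unique(planted$source)] <- "UP"
    true_status[unique(planted$destination)] <- "UP"
    true_status[interiors_all] <- interior_status
  }
  bg_pool <- setdiff(prot, c(unique(planted$source),
                             unique(planted$destination), interiors_all))
  n_bg <- round(frac_background_dereg * length(bg_pool))
  bg <- sample(bg_pool, n_bg)
  true_status[bg] <- sample(c("UP", "DOWN"), n_bg, replace = TRUE)

  mir_status <- sample(c("UP", "DOWN", "NEUTRAL"), n_mirs, replace = TRUE,
                       prob = c(0.2, 0.2, 0.6))
  mir_calls <- regulation_calls(mirs, mir_status)

  node_ann <- data.frame(
    node_id = prot,
    rle = prot %in% sample(met_pool, round(0.3 * length(met_pool))),
    sc = vapply(prot, function(p) length(pathways_of(pathways, p,
                                                     "signaling")) >= 2,
                logical(1)),
    stringsAsFactors = FALSE)

  met_enzymes <- sample(destinations, max(1L, round(0.6 * length(destinations))))
  met_rows <- do.call(rbind, lapply(seq_along(met_enzymes), function(i) {
    n_met <- sample(1:2, 1)
    data.frame(metabolite_id = sprintf("Met%03d_%d", i, seq_len(n_met)),
               status = sample(c("UP", "DOWN"), n_met, replace = TRUE),
               enzyme_id = met_enzymes[i],
               role = sample(c("substrate", "product"), n_met, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(network = net, pathways = pathways,
                 node_annotations = node_ann,
                 metabolites = metabolite_table(met_rows),
                 mir_calls = mir_calls, planted = planted,
                 true_status = true_status,
                 planted_interiors = unique(interiors_all),
                 sources = sources, destinations = destinations,
                 params = list(n_proteins = n_proteins,
                               attachment_m = attachment_m, n_tfs = n_tfs,
                               n_mirs = n_mirs,
                               n_signaling_pathways = n_signaling_pathways,
                               n_metabolic_pathways = n_metabolic_pathways,
                               n_planted = n_planted,
                               max_intermediates = max_intermediates,
                               frac_background_dereg = frac_background_dereg,
                               seed = seed)),
            class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf("<synthetic_universe seed=%d> ", x$params$seed))
  print(x$network)
  cat(sprintf("  %d planted paths, %d sources, %d destinations\n",
              nrow(x$planted), length(x$sources), length(x$destinations)))
  invisible(x)
}

#' Simulate tumor/normal expression for a synthetic universe
#'
#' Draws a log-normal baseline abundance per protein, shifts the tumor
#' mean of every intended UP/DOWN gene by +/- `effect_log2fc` on the
#' log2 scale, places planted path interiors in the top abundance
#' quartile (so mass-action transitions favor the planted routes), and
#' adds Gaussian log-scale noise with standard deviation `sigma`
#' (`sigma = 0` gives the noiseless limit).
#'
#' @param universe A [generate_universe()] result.
#' @param effect_log2fc Planted log2 fold change (default 2.5).
#' @param sigma Log2-scale noise standard deviation (default 0.4).
#' @param n_tumor,n_normal Sample counts (defaults 10 each).
#' @param seed Integer seed (default: universe seed + 1).
#' @return List with `expr` (an [expression_matrix()]), `mir_calls`
#'   (emitted directly from the universe) and `true_status`.
#' @export
generate_expression <- function(universe, effect_log2fc = 2.5, sigma = 0.4,
                                n_tumor = 10, n_normal = 10, seed = NULL,
                                interior_quantile = 0.75) {
  stopifnot(inherits(universe, "synthetic_universe"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(seed)) seed <- universe$params$seed + 1L
  set.seed(seed)
  prot <- universe$network$nodes$id[universe$network$nodes$kind == "protein"]
  n <- length(prot)
  mu <- stats::setNames(stats::runif(n, 5, 9), prot)  # baseline log2 abundance
  # the planted corridor (interiors and destination enzyme) is a
  # high-expression route: baseline abundance in the top band
  corridor <- c(universe$planted_interiors,
                unique(universe$planted$destination))
  corridor <- intersect(corridor, prot)
  if (length(corridor)) {
    qlo <- stats::quantile(mu, interior_quantile)
    mu[corridor] <- stats::runif(length(corridor), qlo, max(mu))
  }
  shift <- stats::setNames(rep(0, n), prot)
  st <- universe$true_status[prot]
  shift[st == "UP"] <- effect_log2fc
  shift[st == "DOWN"] <- -effect_log2fc
  samp <- c(sprintf("T%02d", seq_len(n_tumor)), sprintf("N%02d", seq_len(n_normal)))
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samp)
  vals <- matrix(0, n, length(samp), dimnames = list(prot, samp))
  for (j in seq_along(samp)) {
    m <- if (labels[j] == "tumor") mu + shift else mu
    noise <- if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
    vals[, j] <- 2^(m + noise)
  }
  list(expr = expression_matrix(vals, labels),
       mir_calls = universe$mir_calls,
       true_status = universe$true_status)
}

#' Write a synthetic universe to disk in the pipeline's input dialects
#'
#' Emits the TSV edge lists, GMT pathway file, node-annotation and
#' metabolite tables, miRNA status table and (optionally) the expression
#' matrix in exactly the formats the package's readers consume.
#'
#' @param universe A `synthetic_universe`.
#' @param dir Output directory (created if needed).
#' @param expr Optional `expr_matrix` from [generate_expression()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_universe <- function(universe, dir, expr = NULL) {
  stopifnot(inherits(universe, "synthetic_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(ppi = file.path(dir, "ppi.tsv"), tf = file.path(dir, "tf.tsv"),
         mir = file.path(dir, "mir.tsv"),
         pathways = file.path(dir, "pathways.gmt"),
         node_annotations = file.path(dir, "node_annotations.tsv"),
         metabolites = file.path(dir, "metabolites.tsv"),
         mir_calls = file.path(dir, "mir_status.tsv"),
         planted = file.path(dir, "planted_paths.tsv"))
  write_interaction_tables(universe$network, f[["ppi"]], f[["tf"]], f[["mir"]])
  write_gmt(universe$pathways, f[["pathways"]])
  write_tsv(universe$node_annotations, f[["node_annotations"]])
  write_tsv(universe$metabolites, f[["metabolites"]])
  write_tsv(universe$mir_calls, f[["mir_calls"]])
  write_tsv(as.data.frame(universe$planted), f[["planted"]])
  if (!is.null(expr)) {
    f[["expression"]] <- file.path(dir, "expression.tsv")
    write_expression_matrix(expr, f[["expression"]])
    f[["sample_labels"]] <- file.path(dir, "sample_labels.tsv")
    write_tsv(data.frame(sample_id = names(expr$labels),
                         label = unname(expr$labels)), f[["sample_labels"]])
  }
  invisible(f)
}
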