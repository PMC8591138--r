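#' Score cross-pathway paths under the HMM-style model
#'
#' Each path is scored as a hidden-Markov chain product: transitions are
#' the mass-action probabilities of [transition_probabilities()]
#' (regulatory TF->TG / miR->TG first edges carry probability 1), and
#' every node emits e_i = beta * eff_norm_i + (1 - beta) * entropy_norm_i
#' (the min-max normalized effect-on-node and local entropy), floored at
#' 1e-12. The raw score is the log of the chain product:
#' sum over edges of log p + sum over all path nodes of log e.
#' Nodes without a weighting record (miRNAs and sources outside the PPI
#' subnetwork) emit 1.
#'
#' @param paths A `cross_paths` data.frame.
#' @param weighting A [compute_weighting()] result (or a list with `tm`
#'   and `records`).
#' @param beta Emission blend in [0, 1] between effect-on-node (beta) and
#'   entropy (1 - beta); default 0.5.
#' @return `paths` with added columns `log_score` and `prob_score`
#'   (= exp(log_score)), class `scored_paths`.
#' @export
score_paths <- function(paths, weighting, beta = 0.5) {
  stopifnot(inherits(paths, "cross_paths") || is.data.frame(paths))
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  tm <- weighting$tm
  rec <- weighting$records
  eps <- 1e-12
  emis <- pmax(beta * rec$eff_norm + (1 - beta) * rec$entropy_norm, eps)
  emis <- stats::setNames(emis, rec$node)
  pmap <- stats::setNames(tm$edges$p, paste0(tm$edges$from, "\r", tm$edges$to))
  out <- as.data.frame(paths)
  if (!nrow(out)) {
    out$log_score <- numeric(0); out$prob_score <- numeric(0)
    class(out) <- c("scored_paths", "cross_paths", "data.frame")
    return(out)
  }
  node_lists <- strsplit(out$nodes, "|", fixed = TRUE)
  logs <- vapply(seq_len(nrow(out)), function(i) {
    nd <- node_lists[[i]]
    k <- length(nd)
    lp <- 0
    start_edge <- 1L
    if (out$module[i] != "S") start_edge <- 2L  # regulatory first edge, p = 1
    if (k >= 2L && start_edge <= k - 1L) {
      for (t in start_edge:(k - 1L)) {
        p <- pmap[paste0(nd[t], "\r", nd[t + 1L])]
        if (is.na(p))
          stop("edge absent from transition model: ", nd[t], " -- ", nd[t + 1L])
        lp <- lp + log(max(p, eps))
      }
    }
    e <- emis[nd]
    e[is.na(e)] <- 1
    lp + sum(log(e))
  }, numeric(1))
  out$log_score <- logs
  out$prob_score <- exp(logs)
  class(out) <- c("scored_paths", "cross_paths", "data.frame")
  out
}

#' Stratified z-scores
#'
#' Standardizes values within strata: z = (x - mean) / sd using the
#' sample standard deviation. Strata with fewer than 3 members cannot
#' support a meaningful z; their items get z = 0 and a pass-through flag
#' so downstream selection does not silently drop them. A zero-sd
#' stratum gets all z = 0 (no pass-through).
#'
#' @param values Numeric vector.
#' @param strata Character/factor vector of the same length.
#' @return data.frame with columns `z` and `passthrough`.
#' @export
stratified_zscore <- function(values, strata) {
  stopifnot(length(values) == length(strata), all(is.finite(values)))
  z <- numeric(length(values))
  pass <- logical(length(values))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 3L) {
      pass[idx] <- TRUE
      next
    }
    sd <- stats::sd(values[idx])
    if (sd > 0) z[idx] <- (values[idx] - mean(values[idx])) / sd
  }
  data.frame(z = z, passthrough = pass)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Model 1: select significant source-destination pairs
#'
#' Aggregates every (source, destination, module) pair's path scores into
#' a total path probability (log-sum-exp of the member log scores,
#' forward-style aggregation over alternative routes), assigns each pair
#' to the stratum of its shortest member path's type label, standardizes
#' within strata and selects pairs with z >= `z_cutoff` (or stratum
#' pass-through).
#'
#' @param scored A `scored_paths` data.frame from [score_paths()].
#' @param z_cutoff Selection threshold on the stratified z (default 1).
#' @return data.frame of class `scored_pairs`: `module`, `source`,
#'   `destination`, `n_paths`, `log_score`, `stratum`, `z`,
#'   `passthrough`, `selected`.
#' @export
model1_select_pairs <- function(scored, z_cutoff = 1) {
  stopifnot(inherits(scored, "scored_paths"))
  if (!nrow(scored)) {
    out <- data.frame(module = character(), source = character(),
                      destination = character(), n_paths = integer(),
                      log_score = numeric(), stratum = character(),
                      z = numeric(), passthrough = logical(),
                      selected = logical(), stringsAsFactors = FALSE)
    class(out) <- c("scored_pairs", "data.frame")
    return(out)
  }
  key <- paste(scored$module, scored$source, scored$destination, sep = "\r")
  n_nodes <- lengths(strsplit(scored$nodes, "|", fixed = TRUE))
  pairs <- lapply(split(seq_len(nrow(scored)), key), function(idx) {
    shortest <- idx[which.min(n_nodes[idx])]
    data.frame(module = scored$module[idx[1L]],
               source = scored$source[idx[1L]],
               destination = scored$destination[idx[1L]],
               n_paths = length(idx),
               log_score = logsumexp(scored$log_score[idx]),
               stratum = scored$type_label[shortest],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  zs <- stratified_zscore(out$log_score, out$stratum)
  out$z <- zs$z
  out$passthrough <- zs$passthrough
  out$selected <- out$z >= z_cutoff | out$passthrough
  out <- out[order(out$module, out$source, out$destination), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Model 2: select significant paths within selected pairs
#'
#' Within every Model-1-selected pair, keeps the paths whose
#' probability-scale score is at least `frac` times the best path's
#' probability-scale score in that pair.
#'
#' @param pairs A `scored_pairs` table from [model1_select_pairs()].
#' @param scored The `scored_paths` table the pairs were built from.
#' @param frac Within-pair score fraction (default 0.8).
#' @return The selected subset of `scored` with an added `pair_z` column,
#'   class `scored_paths`.
#' @export
model2_select_paths <- function(pairs, scored, frac = 0.8) {
  stopifnot(inherits(pairs, "scored_pairs"), inherits(scored, "scored_paths"))
  if (frac < 0 || frac > 1) stop("frac must lie in [0, 1]")
  sel_pairs <- pairs[pairs$selected, , drop = FALSE]
  if (!nrow(sel_pairs) || !nrow(scored)) {
    out <- scored[0, , drop = FALSE]
    out$pair_z <- numeric(0)
    return(out)
  }
  pk <- paste(sel_pairs$module, sel_pairs$source, sel_pairs$destination,
              sep = "\r")
  sk <- paste(scored$module, scored$source, scored$destination, sep = "\r")
  keep <- logical(nrow(scored))
  for (i in seq_along(pk)) {
    idx <- which(sk == pk[i])
    best <- max(scored$prob_score[idx])
    keep[idx] <- scored$prob_score[idx] >= frac * best
  }
  out <- scored[keep, , drop = FALSE]
  out$pair_z <- sel_pairs$z[match(sk[keep], pk)]
  rownames(out) <- NULL
  out
}

#' Summarize pair/path counts per path type
#'
#' Produces the per-type tally of candidate pairs and paths and of those
#' surviving Model 1 and Model 2 — the shape in which selection results
#' are conventionally reported.
#'
#' @param scored All scored paths.
#' @param pairs Model 1 output.
#' @param selected Model 2 output.
#' @return data.frame: `type_label`, `n_pairs`, `n_paths`,
#'   `n_pairs_selected`, `n_paths_selected`.
#' @export
selection_summary <- function(scored, pairs, selected) {
  types <- sort(unique(c(scored$type_label, pairs$stratum)))
  if (!length(types))
    return(data.frame(type_label = character(), n_pairs = integer(),
                      n_paths = integer(), n_pairs_selected = integer(),
                      n_paths_selected = integer(), stringsAsFactors = FALSE))
  pair_key <- function(df) paste(df$module, df$source, df$destination)
  out <- do.call(rbind, lapply(types, function(tp) {
    sp <- scored[scored$type_label == tp, , drop = FALSE]
    sel <- selected[selected$type_label == tp, , drop = FALSE]
    data.frame(type_label = tp,
               n_pairs = length(unique(pair_key(sp))),
               n_paths = nrow(sp),
               n_pairs_selected = sum(pairs$selected & pairs$stratum == tp),
               n_paths_selected = nrow(sel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
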