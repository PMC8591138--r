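#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values, capped at 1. Thin,
#' validated wrapper around the standard implementation so the adjustment
#' used across the package is a single auditable call site.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify tumor-vs-normal differential regulation
#'
#' For each gene, computes log2 fold change as the difference of mean
#' log2(x + 1) between tumor and normal samples, tests the difference with
#' Welch's unequal-variance two-sample t-test, adjusts p-values with
#' Benjamini-Hochberg across genes, and assigns a status:
#' \describe{
#'   \item{UP}{log2FC >= +`fc_threshold` and adjusted p <= `p_threshold`}
#'   \item{DOWN}{log2FC <= -`fc_threshold` and adjusted p <= `p_threshold`}
#'   \item{NEUTRAL}{|log2FC| < `fc_threshold` (no p requirement)}
#'   \item{ABSENT}{|log2FC| >= `fc_threshold` but adjusted p above the
#'     threshold; such genes are excluded from all context networks}
#' }
#' Genes with zero variance in both groups get p = 1.
#'
#' @param expr An [expression_matrix()] with >= 2 tumor and >= 2 normal
#'   samples.
#' @param fc_threshold Positive log2 fold-change threshold (default 1.5;
#'   use 1.0 for miRNA expression).
#' @param p_threshold Adjusted-p cutoff (default 0.05).
#' @return data.frame of class `regulation_calls` with columns
#'   `entity_id`, `log2fc`, `adj_p`, `status`.
#' @export
classify_regulation <- function(expr, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  tum <- expr$labels == "tumor"
  if (sum(tum) < 2 || sum(!tum) < 2)
    stop("need >= 2 tumor and >= 2 normal samples")
  lx <- log2(expr$values + 1)
  lt <- lx[, tum, drop = FALSE]
  ln <- lx[, !tum, drop = FALSE]
  log2fc <- rowMeans(lt) - rowMeans(ln)
  pvals <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lt[i, ]; b <- ln[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) return(1)
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, numeric(1))
  adj_p <- benjamini_hochberg(pvals)
  calls <- regulation_status(log2fc, adj_p, fc_threshold, p_threshold)
  out <- data.frame(entity_id = rownames(expr$values),
                    log2fc = log2fc, adj_p = adj_p, status = calls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Threshold rule mapping (log2FC, adjusted p) to a status
#'
#' Pure rule table shared by [classify_regulation()] and usable directly
#' on precomputed statistics.
#'
#' @param log2fc,adj_p Numeric vectors (recycled to common length).
#' @param fc_threshold,p_threshold As in [classify_regulation()].
#' @return Character vector of UP/DOWN/NEUTRAL/ABSENT.
#' @export
regulation_status <- function(log2fc, adj_p, fc_threshold = 1.5,
                              p_threshold = 0.05) {
  n <- max(length(log2fc), length(adj_p))
  log2fc <- rep_len(log2fc, n); adj_p <- rep_len(adj_p, n)
  status <- rep("ABSENT", n)
  status[abs(log2fc) < fc_threshold] <- "NEUTRAL"
  sig <- adj_p <= p_threshold
  status[log2fc >= fc_threshold & sig] <- "UP"
  status[log2fc <= -fc_threshold & sig] <- "DOWN"
  status
}

#' Build a calls table directly from statuses
#'
#' Convenience constructor for externally supplied statuses (e.g. miRNA
#' calls taken from a published table rather than expression).
#'
#' @param entity_id Character vector.
#' @param status UP/DOWN/NEUTRAL/ABSENT per entity.
#' @param log2fc,adj_p Optional numeric vectors (NA if unknown).
#' @return A `regulation_calls` data.frame.
#' @export
regulation_calls <- function(entity_id, status, log2fc = NA_real_,
                             adj_p = NA_real_) {
  stopifnot(all(status %in% c("UP", "DOWN", "NEUTRAL", "ABSENT")))
  if (anyDuplicated(entity_id)) stop("duplicate entity ids")
  out <- data.frame(entity_id = as.character(entity_id),
                    log2fc = rep_len(log2fc, length(entity_id)),
                    adj_p = rep_len(adj_p, length(entity_id)),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Merge regulation calls across datasets
#'
#' Union of per-dataset calls. An entity called UP in one dataset and DOWN
#' in another is flagged as a conflict and assigned the direction of the
#' largest |log2FC|; a deregulated call beats NEUTRAL, which beats ABSENT.
#'
#' @param ... `regulation_calls` data.frames (or a single list of them).
#' @return Merged `regulation_calls` with a logical `conflict` column.
#' @export
merge_regulation_calls <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "data.frame"))
    sets <- sets[[1L]]
  all <- do.call(rbind, lapply(sets, function(s)
    s[, c("entity_id", "log2fc", "adj_p", "status")]))
  rank <- c(ABSENT = 0L, NEUTRAL = 1L, DOWN = 2L, UP = 2L)
  out <- do.call(rbind, lapply(split(all, all$entity_id), function(g) {
    dereg <- g[g$status %in% c("UP", "DOWN"), , drop = FALSE]
    conflict <- length(unique(dereg$status)) > 1L
    if (nrow(dereg)) {
      best <- dereg[which.max(abs(dereg$log2fc)), , drop = FALSE]
    } else {
      best <- g[which.max(rank[g$status]), , drop = FALSE]
    }
    best$conflict <- conflict
    best
  }))
  rownames(out) <- NULL
  if (any(out$conflict))
    message(sum(out$conflict), " entit(ies) with conflicting directions; ",
            "direction of largest |log2FC| kept")
  class(out) <- c("regulation_calls", "data.frame")
  out
}

# Named status vector over a node universe; nodes without a call -> ABSENT.
status_lookup <- function(calls, ids) {
  st <- stats::setNames(rep("ABSENT", length(ids)), ids)
  hit <- intersect(ids, calls$entity_id)
  st[hit] <- calls$status[match(hit, calls$entity_id)]
  st
}
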