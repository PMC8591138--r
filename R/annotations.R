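#' Pathway annotation set
#'
#' Maps pathway ids to a display name, a class (`signaling` or
#' `metabolic`), a free-text category (e.g. "nucleotide metabolism") and a
#' member node set. A node may belong to any number of pathways.
#'
#' @param pathways Named list; each element a list with fields `name`,
#'   `class`, `category`, `members` (character vector).
#' @return Object of class `pathway_annotation` (the validated list).
#' @export
pathway_annotation <- function(pathways) {
  stopifnot(is.list(pathways), !is.null(names(pathways)),
            !anyDuplicated(names(pathways)))
  for (id in names(pathways)) {
    p <- pathways[[id]]
    if (!all(c("name", "class", "category", "members") %in% names(p)))
      stop("pathway '", id, "' must have name, class, category, members")
    if (!p$class %in% c("signaling", "metabolic"))
      stop("pathway '", id, "' class must be 'signaling' or 'metabolic'")
  }
  structure(pathways, class = "pathway_annotation")
}

#' Read pathway sets from a GMT file
#'
#' One pathway per line: `id<TAB>class:category<TAB>member1<TAB>member2...`.
#' The description field encodes the pathway class (signaling/metabolic)
#' and category, separated by a colon.
#'
#' @param path GMT file path.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    desc <- strsplit(f[2L], ":", fixed = TRUE)[[1L]]
    out[[f[1L]]] <- list(name = f[1L],
                         class = desc[1L],
                         category = if (length(desc) > 1L)
                           paste(desc[-1L], collapse = ":") else "",
                         members = unique(f[-(1:2)]))
  }
  pathway_annotation(out)
}

#' Write pathway sets to a GMT file
#'
#' @param annot A `pathway_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annot, path) {
  stopifnot(inherits(annot, "pathway_annotation"))
  lines <- vapply(names(annot), function(id) {
    p <- annot[[id]]
    paste(c(id, paste0(p$class, ":", p$category), p$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Member ids of pathways of a given class
#'
#' @param annot A `pathway_annotation`.
#' @param class `"signaling"` or `"metabolic"`.
#' @return Character vector of node ids (union over matching pathways).
#' @export
pathway_members <- function(annot, class) {
  stopifnot(inherits(annot, "pathway_annotation"))
  unique(unlist(lapply(unclass(annot), function(p)
    if (p$class == class) p$members else character())))
}

#' Pathways containing a node
#' @param annot A `pathway_annotation`.
#' @param id Node id.
#' @param class Optional class filter.
#' @return Character vector of pathway ids.
#' @export
pathways_of <- function(annot, id, class = NULL) {
  hit <- vapply(unclass(annot), function(p)
    (is.null(class) || p$class == class) && id %in% p$members, logical(1))
  names(annot)[hit]
}

#' Read the per-node biological annotation table
#'
#' TSV with columns `node_id`, `rle` (rate-limiting enzyme flag), `sc`
#' (signaling cross-talk flag); flags are 0/1 or TRUE/FALSE.
#'
#' @param path TSV path.
#' @return data.frame with logical `rle`, `sc` columns.
#' @export
read_node_annotations <- function(path) {
  tab <- read_tsv(path)
  need <- c("node_id", "rle", "sc")
  if (!all(need %in% colnames(tab)))
    stop("node annotation table must have columns: ", paste(need, collapse = ", "))
  to_flag <- function(x) {
    if (is.logical(x)) x
    else if (is.numeric(x)) x != 0
    else toupper(as.character(x)) %in% c("TRUE", "1", "YES")
  }
  tab$rle <- to_flag(tab$rle)
  tab$sc <- to_flag(tab$sc)
  if (anyDuplicated(tab$node_id)) stop("duplicate node_id in annotation table")
  tab[, need]
}

#' Metabolite-enzyme association table
#'
#' Rows of (metabolite_id, status, enzyme_id, role) describing deregulated
#' metabolites and the enzymes they are substrates or products of.
#' (metabolite, enzyme, role) triplets must be unique.
#'
#' @param df data.frame with columns `metabolite_id`, `status` (UP/DOWN),
#'   `enzyme_id`, `role` (substrate/product).
#' @return Validated data.frame of class `metabolite_table`.
#' @export
metabolite_table <- function(df) {
  need <- c("metabolite_id", "status", "enzyme_id", "role")
  if (!all(need %in% colnames(df)))
    stop("metabolite table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (!all(df$status %in% c("UP", "DOWN")))
    stop("metabolite status must be UP or DOWN")
  if (!all(df$role %in% c("substrate", "product")))
    stop("metabolite role must be 'substrate' or 'product'")
  key <- paste(df$metabolite_id, df$enzyme_id, df$role)
  if (anyDuplicated(key))
    stop("duplicate (metabolite, enzyme, role) triplet(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(df) <- NULL
  class(df) <- c("metabolite_table", "data.frame")
  df
}

#' Read a metabolite table from TSV
#' @param path TSV path with the [metabolite_table()] columns.
#' @return A `metabolite_table`.
#' @export
read_metabolite_table <- function(path) metabolite_table(read_tsv(path))
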