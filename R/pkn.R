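#' Construct a causal prior-knowledge network
#'
#' A causal PKN is a signed directed graph over protein, metabolite,
#' enzyme-instance and complex nodes. Edges carry a sign (+1 activation,
#' -1 inhibition) and a provenance tag recording which interaction layer
#' they came from.
#'
#' @param edges data.frame with columns `source`, `sign`, `target` and
#'   optionally `provenance` (default `"ppi"`). Signs must be -1 or +1 and
#'   self-loops are not allowed. Duplicate (source, sign, target) rows are
#'   collapsed, keeping the first provenance.
#' @param node_kind named character vector mapping node ids to one of
#'   `"protein"`, `"metabolite"`, `"enzyme_instance"`, `"complex"`. Nodes
#'   present in `edges` but absent here are classified by namespace:
#'   ids starting with `"metab__"` are metabolites, everything else protein.
#' @return object of class `causal_pkn`: list with elements `edges`
#'   (data.frame source/sign/target/provenance) and `node_kind` (named
#'   character covering every node that occurs in an edge).
#' @export
causal_pkn <- function(edges = NULL, node_kind = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), sign = integer(),
                        target = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "sign", "target")
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(edges$provenance)) edges$provenance <- rep("ppi", nrow(edges))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  edges$provenance <- as.character(edges$provenance)
  if (nrow(edges)) {
    if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be -1 or +1")
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(c(edges$source, edges$target))
  kind <- stats::setNames(
    ifelse(startsWith(nodes, "metab__"), "metabolite", "protein"), nodes)
  if (!is.null(node_kind) && length(node_kind)) {
    node_kind <- node_kind[intersect(names(node_kind), nodes)]
    kind[names(node_kind)] <- unname(node_kind)
  }
  bad <- setdiff(unique(kind), c("protein", "metabolite", "enzyme_instance",
                                 "complex"))
  if (length(bad)) stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  structure(list(edges = edges, node_kind = kind), class = "causal_pkn")
}

edge_key <- function(edges) {
  paste(edges$source, edges$sign, edges$target, sep = "\r")
}

#' @export
print.causal_pkn <- function(x, ...) {
  kinds <- table(factor(x$node_kind, levels = c("protein", "metabolite",
                                                "enzyme_instance", "complex")))
  cat("Causal prior-knowledge network\n")
  cat("  edges:", nrow(x$edges), "\n")
  cat("  nodes:", length(x$node_kind),
      sprintf("(%d protein, %d metabolite, %d enzyme instance, %d complex)\n",
              kinds[["protein"]], kinds[["metabolite"]],
              kinds[["enzyme_instance"]], kinds[["complex"]]))
  if (nrow(x$edges)) {
    cat("  provenance:",
        paste(sprintf("%s=%d", names(table(x$edges$provenance)),
                      as.integer(table(x$edges$provenance))), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.causal_pkn <- function(object, ...) {
  print(object)
  if (nrow(object$edges)) {
    cat("  sign balance: ",
        sum(object$edges$sign > 0), " activating / ",
        sum(object$edges$sign < 0), " inhibiting\n", sep = "")
  }
  invisible(object)
}

pkn_nodes <- function(pkn) names(pkn$node_kind)

#' Convert a PKN to an igraph object
#'
#' @param pkn a `causal_pkn`
#' @return directed `igraph` graph with edge attributes `sign`, `provenance`
#' @export
pkn_to_igraph <- function(pkn) {
  g <- igraph::graph_from_data_frame(
    pkn$edges[, c("source", "target")],
    directed = TRUE,
    vertices = data.frame(name = pkn_nodes(pkn), stringsAsFactors = FALSE))
  igraph::E(g)$sign <- pkn$edges$sign
  igraph::E(g)$provenance <- pkn$edges$provenance
  g
}

#' Read / write the SIF dialect
#'
#' The PKN is serialized as a (source, sign, target) table plus a node-kind
#' sidecar. Readers accept tab or ";" delimiters and an optional fourth
#' provenance column.
#'
#' @param path SIF file path (for [read_pkn_sif()]: the edge table).
#' @param node_path optional node-kind sidecar (columns node, kind).
#' @return [read_pkn_sif()] returns a `causal_pkn`.
#' @export
read_pkn_sif <- function(path, node_path = NULL) {
  first <- readLines(path, n = 1L)
  sepc <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else "\t"
  tab <- utils::read.table(path, sep = sepc, header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 3L) stop("SIF table needs at least 3 columns")
  names(tab)[1:3] <- c("source", "sign", "target")
  if (ncol(tab) >= 4L) names(tab)[4] <- "provenance"
  nk <- NULL
  if (!is.null(node_path) && file.exists(node_path)) {
    nt <- utils::read.table(node_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    nk <- stats::setNames(nt[[2]], nt[[1]])
  }
  causal_pkn(tab, node_kind = nk)
}

#' @rdname read_pkn_sif
#' @param pkn a `causal_pkn` to serialize.
#' @export
write_pkn_sif <- function(pkn, path, node_path = NULL) {
  utils::write.table(pkn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path)) {
    utils::write.table(
      data.frame(node = pkn_nodes(pkn), kind = unname(pkn$node_kind)),
      node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Keep a subset of nodes (vertex-induced subgraph)
#' @keywords internal
pkn_induced <- function(pkn, keep_nodes) {
  e <- pkn$edges
  e <- e[e$source %in% keep_nodes & e$target %in% keep_nodes, , drop = FALSE]
  nk <- pkn$node_kind[intersect(names(pkn$node_kind), keep_nodes)]
  p <- causal_pkn(e, node_kind = nk)
  # preserve isolated-but-kept nodes (e.g. k = 0 reduction keeps sources)
  iso <- setdiff(keep_nodes, names(p$node_kind))
  iso <- intersect(iso, names(pkn$node_kind))
  if (length(iso)) p$node_kind <- c(p$node_kind, pkn$node_kind[iso])
  p
}
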