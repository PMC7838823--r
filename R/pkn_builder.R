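#' Parse a signed directed protein-protein interaction table
#'
#' Accepts interaction tables in the style of curated signaling resources:
#' one row per interaction with boolean stimulation/inhibition flags. Only
#' signed rows are kept; a row flagged as both stimulating and inhibiting
#' yields two edges of opposite sign.
#'
#' @param rows data.frame with columns `source`, `target`,
#'   `is_stimulation`, `is_inhibition` (0/1 flags).
#' @param provenance provenance tag stamped on the edges (default `"ppi"`;
#'   use `"transcriptional"` for TF-target layers so the contextualization
#'   correction step can recognize them).
#' @return data.frame of signed edges (source, sign, target, provenance).
#' @export
parse_ppi_table <- function(rows, provenance = "ppi") {
  need <- c("source", "target", "is_stimulation", "is_inhibition")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("interaction table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  stim <- as.integer(rows$is_stimulation) == 1L
  inh <- as.integer(rows$is_inhibition) == 1L
  out <- rbind(
    data.frame(source = as.character(rows$source[stim]), sign = 1L,
               target = as.character(rows$target[stim]),
               stringsAsFactors = FALSE),
    data.frame(source = as.character(rows$source[inh]), sign = -1L,
               target = as.character(rows$target[inh]),
               stringsAsFactors = FALSE))
  out <- out[!duplicated(edge_key(out)), , drop = FALSE]
  out$provenance <- rep(provenance, nrow(out))
  rownames(out) <- NULL
  out
}

#' Parse an allosteric metabolite-protein interaction table
#'
#' Keeps high-confidence regulatory metabolite-protein links: rows whose
#' combined confidence score is at least `min_score` (the reference
#' pipeline uses 900 on a 0-1000 scale). Activation maps to +1,
#' inhibition to -1.
#'
#' @param rows data.frame with columns `metabolite`, `protein`, `action`
#'   (`"activation"`/`"inhibition"`) and `score`.
#' @param min_score minimum combined confidence score (inclusive).
#' @return data.frame of signed edges with provenance `"allosteric"`.
#' @export
parse_allosteric_table <- function(rows, min_score = 900) {
  need <- c("metabolite", "protein", "action", "score")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("allosteric table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  act <- as.character(rows$action)
  bad <- setdiff(unique(act), c("activation", "inhibition"))
  if (length(bad)) {
    stop("unknown action label(s): ", paste(bad, collapse = ", "))
  }
  keep <- as.numeric(rows$score) >= min_score
  out <- data.frame(
    source = as.character(rows$metabolite[keep]),
    sign = ifelse(act[keep] == "activation", 1L, -1L),
    target = as.character(rows$protein[keep]),
    provenance = "allosteric", stringsAsFactors = FALSE)
  out <- out[!duplicated(edge_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- GPR boolean rules ------------------------------------------------------

#' Parse a gene-protein-reaction boolean rule
#'
#' GPR rules are monotone boolean expressions over gene ids with `AND`
#' (complex), `OR` (isozymes) and parentheses (case-insensitive; `&`/`|`
#' also accepted). Returns a parse tree of nested lists with elements
#' `op` (`"and"`, `"or"`, `"gene"`) and `args`/`gene`.
#'
#' @param text the rule, e.g. `"G1 and (G2 or G3)"`.
#' @param max_depth maximum parenthesis nesting (default 10).
#' @export
parse_gpr <- function(text, max_depth = 10) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  if (!length(toks)) stop("empty GPR expression")
  pos <- 1L
  depth <- 0L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]
    pos <<- pos + 1L
    t
  }
  is_op <- function(t, what) !is.na(t) && tolower(t) %in% what
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (is_op(peek(), c("or", "|", "||"))) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (is_op(peek(), c("and", "&", "&&"))) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR expression")
    if (t == "(") {
      advance()
      depth <<- depth + 1L
      if (depth > max_depth) stop("GPR nesting deeper than ", max_depth)
      inner <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR")
      advance()
      depth <<- depth - 1L
      return(inner)
    }
    if (t == ")" || is_op(t, c("and", "or", "&", "|", "&&", "||"))) {
      stop("malformed GPR expression near '", t, "'")
    }
    advance()
    list(op = "gene", gene = t)
  }
  tree <- parse_or()
  if (pos <= length(toks)) {
    stop("trailing tokens in GPR expression: ",
         paste(toks[pos:length(toks)], collapse = " "))
  }
  tree
}

#' Expand a GPR parse tree to minimal disjunctive normal form
#'
#' Each disjunct is a set of genes that together suffice to catalyze the
#' reaction (an isozyme or a complex). Duplicate disjuncts are collapsed
#' and absorbed disjuncts (supersets of another disjunct) removed, so for
#' a monotone rule the result equals the minimal models of its truth
#' table.
#'
#' @param tree result of [parse_gpr()] (or a rule string, parsed first).
#' @return list of character vectors, each sorted; the list is sorted for
#'   determinism.
#' @export
gpr_to_dnf <- function(tree) {
  if (is.character(tree)) tree <- parse_gpr(tree)
  expand <- function(t) {
    if (t$op == "gene") return(list(t$gene))
    parts <- lapply(t$args, expand)
    if (t$op == "or") return(do.call(c, parts))
    # and: cross product of disjunct sets
    acc <- parts[[1]]
    for (p in parts[-1]) {
      acc <- unlist(lapply(acc, function(a) {
        lapply(p, function(b) unique(c(a, b)))
      }), recursive = FALSE)
    }
    acc
  }
  dis <- lapply(expand(tree), function(g) sort(unique(g)))
  dis <- dis[!duplicated(vapply(dis, paste, "", collapse = "\r"))]
  # absorption: drop any disjunct that is a superset of another
  keep <- rep(TRUE, length(dis))
  for (i in seq_along(dis)) {
    for (j in seq_along(dis)) {
      if (i != j && keep[j] &&
          length(dis[[j]]) < length(dis[[i]]) &&
          all(dis[[j]] %in% dis[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  dis <- dis[keep]
  dis[order(vapply(dis, paste, "", collapse = "_"))]
}

#' Metabolite handling policy for reaction-network conversion
#'
#' @param coenzyme_ids metabolite ids excluded before any edge is written
#'   (ubiquitous cofactors that would otherwise shortcut unrelated
#'   reactions).
#' @param degree_threshold promiscuity cutoff: after conversion,
#'   metabolites with more than this many incident edges in the metabolic
#'   layer are removed (default 338, the connectivity of the most
#'   connected central-carbon metabolite in the reference reconstruction).
#' @export
metabolite_policy <- function(coenzyme_ids = character(),
                              degree_threshold = 338) {
  stopifnot(degree_threshold >= 1)
  structure(list(coenzyme_ids = as.character(coenzyme_ids),
                 degree_threshold = as.integer(degree_threshold)),
            class = "metabolite_policy")
}

#' Convert a metabolic reaction network into causal edges
#'
#' Every reaction's GPR rule is expanded to minimal DNF; each disjunct
#' becomes one catalytic node (an enzyme instance for a single gene, a
#' complex for AND-joined genes) named `<sorted genes joined by _>__<reaction id>`
#' so enzymes of different reactions never share a node (this prevents
#' cross-links between reactants and products of different reactions).
#' Each reactant activates the catalytic node and the catalytic node
#' activates each product (all +1: presence/flux semantics). Exchange
#' reactions get the exchanged metabolite appended to the node name so
#' transport is never confused with transformation. Coenzymes are removed
#' before edges are written; afterwards, metabolites whose degree in the
#' converted layer exceeds the policy threshold are removed with all
#' incident edges.
#'
#' @param reactions list of reaction records (see [read_reaction_table()]):
#'   each a list with `reaction_id`, `reactants`, `products`, `gpr`, and
#'   optionally `is_exchange`, `exchanged_metabolite`.
#' @param policy a [metabolite_policy()].
#' @return a `causal_pkn` for the metabolic layer.
#' @export
convert_reaction_network <- function(reactions, policy = metabolite_policy()) {
  src <- character(); tgt <- character()
  kind <- character(0)
  for (rx in reactions) {
    rid <- rx$reaction_id
    reac <- setdiff(as.character(rx$reactants), policy$coenzyme_ids)
    prod <- setdiff(as.character(rx$products), policy$coenzyme_ids)
    gpr <- rx$gpr
    if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) {
      # spontaneous / orphan reaction: a reaction-specific pseudo-enzyme
      disjuncts <- list(character(0))
    } else {
      disjuncts <- tryCatch(gpr_to_dnf(gpr), error = function(e) {
        stop("reaction ", rid, ": ", conditionMessage(e), call. = FALSE)
      })
    }
    for (genes in disjuncts) {
      base <- if (length(genes)) paste(genes, collapse = "_") else "rxn"
      cat_node <- paste0(base, "__", rid)
      if (isTRUE(rx$is_exchange)) {
        ex <- rx$exchanged_metabolite
        if (is.null(ex) || is.na(ex) || !nzchar(ex)) {
          stop("exchange reaction ", rid, " names no exchanged metabolite")
        }
        cat_node <- paste0(cat_node, "__", ex)
      }
      kind[cat_node] <- if (length(genes) > 1L) "complex" else "enzyme_instance"
      for (m in reac) {
        src <- c(src, m); tgt <- c(tgt, cat_node)
      }
      for (m in prod) {
        src <- c(src, cat_node); tgt <- c(tgt, m)
      }
    }
  }
  edges <- data.frame(source = src, sign = rep(1L, length(src)), target = tgt,
                      provenance = "metabolic", stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  # promiscuity filter on the converted layer (in + out degree)
  metab <- setdiff(unique(c(edges$source, edges$target)), names(kind))
  deg <- table(factor(c(edges$source, edges$target), levels = metab))
  hub <- names(deg)[deg > policy$degree_threshold]
  if (length(hub)) {
    edges <- edges[!(edges$source %in% hub | edges$target %in% hub), ,
                   drop = FALSE]
  }
  mkind <- stats::setNames(rep("metabolite", length(metab)), metab)
  causal_pkn(edges, node_kind = c(kind, mkind))
}

#' Read a reaction table (TSV or JSON dialect)
#'
#' TSV columns: `reaction_id`, `reactants` (comma-joined), `products`
#' (comma-joined), `gpr`, `is_exchange` (0/1), `exchanged_metabolite`.
#' The JSON dialect is an array of objects with the same fields
#' (reactants/products as arrays).
#'
#' @param path file path (`.json` selects the JSON dialect).
#' @return list of reaction records for [convert_reaction_network()].
#' @export
read_reaction_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(raw, function(r) {
      list(reaction_id = r$reaction_id,
           reactants = unlist(r$reactants),
           products = unlist(r$products),
           gpr = if (is.null(r$gpr)) "" else r$gpr,
           is_exchange = isTRUE(r$is_exchange),
           exchanged_metabolite = r$exchanged_metabolite)
    }))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", na.strings = "")
  split_ids <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  lapply(seq_len(nrow(tab)), function(i) {
    list(reaction_id = as.character(tab$reaction_id[i]),
         reactants = split_ids(tab$reactants[i]),
         products = split_ids(tab$products[i]),
         gpr = if (is.na(tab$gpr[i])) "" else tab$gpr[i],
         is_exchange = !is.na(tab$is_exchange[i]) &&
           as.integer(tab$is_exchange[i]) == 1L,
         exchanged_metabolite = if ("exchanged_metabolite" %in% names(tab))
           tab$exchanged_metabolite[i] else NA_character_)
  })
}

#' Convert regulon tables to transcriptional PKN edges
#'
#' TF-target regulons double as causal edges of the transcriptional layer
#' (provenance `"transcriptional"`), which the contextualization
#' correction step treats specially.
#'
#' @param regulons data.frame with columns `regulator`, `target`, `mode`.
#' @return data.frame of signed edges.
#' @export
regulons_to_edges <- function(regulons) {
  out <- data.frame(source = as.character(regulons$regulator),
                    sign = as.integer(regulons$mode),
                    target = as.character(regulons$target),
                    provenance = "transcriptional", stringsAsFactors = FALSE)
  out <- out[!duplicated(edge_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge interaction layers into the meta PKN
#'
#' Deduplicated union of the edge tables; when the same (source, sign,
#' target) triple appears in several layers the first-listed layer's
#' provenance is kept and all provenances are recorded in the
#' `"provenances"` attribute. Node kinds come from the metabolic layer
#' where available, otherwise from the namespace (the `metab__` prefix
#' marks metabolites). A node claimed as both metabolite and protein
#' raises a namespace error.
#'
#' @param ... edge data.frames and/or `causal_pkn` objects, in priority
#'   order (e.g. ppi, allosteric, metabolic, transcriptional).
#' @return a `causal_pkn`.
#' @export
merge_sources <- function(...) {
  parts <- list(...)
  edge_tabs <- list(); kinds <- character(0)
  for (p in parts) {
    if (inherits(p, "causal_pkn")) {
      edge_tabs[[length(edge_tabs) + 1L]] <- p$edges
      new <- p$node_kind
      both <- intersect(names(new), names(kinds))
      clash <- both[kinds[both] != new[both] &
                      (kinds[both] == "metabolite" | new[both] == "metabolite")]
      if (length(clash)) {
        stop("node(s) appear as both metabolite and protein kind: ",
             paste(clash, collapse = ", "))
      }
      kinds[names(new)] <- unname(new)
    } else if (!is.null(p) && nrow(p)) {
      edge_tabs[[length(edge_tabs) + 1L]] <- p
    }
  }
  if (!length(edge_tabs)) return(causal_pkn())
  all_edges <- do.call(rbind, lapply(edge_tabs, function(e) {
    if (is.null(e$provenance)) e$provenance <- "ppi"
    e[, c("source", "sign", "target", "provenance")]
  }))
  key <- edge_key(all_edges)
  prov_map <- split(all_edges$provenance, key)
  merged <- all_edges[!duplicated(key), , drop = FALSE]
  rownames(merged) <- NULL
  pkn <- causal_pkn(merged, node_kind = kinds)
  attr(pkn, "provenances") <- lapply(prov_map, unique)
  pkn
}
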