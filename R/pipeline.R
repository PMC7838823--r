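#' Default run configuration
#'
#' @param ... overrides for the defaults: `nes_cut` (1.7), `p_cut`
#'   (0.05), `beta` (0.2), `k_forward` (8), `k_backward` (7),
#'   `min_mean_count` (50), `min_targets` (5), `time_limit_s` (7200
#'   forward / 21800 backward when unset), `pool_cap` (100), `backend`
#'   (`"bnb"`), `prerun` (TRUE), `seed` (1).
#' @return named list of run settings.
#' @export
run_config <- function(...) {
  cfg <- list(nes_cut = 1.7, p_cut = 0.05, beta = 0.2, k_forward = 8,
              k_backward = 7, min_mean_count = 50, min_targets = 5,
              time_limit_s = NULL, pool_cap = 100, backend = "bnb",
              prerun = TRUE, seed = 1)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Read a flat TOML run configuration
#'
#' Supports the subset used by run files: `[section]` headers (flattened
#' away), `key = value` scalars (numbers, booleans, quoted strings) and
#' simple arrays of scalars.
#'
#' @param path TOML file path.
#' @return named list merged over [run_config()] defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  parse_scalar <- function(v) {
    v <- trimws(v)
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl("^\\[.*\\]$", val)) {
      items <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      out[[key]] <- unlist(lapply(items, parse_scalar), use.names = FALSE)
    } else {
      out[[key]] <- parse_scalar(val)
    }
  }
  do.call(run_config, out)
}

contextualize <- function(pkn, sources, k, activities, transcript_stats,
                          counts, config, inputs = NULL,
                          measurements = NULL) {
  if (!is.null(counts)) {
    pkn <- filter_expressed(pkn, counts,
                            min_mean_count = config$min_mean_count)
  }
  pkn <- reduce_to_reachable(pkn, sources, k = k)
  if (!is.null(transcript_stats)) {
    pkn <- correct_transcriptional_edges(pkn, activities, transcript_stats,
                                         p_cut = config$p_cut)
    if (isTRUE(config$prerun) && !is.null(inputs)) {
      pkn <- suppressWarnings(ilp_prerun_correction(
        pkn, inputs, measurements, transcript_stats,
        p_cut = config$p_cut, beta = config$beta,
        time_limit_s = config$time_limit_s %||% 600,
        pool_cap = config$pool_cap, backend = config$backend))
    }
  }
  pkn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward run: signaling regulators to metabolites
#'
#' Selects deregulated regulators (|NES| > `nes_cut`) as fixed-sign
#' inputs and deregulated metabolites (p < `p_cut`) as weighted
#' measurements, contextualizes the PKN (expression filtering,
#' reachability reduction at `k_forward` steps, transcriptional
#' correction and an optimization pre-run correction), then solves for
#' the optimal sign-consistent subnetworks.
#'
#' Measurement weights default to 1 for metabolites; regulator
#' measurements in the backward run are weighted by |NES|.
#'
#' @param pkn the meta `causal_pkn`.
#' @param activities activity table of TFs/kinases/phosphatases.
#' @param metab_stats StatTable for metabolites.
#' @param config a [run_config()] list.
#' @param counts optional gene x sample count matrix for the expression
#'   filter.
#' @param transcript_stats optional transcript StatTable for the
#'   correction steps.
#' @return a `causal_solution_pool`.
#' @export
run_forward <- function(pkn, activities, metab_stats, config = run_config(),
                        counts = NULL, transcript_stats = NULL) {
  sel <- select_inputs(activities, metab_stats, nes_cut = config$nes_cut,
                       p_cut = config$p_cut)
  if (!nrow(sel$signaling)) {
    stop("no deregulated regulator passes |NES| > ", config$nes_cut,
         "; lower nes_cut or check the activity estimates")
  }
  if (!nrow(sel$metabolites)) {
    stop("no deregulated metabolite passes p < ", config$p_cut,
         "; lower p_cut or check the metabolite statistics")
  }
  inputs <- stats::setNames(sign(sel$signaling$value), sel$signaling$node)
  measurements <- data.frame(node = sel$metabolites$node,
                             sign = sel$metabolites$value, weight = 1,
                             stringsAsFactors = FALSE)
  cpkn <- contextualize(pkn, names(inputs), config$k_forward, activities,
                        transcript_stats, counts, config,
                        inputs = inputs, measurements = measurements)
  inst <- causal_instance(cpkn, inputs, measurements, beta = config$beta,
                          time_limit_s = config$time_limit_s %||% 7200,
                          pool_cap = config$pool_cap)
  solve_instance(inst, backend = config$backend)
}

#' Backward run: metabolites to signaling regulators
#'
#' As [run_forward()] with the roles swapped: deregulated metabolites
#' become fixed-sign inputs, deregulated regulators become measurements
#' weighted by |NES|, and the reachability reduction uses `k_backward`
#' steps from the metabolite inputs.
#'
#' @inheritParams run_forward
#' @return a `causal_solution_pool`.
#' @export
run_backward <- function(pkn, activities, metab_stats,
                         config = run_config(), counts = NULL,
                         transcript_stats = NULL) {
  sel <- select_inputs(activities, metab_stats, nes_cut = config$nes_cut,
                       p_cut = config$p_cut)
  if (!nrow(sel$metabolites)) {
    stop("no deregulated metabolite passes p < ", config$p_cut,
         "; backward run needs metabolite inputs")
  }
  if (!nrow(sel$signaling)) {
    stop("no deregulated regulator passes |NES| > ", config$nes_cut,
         "; backward run needs regulator measurements")
  }
  inputs <- stats::setNames(sel$metabolites$value, sel$metabolites$node)
  measurements <- data.frame(node = sel$signaling$node,
                             sign = sign(sel$signaling$value),
                             weight = abs(sel$signaling$value),
                             stringsAsFactors = FALSE)
  cpkn <- contextualize(pkn, names(inputs), config$k_backward, activities,
                        transcript_stats, counts, config,
                        inputs = inputs, measurements = measurements)
  inst <- causal_instance(cpkn, inputs, measurements, beta = config$beta,
                          time_limit_s = config$time_limit_s %||% 21800,
                          pool_cap = config$pool_cap)
  solve_instance(inst, backend = config$backend)
}

#' Merge forward and backward runs
#'
#' Takes the union of the two summary networks (edges with pool weight
#' greater than zero), carrying each run's weight separately plus a
#' display-only combined weight (the maximum); node attributes are the
#' union of consensus states. Nodes assigned opposite signs by the two
#' runs are kept as-is and listed in the sign-conflict report rather
#' than resolved.
#'
#' @param forward,backward `causal_solution_pool` objects.
#' @return list of class `cosmos_merged`: `edges` (source, sign, target,
#'   weight_forward, weight_backward, weight_combined), `nodes` (id,
#'   state_forward, state_backward), `conflicts` (sign-conflict report).
#' @export
merge_runs <- function(forward, backward) {
  if (!length(forward$solutions) || !length(backward$solutions)) {
    stop("both runs must contain at least one solution")
  }
  merge_core(forward$edge_weight, consensus_states(forward),
             backward$edge_weight, consensus_states(backward))
}

#' @export
print.cosmos_merged <- function(x, ...) {
  cat("Merged causal network\n")
  cat("  edges:", nrow(x$edges), " nodes:", nrow(x$nodes), "\n")
  cat("  sign conflicts between runs:", nrow(x$conflicts), "\n")
  if (nrow(x$conflicts)) print(x$conflicts)
  invisible(x)
}

#' Map network node ids back to gene symbols
#'
#' Enzyme-instance and complex ids are stripped of their reaction suffix
#' and complexes split into member genes; metabolite nodes are dropped.
#'
#' @param node_ids character vector of network node ids.
#' @return character vector of unique gene symbols.
#' @export
nodes_to_genes <- function(node_ids) {
  node_ids <- node_ids[!startsWith(node_ids, "metab__")]
  genes <- unlist(lapply(node_ids, function(v) {
    base <- strsplit(v, "__", fixed = TRUE)[[1]][1]
    if (identical(base, "rxn")) return(character(0))
    strsplit(base, "_", fixed = TRUE)[[1]]
  }))
  unique(genes)
}

#' Over-representation analysis of network genes
#'
#' Hypergeometric upper-tail test of the overlap between the selected
#' gene set (e.g. the genes of a merged solution network) and each gene
#' set of a collection, with Benjamini-Hochberg adjustment across sets.
#'
#' @param nodes character vector of selected genes (network nodes are
#'   first mapped with [nodes_to_genes()] if they contain namespaced
#'   ids).
#' @param genesets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all genes eligible for selection.
#' @return data.frame (set, set_size, overlap, p, padj) sorted by p.
#' @export
ora <- function(nodes, genesets, universe) {
  if (!length(universe)) stop("ORA universe must not be empty")
  universe <- unique(universe)
  sel <- unique(intersect(nodes_to_genes(nodes), universe))
  res <- do.call(rbind, lapply(names(genesets), function(nm) {
    gs <- intersect(unique(genesets[[nm]]), universe)
    ov <- length(intersect(sel, gs))
    p <- stats::phyper(ov - 1, length(gs), length(universe) - length(gs),
                       length(sel), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  }))
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
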