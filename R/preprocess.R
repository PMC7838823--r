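# gene members of a node: proteins are themselves; enzyme instances and
# complexes are "<g1>_<g2>__<reaction>[__<metab>]"
node_genes <- function(node, kind) {
  if (kind %in% c("enzyme_instance", "complex")) {
    base <- strsplit(node, "__", fixed = TRUE)[[1]][1]
    if (identical(base, "rxn")) return(character(0)) # orphan pseudo-enzyme
    strsplit(base, "_", fixed = TRUE)[[1]]
  } else if (kind == "protein") {
    node
  } else {
    character(0)
  }
}

#' Expression filter
#'
#' Removes every edge touching a gene product that is not expressed: a
#' protein node whose gene has mean count below `min_mean_count` across
#' all provided samples (or is absent from the count matrix) is dropped
#' with all incident edges; enzyme-instance and complex nodes are dropped
#' if any member gene fails. Edges between metabolites only are never
#' touched.
#'
#' @param pkn a `causal_pkn`.
#' @param counts nonnegative gene x sample matrix (rownames = gene ids).
#' @param min_mean_count minimum mean count (default 50).
#' @return the filtered `causal_pkn`.
#' @export
filter_expressed <- function(pkn, counts, min_mean_count = 50) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  mu <- rowMeans(counts)
  expressed <- names(mu)[mu >= min_mean_count]
  ok <- vapply(pkn_nodes(pkn), function(v) {
    g <- node_genes(v, pkn$node_kind[[v]])
    all(g %in% expressed)
  }, TRUE)
  keep <- pkn_nodes(pkn)[ok]
  out <- pkn_induced(pkn, keep)
  if (!nrow(out$edges)) warning("expression filter removed every edge")
  out
}

#' Reachability reduction
#'
#' Keeps exactly the nodes whose shortest directed distance from some
#' source node is at most `k` steps, and the edges among them. This
#' removes network modules that cannot be influenced by any input and
#' bounds the causal path length considered plausible (reference
#' defaults: 8 steps downstream of signaling inputs for the forward run,
#' 7 for the backward run).
#'
#' @param pkn a `causal_pkn`.
#' @param sources character vector of source node ids.
#' @param k maximum number of steps (>= 0).
#' @return the reduced `causal_pkn` (sources are kept even when
#'   isolated).
#' @export
reduce_to_reachable <- function(pkn, sources, k = 8) {
  stopifnot(k >= 0)
  absent <- setdiff(sources, pkn_nodes(pkn))
  if (length(absent)) {
    warning("source(s) absent from the PKN: ", paste(absent, collapse = ", "))
  }
  sources <- intersect(sources, pkn_nodes(pkn))
  if (!length(sources)) return(causal_pkn())
  g <- pkn_to_igraph(pkn)
  d <- igraph::distances(g, v = sources, mode = "out")
  reach <- colnames(d)[apply(d, 2L, min) <= k]
  pkn_induced(pkn, union(reach, sources))
}

#' Transcriptional-coherence correction
#'
#' Removes every transcriptional edge that contradicts the measured
#' transcript response of its target: a transcriptional edge (TF, s,
#' gene) is removed iff the TF has a known activity sign `a`, the target
#' transcript is significantly changed (p < `p_cut`, uncorrected) and the
#' sign of its log fold change differs from `a * s`. Edges of TFs without
#' an activity estimate, targets without significant evidence, and all
#' non-transcriptional edges are retained.
#'
#' @param pkn a `causal_pkn` whose transcriptional layer carries
#'   provenance `"transcriptional"`.
#' @param tf_activities an activity table (`node`, `nes`) or a named
#'   numeric vector of node states from a solution network.
#' @param transcript_stats StatTable for transcripts (`feature_id`,
#'   `p_value`, `log_fc`).
#' @param p_cut significance cutoff for the target transcript (default
#'   0.05).
#' @return the corrected `causal_pkn`.
#' @export
correct_transcriptional_edges <- function(pkn, tf_activities,
                                          transcript_stats, p_cut = 0.05) {
  if (is.data.frame(tf_activities)) {
    acts <- stats::setNames(sign(tf_activities$nes), tf_activities$node)
  } else {
    acts <- sign(tf_activities)
  }
  e <- pkn$edges
  p <- stats::setNames(transcript_stats$p_value, transcript_stats$feature_id)
  lfc <- stats::setNames(transcript_stats$log_fc, transcript_stats$feature_id)
  drop <- rep(FALSE, nrow(e))
  tx <- which(e$provenance == "transcriptional")
  for (j in tx) {
    a <- acts[e$source[j]]
    if (is.na(a) || a == 0) next
    pv <- p[e$target[j]]
    if (is.na(pv) || pv >= p_cut) next
    if (sign(lfc[[e$target[j]]]) != a * e$sign[j]) drop[j] <- TRUE
  }
  out <- causal_pkn(e[!drop, , drop = FALSE], node_kind = pkn$node_kind)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Correction using a solver pre-run
#'
#' Runs the forward optimization once on the current PKN and uses the TF
#' states of the solution pool (consensus across equally optimal
#' networks) to remove transcriptional regulation events that contradict
#' the measured transcript changes, then returns the re-corrected PKN.
#' If the pre-run yields no solution the PKN is returned unchanged with a
#' warning.
#'
#' @param pkn a `causal_pkn`.
#' @param inputs named sign vector of fixed inputs.
#' @param measurements measurement data.frame (`node`,`sign`,`weight`).
#' @param transcript_stats StatTable for transcripts.
#' @param p_cut significance cutoff passed to
#'   [correct_transcriptional_edges()].
#' @param beta,time_limit_s,pool_cap,backend solver settings, see
#'   [causal_instance()] and [solve_instance()].
#' @return the corrected `causal_pkn`.
#' @export
ilp_prerun_correction <- function(pkn, inputs, measurements,
                                  transcript_stats, p_cut = 0.05,
                                  beta = 0.2, time_limit_s = 600,
                                  pool_cap = 100, backend = "bnb") {
  inst <- tryCatch(
    causal_instance(pkn, inputs, measurements, beta = beta,
                    time_limit_s = time_limit_s, pool_cap = pool_cap),
    error = function(e) NULL)
  if (is.null(inst)) {
    warning("pre-run instance could not be built; PKN left unchanged")
    return(pkn)
  }
  pool <- solve_instance(inst, backend = backend)
  if (!length(pool$solutions)) {
    warning("pre-run found no solution; PKN left unchanged")
    return(pkn)
  }
  st <- consensus_states(pool)
  st <- st[abs(st) == 1] # consensus: same state in every pooled solution
  if (!length(st)) return(pkn)
  correct_transcriptional_edges(pkn, st, transcript_stats, p_cut = p_cut)
}
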