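#' Generate a random multi-layer causal PKN
#'
#' Produces a reproducible signed directed graph with the wiring of the
#' meta PKN: a protein-protein signaling layer (with a transcriptional
#' sub-layer), metabolite-to-protein allosteric edges, and a metabolic
#' layer in which reaction-specific enzyme-instance nodes sit between
#' their gene product, their reactant metabolites and their product
#' metabolites. Metabolite ids use the `metab__` namespace.
#'
#' @param n_protein number of protein nodes.
#' @param n_metabolite number of metabolite nodes.
#' @param n_edges total number of edges.
#' @param sign_neg_fraction fraction of inhibitory edges in the signaling,
#'   transcriptional and allosteric layers (metabolic edges are always
#'   activating).
#' @param seed mandatory RNG seed; same seed, same network.
#' @return a `causal_pkn`.
#' @export
generate_random_pkn <- function(n_protein = 20, n_metabolite = 8,
                                n_edges = 40, sign_neg_fraction = 0.3,
                                seed) {
  stopifnot(!missing(seed), n_protein >= 2, n_metabolite >= 1, n_edges >= 0)
  set.seed(seed)
  prot <- sprintf("P%02d", seq_len(n_protein))
  met <- sprintf("metab__m%02d", seq_len(n_metabolite))
  n_enz <- max(2L, ceiling(n_metabolite / 2))
  enz_gene <- sample(prot, n_enz, replace = TRUE)
  enz <- sprintf("%s__R%02d", enz_gene, seq_len(n_enz))
  kind <- c(stats::setNames(rep("protein", n_protein), prot),
            stats::setNames(rep("metabolite", n_metabolite), met),
            stats::setNames(rep("enzyme_instance", n_enz), enz))
  # candidate edges per layer
  pp <- expand.grid(source = prot, target = prot, stringsAsFactors = FALSE)
  pp <- pp[pp$source != pp$target, ]
  alo <- expand.grid(source = met, target = prot, stringsAsFactors = FALSE)
  gene_link <- data.frame(source = enz_gene, target = enz,
                          stringsAsFactors = FALSE)
  met_in <- expand.grid(source = met, target = enz, stringsAsFactors = FALSE)
  met_out <- expand.grid(source = enz, target = met, stringsAsFactors = FALSE)
  mk <- function(cand, n, prov, signed = TRUE) {
    n <- min(n, nrow(cand))
    if (n <= 0) return(NULL)
    pick <- cand[sample.int(nrow(cand), n), , drop = FALSE]
    pick$sign <- if (signed) {
      ifelse(stats::runif(n) < sign_neg_fraction, -1L, 1L)
    } else 1L
    pick$provenance <- prov
    pick
  }
  quota <- round(n_edges * c(ppi = 0.4, transcriptional = 0.15,
                             allosteric = 0.1, metabolic = 0.35))
  quota["ppi"] <- n_edges - sum(quota[-1])
  n_met_edges <- quota[["metabolic"]]
  n_link <- min(nrow(gene_link), ceiling(n_met_edges / 4))
  n_in <- floor((n_met_edges - n_link) / 2)
  n_out <- n_met_edges - n_link - n_in
  edges <- rbind(
    mk(pp, quota[["ppi"]], "ppi"),
    mk(pp, quota[["transcriptional"]], "transcriptional"),
    mk(alo, quota[["allosteric"]], "allosteric"),
    mk(gene_link, n_link, "metabolic", signed = FALSE),
    mk(met_in, n_in, "metabolic", signed = FALSE),
    mk(met_out, n_out, "metabolic", signed = FALSE))
  if (is.null(edges)) return(causal_pkn(node_kind = kind))
  edges <- edges[!duplicated(paste(edges$source, edges$target)), ,
                 drop = FALSE]
  if (nrow(edges) < n_edges) {
    extra <- mk(pp, 2L * (n_edges - nrow(edges)), "ppi")
    extra <- extra[!(paste(extra$source, extra$target) %in%
                       paste(edges$source, edges$target)), , drop = FALSE]
    if (nrow(edges) + nrow(extra) < n_edges) {
      stop("requested edge count exceeds simple-graph capacity")
    }
    edges <- rbind(edges, extra[seq_len(n_edges - nrow(edges)), ,
                                drop = FALSE])
  }
  causal_pkn(edges[, c("source", "sign", "target", "provenance")],
             node_kind = kind)
}

#' Plant a causal instance with known ground truth on a given PKN
#'
#' Selects random input nodes, grows a random acyclic sub-DAG downstream
#' of them, propagates the input signs along it and designates deep nodes
#' (directed distance >= 2) as measurements carrying the propagated
#' signs, so a zero-mismatch solution is guaranteed to exist. The planted
#' ground truth stored in `true_network` is the minimal zero-mismatch
#' explanation of those measurements (computed exactly), so
#' `beta * length(true_network$node_state)` equals the optimal objective.
#'
#' @param pkn a `causal_pkn`.
#' @param n_inputs,n_measurements numbers of inputs and measurements
#'   (both >= 1).
#' @param seed mandatory RNG seed.
#' @param beta size penalty used for the instance.
#' @param max_depth maximum planting depth (default 4).
#' @return list with `instance` (a `causal_instance`), `true_network`
#'   (node_state + active_edges), `inputs`, `measurements`.
#' @export
plant_causal_instance <- function(pkn, n_inputs = 2, n_measurements = 2,
                                  seed, beta = 0.2, max_depth = 4) {
  stopifnot(!missing(seed), n_inputs >= 1)
  if (n_measurements < 1) stop("at least one measurement must be planted")
  set.seed(seed)
  e <- pkn$edges
  roots <- unique(e$source)
  if (length(roots) < n_inputs) stop("not enough source nodes to plant inputs")
  inputs <- stats::setNames(sample(c(-1, 1), n_inputs, replace = TRUE),
                            sample(roots, n_inputs))
  state <- inputs
  depth <- stats::setNames(rep(0L, n_inputs), names(inputs))
  frontier <- names(inputs)
  for (d in seq_len(max_depth)) {
    nxt <- character(0)
    for (u in sample(frontier)) {
      out <- e[e$source == u & !(e$target %in% names(state)), , drop = FALSE]
      if (!nrow(out)) next
      take <- out[sample.int(nrow(out), min(nrow(out), 2L)), , drop = FALSE]
      for (j in seq_len(nrow(take))) {
        v <- take$target[j]
        if (v %in% names(state)) next
        state[[v]] <- take$sign[j] * state[[u]]
        depth[[v]] <- d
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  deep <- names(depth)[depth >= 2L]
  if (!length(deep)) stop("no path of length >= 2 available from the inputs")
  meas_nodes <- sample(deep, min(n_measurements, length(deep)))
  measurements <- data.frame(node = meas_nodes,
                             sign = unname(state[meas_nodes]), weight = 2,
                             stringsAsFactors = FALSE)
  instance <- causal_instance(pkn, inputs, measurements, beta = beta,
                              time_limit_s = 300, pool_cap = 50)
  pool <- solve_instance(instance)
  if (!length(pool$solutions)) stop("planting failed to produce a solution")
  true_network <- pool$solutions[[1L]]
  list(instance = instance, true_network = true_network, inputs = inputs,
       measurements = measurements)
}

#' Generate a regulon study with planted activities
#'
#' Regulators get disjoint random target sets with random modes; target
#' statistics are `activity x mode` plus Gaussian noise, off-target
#' features pure noise.
#'
#' @param n_regulators number of regulators.
#' @param targets_per_regulator targets per regulator (disjoint across
#'   regulators; `n_regulators * targets_per_regulator <= n_features`).
#' @param activity_vector planted activities, recycled to
#'   `n_regulators`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_features total measured features.
#' @param seed mandatory RNG seed.
#' @return list with `regulons` (data.frame) and `stats` (StatTable
#'   data.frame) and `activities` (named planted activity vector).
#' @export
generate_regulon_study <- function(n_regulators = 10,
                                   targets_per_regulator = 10,
                                   activity_vector = 0, noise_sd = 1,
                                   n_features = 200, seed) {
  stopifnot(!missing(seed))
  if (n_regulators * targets_per_regulator > n_features) {
    stop("n_regulators * targets_per_regulator must be <= n_features")
  }
  set.seed(seed)
  acts <- rep_len(activity_vector, n_regulators)
  names(acts) <- sprintf("R%02d", seq_len(n_regulators))
  feats <- sprintf("F%04d", seq_len(n_features))
  assign_idx <- sample.int(n_features,
                           n_regulators * targets_per_regulator)
  regulons <- do.call(rbind, lapply(seq_len(n_regulators), function(i) {
    idx <- assign_idx[((i - 1L) * targets_per_regulator + 1L):
                        (i * targets_per_regulator)]
    data.frame(regulator = names(acts)[i], target = feats[idx],
               mode = sample(c(-1L, 1L), targets_per_regulator,
                             replace = TRUE),
               weight = 1, stringsAsFactors = FALSE)
  }))
  stat <- stats::rnorm(n_features, 0, max(noise_sd, 0))
  if (noise_sd == 0) stat <- rep(0, n_features)
  names(stat) <- feats
  for (i in seq_len(n_regulators)) {
    reg <- regulons[regulons$regulator == names(acts)[i], ]
    stat[reg$target] <- acts[i] * reg$mode +
      if (noise_sd > 0) stats::rnorm(nrow(reg), 0, noise_sd) else 0
  }
  stats_tab <- data.frame(feature_id = feats, statistic = unname(stat),
                          p_value = 2 * stats::pnorm(-abs(unname(stat))),
                          log_fc = unname(stat), stringsAsFactors = FALSE)
  list(regulons = regulons, stats = stats_tab, activities = acts)
}

#' Generate a complete planted multi-omics study
#'
#' Builds a PKN whose planted part is a set of disjoint causal chains
#' TF -> gene -> enzyme gene -> enzyme instance -> metabolite (one per
#' input, with random signs on the signaling and transcriptional edges),
#' surrounded by decoy nodes, decoy transcriptional targets (some
#' measurably incoherent, to exercise the correction step) and
#' unexpressed genes (to exercise the expression filter). Because no
#' distractor edge enters a planted node, every planted non-input node
#' has a unique supporting in-edge, so the planted network is provably
#' the unique minimal zero-mismatch solution of the forward run and the
#' optimal objective equals `beta * (5 * n_inputs)`.
#'
#' Alongside the network the generator emits everything the pipeline
#' consumes: TF regulons with planted activities (+-3 for planted TFs, 0
#' for null regulators), transcript and metabolite differential
#' statistics, a count matrix, per-sample data and the per-sample
#' activity matrix.
#'
#' @param n_inputs number of planted causal chains (and input TFs).
#' @param n_decoy number of decoy protein nodes.
#' @param n_null_regulators TF regulons with zero planted activity.
#' @param targets_per_regulator regulon size.
#' @param n_features transcript features used for activity estimation.
#' @param noise_sd noise on regulon target statistics (0 = noise-free).
#' @param n_samples samples in the count matrix / per-sample design.
#' @param beta size penalty of the planted optimum.
#' @param seed mandatory RNG seed.
#' @return object of class `planted_study`; see Details.
#' @export
generate_planted_study <- function(n_inputs = 3, n_decoy = 12,
                                   n_null_regulators = 5,
                                   targets_per_regulator = 10,
                                   n_features = 300, noise_sd = 0,
                                   n_samples = 6, beta = 0.2, seed) {
  stopifnot(!missing(seed), n_inputs >= 1)
  set.seed(seed)
  tf <- sprintf("TF%02d", seq_len(n_inputs))
  g1 <- sprintf("GA%02d", seq_len(n_inputs))
  g2 <- sprintf("GB%02d", seq_len(n_inputs))
  enz <- sprintf("%s__R%02d", g2, seq_len(n_inputs))
  met <- sprintf("metab__m%02d", seq_len(n_inputs))
  a <- sample(c(-1, 1), n_inputs, replace = TRUE) # input states
  s1 <- sample(c(-1L, 1L), n_inputs, replace = TRUE)
  s2 <- sample(c(-1L, 1L), n_inputs, replace = TRUE)
  chain_edges <- do.call(rbind, lapply(seq_len(n_inputs), function(k) {
    data.frame(
      source = c(tf[k], g1[k], g2[k], enz[k]),
      sign = c(s1[k], s2[k], 1L, 1L),
      target = c(g1[k], g2[k], enz[k], met[k]),
      provenance = c("transcriptional", "ppi", "metabolic", "metabolic"),
      stringsAsFactors = FALSE)
  }))
  planted_nodes <- c(tf, g1, g2, enz, met)
  state <- stats::setNames(numeric(0), character(0))
  for (k in seq_len(n_inputs)) {
    st_tf <- a[k]
    state[tf[k]] <- st_tf
    state[g1[k]] <- st_tf * s1[k]
    state[g2[k]] <- state[g1[k]] * s2[k]
    state[enz[k]] <- state[g2[k]]
    state[met[k]] <- state[enz[k]]
  }
  # allosteric feedback: each planted metabolite regulates the next
  # chain's TF, signed coherently with the planted states, so the
  # backward run (metabolites -> regulators) has a planted truth too.
  # Edges into inputs are never active in forward solutions, so the
  # forward optimum is untouched.
  nxt <- c(seq_len(n_inputs)[-1L], 1L)
  allo_edges <- data.frame(
    source = met, sign = as.integer(a[nxt] * state[met]), target = tf[nxt],
    provenance = "allosteric", stringsAsFactors = FALSE)
  # decoys: edges out of planted nodes and among decoys, never into
  # planted nodes, so planted supports stay unique
  dec <- if (n_decoy > 0) sprintf("D%02d", seq_len(n_decoy)) else character(0)
  decoy_edges <- NULL
  if (n_decoy > 0) {
    src <- sample(c(planted_nodes[!startsWith(planted_nodes, "metab__")],
                    dec), 2L * n_decoy, replace = TRUE)
    tgt <- sample(dec, 2L * n_decoy, replace = TRUE)
    keep <- src != tgt
    decoy_edges <- data.frame(
      source = src[keep], sign = sample(c(-1L, 1L), sum(keep),
                                        replace = TRUE),
      target = tgt[keep], provenance = "ppi", stringsAsFactors = FALSE)
  }
  # decoy transcriptional targets of the input TFs: half get measurably
  # incoherent transcripts (edge should be removed by correction)
  n_tx_dec <- max(2L, n_inputs)
  txd <- sprintf("TX%02d", seq_len(n_tx_dec))
  tx_tf <- sample(tf, n_tx_dec, replace = TRUE)
  tx_sign <- sample(c(-1L, 1L), n_tx_dec, replace = TRUE)
  tx_edges <- data.frame(source = tx_tf, sign = tx_sign, target = txd,
                         provenance = "transcriptional",
                         stringsAsFactors = FALSE)
  incoherent <- seq_len(n_tx_dec) %% 2L == 0L
  # unexpressed genes: below the count filter, their edges disappear
  unex <- c("UX01", "UX02")
  unex_edges <- data.frame(
    source = sample(tf, 2L, replace = TRUE), sign = 1L, target = unex,
    provenance = "ppi", stringsAsFactors = FALSE)
  pkn <- causal_pkn(
    rbind(chain_edges, allo_edges, decoy_edges, tx_edges, unex_edges),
    node_kind = stats::setNames(rep("enzyme_instance", n_inputs), enz))
  inputs <- stats::setNames(a, tf)
  measurements <- data.frame(node = met, sign = unname(state[met]),
                             weight = 1, stringsAsFactors = FALSE)
  true_edges <- chain_edges[, c("source", "sign", "target")]
  true_network <- list(
    node_state = state[planted_nodes],
    active_edges = true_edges[order(true_edges$source, true_edges$target), ])
  # regulons and transcript-level statistics
  null_names <- if (n_null_regulators > 0)
    sprintf("NR%02d", seq_len(n_null_regulators)) else character(0)
  reg_study <- generate_regulon_study(
    n_regulators = n_inputs + n_null_regulators,
    targets_per_regulator = targets_per_regulator,
    activity_vector = c(3 * a, rep(0, n_null_regulators)),
    noise_sd = noise_sd, n_features = n_features,
    seed = seed + 1L)
  regulons <- reg_study$regulons
  regulons$regulator <- c(tf, null_names)[
    match(regulons$regulator, sort(unique(regulons$regulator)))]
  # transcript stats: regulon features + genes targeted by transcriptional
  # edges (planted coherent and significant; decoys half incoherent)
  gene_stats <- data.frame(
    feature_id = c(g1, txd),
    statistic = c(3 * state[g1],
                  ifelse(incoherent, -3, 3) * (state[tx_tf] * tx_sign)),
    p_value = 0.001,
    log_fc = c(sign(state[g1]),
               ifelse(incoherent, -1, 1) * sign(state[tx_tf] * tx_sign)),
    stringsAsFactors = FALSE)
  transcript_stats <- rbind(reg_study$stats, gene_stats)
  met_dec <- sprintf("metab__d%02d", seq_len(2))
  metab_stats <- data.frame(
    feature_id = c(met, met_dec),
    statistic = c(3 * state[met], stats::rnorm(2, 0, 0.2)),
    p_value = c(rep(0.001, n_inputs), 0.7, 0.8),
    log_fc = c(sign(state[met]), 0, 0), stringsAsFactors = FALSE)
  # counts: every planted / decoy gene expressed, UX genes not
  genes <- unique(c(tf, g1, g2, dec, txd, null_names))
  counts <- matrix(rep(100 + round(stats::runif(length(genes), -20, 20)),
                       n_samples),
                   nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, sprintf("S%02d",
                                                  seq_len(n_samples))))
  counts <- rbind(counts, matrix(5, 2, n_samples,
                                 dimnames = list(unex, colnames(counts))))
  # per-sample design: latent TF activity a_k + noise, targets follow
  sample_data <- matrix(stats::rnorm(n_features * n_samples, 0, 1),
                        n_features, n_samples,
                        dimnames = list(reg_study$stats$feature_id,
                                        sprintf("S%02d", seq_len(n_samples))))
  for (k in seq_len(n_inputs)) {
    reg <- regulons[regulons$regulator == tf[k], ]
    latent <- a[k] * 2 + stats::rnorm(n_samples, 0, 0.5)
    sample_data[reg$target, ] <-
      outer(reg$mode, latent) +
      matrix(stats::rnorm(nrow(reg) * n_samples, 0, 1), nrow(reg))
  }
  activity_matrix <- per_sample_activities(sample_data, regulons,
                                           min_targets = 3)
  structure(list(
    pkn = pkn, true_network = true_network, inputs = inputs,
    measurements = measurements, regulons = regulons,
    stat_tables = list(transcript = transcript_stats,
                       metabolite = metab_stats),
    counts = counts, sample_data = sample_data,
    activity_matrix = activity_matrix, beta = beta,
    expected_objective = beta * length(planted_nodes),
    expected_backward_objective = beta * 2 * n_inputs,
    planted_activities = stats::setNames(3 * a, tf), seed = seed),
    class = "planted_study")
}

#' @export
print.planted_study <- function(x, ...) {
  cat("Planted multi-omics study (seed ", x$seed, ")\n", sep = "")
  cat("  PKN:", nrow(x$pkn$edges), "edges;",
      length(x$true_network$node_state), "planted nodes\n")
  cat("  inputs:", length(x$inputs),
      " measurements:", nrow(x$measurements), "\n")
  cat("  expected forward objective:", x$expected_objective, "\n")
  invisible(x)
}

#' Generate a planted co-regulation study
#'
#' A star-shaped solution network (parents regulating disjoint child
#' sets) plus a per-sample activity matrix in which siblings share a
#' latent factor giving pairwise correlation `r`; extra regulators are
#' independent noise (the baseline population).
#'
#' @param n_parents number of parent regulators.
#' @param children_per_parent children per parent.
#' @param n_extra independent regulators added to the matrix.
#' @param n_samples samples (columns).
#' @param r planted sibling correlation in [0, 1).
#' @param seed mandatory RNG seed.
#' @return list with `network` (edge data.frame with pool weights) and
#'   `activity_matrix`.
#' @export
generate_coregulation_study <- function(n_parents = 5,
                                        children_per_parent = 4,
                                        n_extra = 10, n_samples = 20,
                                        r = 0.8, seed) {
  stopifnot(!missing(seed), r >= 0, r < 1)
  set.seed(seed)
  parents <- sprintf("PA%02d", seq_len(n_parents))
  children <- sprintf("CH%02d", seq_len(n_parents * children_per_parent))
  extras <- if (n_extra > 0) sprintf("EX%02d", seq_len(n_extra)) else
    character(0)
  network <- do.call(rbind, lapply(seq_len(n_parents), function(i) {
    ch <- children[((i - 1L) * children_per_parent + 1L):
                     (i * children_per_parent)]
    data.frame(source = parents[i], sign = 1L, target = ch, weight = 100,
               stringsAsFactors = FALSE)
  }))
  amat <- matrix(NA_real_, n_parents + length(children) + length(extras),
                 n_samples,
                 dimnames = list(c(parents, children, extras), NULL))
  # parents are measured with extra noise (loading sqrt(q), q = r^2) so
  # sibling pairs (correlation r) are the strongest signal in the matrix
  q <- r^2
  for (i in seq_len(n_parents)) {
    latent <- stats::rnorm(n_samples)
    amat[parents[i], ] <- sqrt(q) * latent +
      sqrt(1 - q) * stats::rnorm(n_samples)
    ch <- children[((i - 1L) * children_per_parent + 1L):
                     (i * children_per_parent)]
    amat[ch, ] <- sqrt(r) * matrix(latent, length(ch), n_samples,
                                   byrow = TRUE) +
      sqrt(1 - r) * matrix(stats::rnorm(length(ch) * n_samples),
                           length(ch))
  }
  if (length(extras)) {
    amat[extras, ] <- matrix(stats::rnorm(length(extras) * n_samples),
                             length(extras))
  }
  list(network = network, activity_matrix = amat)
}

#' Write a complete synthetic study directory
#'
#' Emits every file the pipeline subcommands consume: the PKN SIF and
#' node sidecar, regulon table, transcript/metabolite statistics, count
#' matrix, ground-truth network and a run configuration.
#'
#' @param preset `"tiny"`, `"small"` or `"medium"`.
#' @param dir output directory.
#' @param seed RNG seed.
#' @return (invisibly) the `planted_study` that was written.
#' @export
simulate_study_preset <- function(preset = c("tiny", "small", "medium"),
                                  dir, seed = 1) {
  preset <- match.arg(preset)
  par <- switch(preset,
    tiny = list(n_inputs = 2, n_decoy = 3, n_null_regulators = 3,
                n_features = 150, n_samples = 4),
    small = list(n_inputs = 4, n_decoy = 14, n_null_regulators = 6,
                 n_features = 300, n_samples = 6),
    medium = list(n_inputs = 8, n_decoy = 40, n_null_regulators = 10,
                  n_features = 600, n_samples = 10))
  study <- generate_planted_study(
    n_inputs = par$n_inputs, n_decoy = par$n_decoy,
    n_null_regulators = par$n_null_regulators,
    n_features = par$n_features, n_samples = par$n_samples, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pkn_sif(study$pkn, file.path(dir, "pkn.sif"),
                file.path(dir, "pkn_nodes.tsv"))
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(study$regulons, "regulons.tsv")
  wt(study$stat_tables$transcript, "stats_transcript.tsv")
  wt(study$stat_tables$metabolite, "stats_metabolite.tsv")
  utils::write.table(data.frame(gene = rownames(study$counts),
                                study$counts, check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt(study$true_network$active_edges, "true_edges.tsv")
  wt(data.frame(node = names(study$true_network$node_state),
                state = unname(study$true_network$node_state)),
     "true_nodes.tsv")
  writeLines(c(
    "[run]",
    paste0("seed = ", seed),
    paste0("beta = ", study$beta),
    "nes_cut = 1.7", "p_cut = 0.05",
    "k_forward = 8", "k_backward = 7",
    "time_limit_s = 120", "pool_cap = 100",
    "backend = \"bnb\""), file.path(dir, "run.toml"))
  invisible(study)
}
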