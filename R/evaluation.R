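#' Co-regulated pairs from network topology
#'
#' All unordered pairs of nodes that share an active parent (some node p
#' with edges p -> a and p -> b): direct downstream targets of the same
#' regulator are expected to be co-regulated.
#'
#' @param network edge data.frame (`source`, `target`; e.g. the merged
#'   network or a pool's `edge_weight` table).
#' @param measurable optional character vector; pairs are restricted to
#'   nodes with measurable activities (e.g. rownames of an activity
#'   matrix).
#' @return data.frame with columns `a`, `b` (a < b), one row per pair.
#' @export
topology_coregulation_pairs <- function(network, measurable = NULL) {
  if (!nrow(network)) stop("network is empty")
  kids <- split(network$target, network$source)
  pairs <- unique(do.call(rbind, lapply(kids, function(ch) {
    ch <- unique(ch)
    if (!is.null(measurable)) ch <- intersect(ch, measurable)
    if (length(ch) < 2L) return(NULL)
    t(utils::combn(sort(ch), 2L))
  })))
  if (is.null(pairs)) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(a = pairs[, 1], b = pairs[, 2], stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

#' True-positive rate of predicted co-regulation vs correlation
#'
#' For each absolute-correlation threshold t, the TPR is the fraction of
#' predicted pairs whose activity profiles have |correlation| >= t.
#' Pairs with a member missing from the matrix are dropped (the number of
#' evaluable pairs is reported alongside).
#'
#' @param pairs data.frame (`a`, `b`) from
#'   [topology_coregulation_pairs()].
#' @param activity_matrix regulators x samples matrix (>= 3 samples).
#' @param thresholds correlation thresholds (default 0 to 1 step 0.01).
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame `threshold`, `tpr`, with attribute `n` = number of
#'   evaluable pairs.
#' @export
coregulation_tpr <- function(pairs, activity_matrix,
                             thresholds = seq(0, 1, by = 0.01),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(activity_matrix) < 3L) stop("need at least 3 samples")
  ok <- pairs$a %in% rownames(activity_matrix) &
    pairs$b %in% rownames(activity_matrix)
  pairs <- pairs[ok, , drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    stats::cor(activity_matrix[pairs$a[i], ], activity_matrix[pairs$b[i], ],
               method = method, use = "pairwise.complete.obs")
  }, 0)
  r <- abs(r[is.finite(r)])
  tpr <- vapply(thresholds, function(t) {
    if (!length(r)) NA_real_ else mean(r >= t)
  }, 0)
  out <- data.frame(threshold = thresholds, tpr = tpr)
  attr(out, "n") <- length(r)
  out
}

#' Random-pair baseline TPR with uncertainty band
#'
#' Draws `n_repeats` sets of `n_pairs` uniformly random node pairs from
#' the activity matrix and reports the mean and 2.5/97.5 percentile TPR
#' per threshold — the reference any topology-derived TPR must beat.
#'
#' @param activity_matrix regulators x samples matrix.
#' @param n_pairs pairs per draw.
#' @param n_repeats number of random draws (default 1000).
#' @param seed RNG seed.
#' @param thresholds correlation thresholds.
#' @param method correlation estimator.
#' @return data.frame `threshold`, `mean`, `lo`, `hi`.
#' @export
random_baseline <- function(activity_matrix, n_pairs, n_repeats = 1000,
                            seed = 1, thresholds = seq(0, 1, by = 0.01),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- nrow(activity_matrix)
  if (choose(n, 2) < n_pairs) stop("matrix has fewer than n_pairs pairs")
  set.seed(seed)
  cm <- abs(stats::cor(t(activity_matrix), method = method))
  vals <- cm[upper.tri(cm)]
  draws <- matrix(vals[sample.int(length(vals), n_pairs * n_repeats,
                                  replace = TRUE)],
                  nrow = n_repeats)
  tpr_mat <- vapply(thresholds, function(t) rowMeans(draws >= t),
                    numeric(n_repeats))
  data.frame(threshold = thresholds,
             mean = colMeans(tpr_mat),
             lo = apply(tpr_mat, 2L, stats::quantile, probs = 0.025),
             hi = apply(tpr_mat, 2L, stats::quantile, probs = 0.975))
}

#' Shuffle a fraction of PKN edges
#'
#' Selects `ceiling(fraction * |E|)` edges uniformly and permutes their
#' target endpoints among themselves (signs stay with their rows), which
#' preserves the overall in-degree multiset while destroying the selected
#' causal links. Duplicate edges arising from the permutation are
#' deduplicated and counted. With `mode = "rewire"` the selected edges
#' instead get fully random new targets.
#'
#' @param pkn a `causal_pkn`.
#' @param fraction fraction of edges to shuffle, in [0, 1].
#' @param seed RNG seed.
#' @param mode `"permute"` (default) or `"rewire"`.
#' @return the shuffled `causal_pkn`; attribute `n_duplicates` counts
#'   edges lost to deduplication.
#' @export
shuffle_pkn <- function(pkn, fraction, seed, mode = c("permute", "rewire")) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  e <- pkn$edges
  if (fraction == 0 || !nrow(e)) {
    out <- pkn
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  set.seed(seed)
  k <- ceiling(fraction * nrow(e))
  idx <- sample.int(nrow(e), k)
  if (mode == "permute") {
    e$target[idx] <- e$target[idx][sample.int(k)]
  } else {
    e$target[idx] <- sample(pkn_nodes(pkn), k, replace = TRUE)
  }
  e <- e[e$source != e$target, , drop = FALSE]
  dup <- duplicated(edge_key(e))
  out <- causal_pkn(e[!dup, , drop = FALSE], node_kind = pkn$node_kind)
  attr(out, "n_duplicates") <- sum(dup) + (nrow(pkn$edges) - nrow(e))
  out
}

#' Compare edge weights between two solution pools
#'
#' Over the union of edges of both pools (an edge absent from a pool has
#' weight 0), reports the per-edge absolute weight difference
#' distribution: median |delta|, fraction |delta| = 0 and fraction
#' flipped (0 in one pool, 100 in the other).
#'
#' @param pool_a,pool_b `causal_solution_pool` objects (or bare edge
#'   weight data.frames with columns source/sign/target/weight).
#' @return list with `summary` (median_abs_diff, frac_zero,
#'   frac_flipped, n_edges) and `per_edge` (data.frame).
#' @export
compare_edge_weights <- function(pool_a, pool_b) {
  wa <- if (inherits(pool_a, "causal_solution_pool")) pool_a$edge_weight else
    pool_a
  wb <- if (inherits(pool_b, "causal_solution_pool")) pool_b$edge_weight else
    pool_b
  ka <- edge_key(wa); kb <- edge_key(wb)
  keys <- union(ka, kb)
  if (!length(keys)) {
    return(list(summary = data.frame(median_abs_diff = 0, frac_zero = 1,
                                     frac_flipped = 0, n_edges = 0L),
                per_edge = data.frame(source = character(), sign = integer(),
                                      target = character(),
                                      weight_a = numeric(),
                                      weight_b = numeric(),
                                      abs_diff = numeric(),
                                      stringsAsFactors = FALSE)))
  }
  a <- stats::setNames(wa$weight, ka)[keys]
  b <- stats::setNames(wb$weight, kb)[keys]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  d <- abs(a - b)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  per_edge <- data.frame(source = parts[, 1],
                         sign = as.integer(parts[, 2]),
                         target = parts[, 3],
                         weight_a = unname(a), weight_b = unname(b),
                         abs_diff = unname(d), stringsAsFactors = FALSE)
  per_edge <- per_edge[order(per_edge$source, per_edge$target,
                             per_edge$sign), , drop = FALSE]
  rownames(per_edge) <- NULL
  flipped <- (a == 0 & b == 100) | (a == 100 & b == 0)
  list(summary = data.frame(median_abs_diff = stats::median(d),
                            frac_zero = mean(d == 0),
                            frac_flipped = mean(flipped),
                            n_edges = length(d)),
       per_edge = per_edge)
}

#' Prior-network shuffling robustness harness
#'
#' Runs the forward pipeline on the study's original PKN, then once per
#' shuffling fraction on a shuffled PKN, and summarizes how the solution
#' edge weights change (median |delta weight|, fraction unchanged,
#' fraction fully flipped).
#'
#' @param study a `planted_study` (see [generate_planted_study()]).
#' @param fractions shuffling fractions (e.g. `c(0, 0.02, 0.1, 0.5)`).
#' @param config a [run_config()].
#' @param seed RNG seed for the shuffles.
#' @return data.frame, one row per fraction: fraction, median_abs_diff,
#'   frac_zero, frac_flipped, n_edges, status.
#' @export
evaluate_shuffle_robustness <- function(study,
                                        fractions = c(0, 0.02, 0.1, 0.5),
                                        config = run_config(), seed = 1) {
  acts <- estimate_activities(study$regulons,
                              study$stat_tables$transcript,
                              min_targets = config$min_targets)
  base_pool <- run_forward(study$pkn, acts, study$stat_tables$metabolite,
                           config = config, counts = study$counts,
                           transcript_stats = study$stat_tables$transcript)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    spkn <- shuffle_pkn(study$pkn, f, seed = seed + i)
    pool <- tryCatch(
      run_forward(spkn, acts, study$stat_tables$metabolite, config = config,
                  counts = study$counts,
                  transcript_stats = study$stat_tables$transcript),
      error = function(e) NULL)
    if (is.null(pool)) {
      empty <- data.frame(source = character(), sign = integer(),
                          target = character(), weight = numeric(),
                          stringsAsFactors = FALSE)
      cmp <- compare_edge_weights(base_pool$edge_weight, empty)
      status <- "no_solution"
    } else {
      cmp <- compare_edge_weights(base_pool, pool)
      status <- pool$status
    }
    cbind(data.frame(fraction = f), cmp$summary,
          data.frame(status = status, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
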