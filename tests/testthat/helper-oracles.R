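# Independent oracles and generators used across the suite. These
# re-derive expected values from first principles and never call the
# implementation paths they check.

# -- permutation null for enrichment scores ----------------------------------

# Empirical z-score of a regulon's raw enrichment score against the
# permutation null (statistics permuted among features, i.e. target
# z-scores resampled without replacement).
perm_null_z <- function(targets, modes, weights, stat_tab, n_perm = 1e4,
                        seed = 1) {
  n <- nrow(stat_tab)
  z <- qnorm((rank(stat_tab$statistic, ties.method = "average") - 0.5) / n)
  names(z) <- stat_tab$feature_id
  a <- weights * modes
  s_obs <- sum(a * z[targets])
  k <- length(targets)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(i) sum(a * z[sample.int(n, k)]), 0)
  (s_obs - mean(null)) / sd(null)
}

# -- monotone boolean rules ---------------------------------------------------

# gene tokens of a GPR string
gpr_genes <- function(text) {
  toks <- regmatches(text, gregexpr("[^()[:space:]]+", text))[[1]]
  sort(unique(toks[!tolower(toks) %in% c("and", "or", "&", "|")]))
}

# minimal satisfying gene sets by truth-table enumeration (the minimal
# DNF of a monotone formula)
truth_table_minimal_models <- function(text) {
  genes <- gpr_genes(text)
  expr_txt <- gsub("\\bAND\\b", "&", gsub("\\bOR\\b", "|", text,
                                          ignore.case = TRUE),
                   ignore.case = TRUE)
  ex <- parse(text = expr_txt)[[1]]
  models <- list()
  for (mask in 0:(2^length(genes) - 1)) {
    on <- genes[bitwAnd(mask, bitwShiftL(1L, seq_along(genes) - 1L)) != 0L]
    env <- list2env(setNames(as.list(genes %in% on), genes),
                    parent = baseenv())
    if (isTRUE(eval(ex, env))) models[[length(models) + 1L]] <- on
  }
  keep <- vapply(seq_along(models), function(i) {
    !any(vapply(seq_along(models), function(j) {
      i != j && length(models[[j]]) < length(models[[i]]) &&
        all(models[[j]] %in% models[[i]])
    }, TRUE))
  }, TRUE)
  models <- models[keep]
  models[order(vapply(models, paste, "", collapse = "_"))]
}

# random monotone GPR over up to `max_genes` genes
random_gpr <- function(seed, max_genes = 6, depth = 3) {
  set.seed(seed)
  genes <- paste0("G", seq_len(sample(2:max_genes, 1)))
  grow <- function(d) {
    if (d == 0 || runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c("AND", "OR"), 1)
    paste0("(", grow(d - 1), " ", op, " ", grow(d - 1), ")")
  }
  grow(depth)
}

# -- random causal instances --------------------------------------------------

sol_key <- function(s) {
  ns <- s$node_state[order(names(s$node_state))]
  paste(paste(names(ns), ns, collapse = ";"),
        paste(s$active_edges$source, s$active_edges$sign,
              s$active_edges$target, collapse = ";"), sep = "|")
}

pool_keys <- function(pool) sort(vapply(pool$solutions, sol_key, ""))

random_instance <- function(seed, max_edges = 12, max_nodes = 10,
                            beta = 0.2) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- paste0("N", seq_len(n))
  m <- sample(4:max_edges, 1)
  src <- sample(nodes, m, replace = TRUE)
  tgt <- sample(nodes, m, replace = TRUE)
  ok <- src != tgt
  if (!any(ok)) return(NULL)
  e <- data.frame(source = src[ok],
                  sign = sample(c(-1L, 1L), sum(ok), replace = TRUE),
                  target = tgt[ok], stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$source, e$sign, e$target)), , drop = FALSE]
  pkn <- causal_pkn(e)
  nn <- names(pkn$node_kind)
  ni <- sample(1:2, 1)
  ins <- setNames(sample(c(-1, 1), ni, replace = TRUE), sample(nn, ni))
  rest <- setdiff(nn, names(ins))
  if (!length(rest)) return(NULL)
  mn <- sample(rest, min(sample(1:3, 1), length(rest)))
  meas <- data.frame(node = mn,
                     sign = sample(c(-1, 1), length(mn), replace = TRUE),
                     weight = round(runif(length(mn), 0.5, 2), 2),
                     stringsAsFactors = FALSE)
  causal_instance(pkn, ins, meas, beta = beta, pool_cap = 1000)
}

edge_keys_df <- function(edges) {
  paste(edges$source, edges$sign, edges$target)
}

# hand-rolled BFS distances from a source set over an edge table
bfs_distances <- function(edges, sources) {
  dist <- setNames(rep(Inf, length(unique(c(edges$source, edges$target,
                                            sources)))),
                   unique(c(edges$source, edges$target, sources)))
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(edges$target[edges$source %in% frontier])
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# enumerate all binary assignments of an abstract ILP model (node/edge
# binaries), check the linear constraints plus acyclicity of the active
# edges, and return the minimum objective. Independent check of
# build_ilp()'s formulation on tiny instances.
ilp_enumerate_min <- function(model, instance) {
  vars <- model$variables
  bin <- vars$name[vars$type == "binary"]
  stopifnot(length(bin) <= 16)
  e <- instance$pkn$edges
  best <- Inf
  for (mask in 0:(2^length(bin) - 1)) {
    x <- setNames(as.numeric(
      bitwAnd(mask, bitwShiftL(1L, seq_along(bin) - 1L)) != 0L), bin)
    ok <- TRUE
    for (cn in model$constraints) {
      nm <- names(cn$coef)
      if (any(startsWith(nm, "ord_"))) next # handled via acyclicity below
      lhs <- sum(cn$coef * x[nm])
      ok <- switch(cn$dir,
                   "<=" = lhs <= cn$rhs + 1e-9,
                   ">=" = lhs >= cn$rhs - 1e-9,
                   "==" = abs(lhs - cn$rhs) < 1e-9)
      if (!ok) break
    }
    if (!ok) next
    act <- which(x[paste0("ep_", seq_len(nrow(e)))] +
                   x[paste0("en_", seq_len(nrow(e)))] > 0)
    if (length(act) > 1L) {
      g <- igraph::graph_from_data_frame(
        e[act, c("source", "target")], directed = TRUE)
      if (!igraph::is_dag(g)) next
    }
    obj <- sum(model$objective * x[names(model$objective)]) +
      model$objective_constant
    best <- min(best, obj)
  }
  best
}
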