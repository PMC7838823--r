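#' Assemble a causal optimization instance
#'
#' Bundles a PKN with fixed-sign input nodes (perturbation/regulator
#' states), weighted sign measurements (downstream readouts), and run
#' parameters. Input and measurement ids absent from the PKN are recorded
#' on the instance and excluded from the optimization (with a warning);
#' measurements present in the network but unreachable simply stay
#' mismatched in any solution.
#'
#' @param pkn a `causal_pkn`.
#' @param inputs named numeric vector of -1/+1 (or data.frame
#'   `node`,`sign`). Input states are hard constraints.
#' @param measurements data.frame `node`,`sign`,`weight` (weight defaults
#'   to 1) or a named numeric vector of signs.
#' @param beta size penalty per stated node (default 0.2).
#' @param time_limit_s solver time budget in seconds.
#' @param pool_cap maximum number of equally optimal solutions returned.
#' @return object of class `causal_instance`.
#' @export
causal_instance <- function(pkn, inputs, measurements, beta = 0.2,
                            time_limit_s = 600, pool_cap = 100) {
  stopifnot(inherits(pkn, "causal_pkn"), beta >= 0, time_limit_s > 0,
            pool_cap >= 1)
  if (is.data.frame(inputs)) {
    inputs <- stats::setNames(as.numeric(inputs$sign),
                              as.character(inputs$node))
  }
  if (!length(inputs)) stop("at least one input node is required")
  if (!all(inputs %in% c(-1, 1))) stop("input signs must be -1 or +1")
  if (is.numeric(measurements) && !is.null(names(measurements))) {
    measurements <- data.frame(node = names(measurements),
                               sign = as.numeric(measurements), weight = 1,
                               stringsAsFactors = FALSE)
  }
  if (!nrow(measurements)) stop("at least one measurement is required")
  if (is.null(measurements$weight)) measurements$weight <- 1
  if (!all(measurements$sign %in% c(-1, 1))) {
    stop("measurement signs must be -1 or +1")
  }
  if (any(measurements$weight < 0)) stop("measurement weights must be >= 0")
  nodes <- sort(pkn_nodes(pkn))
  missing_inputs <- setdiff(names(inputs), nodes)
  missing_meas <- setdiff(measurements$node, nodes)
  if (length(missing_inputs) || length(missing_meas)) {
    warning("id(s) absent from the PKN excluded from the run: ",
            paste(c(missing_inputs, missing_meas), collapse = ", "))
  }
  inputs <- inputs[setdiff(names(inputs), missing_inputs)]
  measurements <- measurements[!(measurements$node %in% missing_meas), ,
                               drop = FALSE]
  measurements <- measurements[!duplicated(measurements$node), , drop = FALSE]
  rownames(measurements) <- NULL
  structure(list(
    pkn = pkn, nodes = nodes, inputs = inputs,
    measurements = measurements[, c("node", "sign", "weight")],
    beta = beta, time_limit_s = time_limit_s, pool_cap = pool_cap,
    missing_inputs = missing_inputs, missing_measurements = missing_meas),
    class = "causal_instance")
}

#' @export
print.causal_instance <- function(x, ...) {
  cat("Causal optimization instance\n")
  cat("  PKN:", nrow(x$pkn$edges), "edges over", length(x$nodes), "nodes\n")
  cat("  inputs:", length(x$inputs),
      " measurements:", nrow(x$measurements), "\n")
  cat("  beta:", x$beta, " time limit:", x$time_limit_s, "s",
      " pool cap:", x$pool_cap, "\n")
  if (length(x$missing_inputs) || length(x$missing_measurements)) {
    cat("  excluded (absent from PKN):",
        length(x$missing_inputs), "inputs,",
        length(x$missing_measurements), "measurements\n")
  }
  invisible(x)
}

# mismatch term |target - state| with state in {-1, 0, +1}
mismatch_cost <- function(meas, state_of) {
  s <- state_of[meas$node]
  s[is.na(s)] <- 0
  sum(meas$weight * abs(meas$sign - s))
}

#' Build the abstract ILP model of an instance
#'
#' Variables: per node u, sign-split binaries `up_u`, `dn_u` with
#' `up_u + dn_u <= 1`; per edge e = (u, s, v), activation and inhibition
#' carriers `ep_e`, `en_e`; per node a continuous order variable
#' `ord_u` in [0, N] used for loop prevention. Constraints: inputs fixed;
#' carriers gated by the source state (`ep <= up_u` for s = +1, etc.);
#' non-input node states supported by incoming carriers
#' (`up_v <= sum ep`, `dn_v <= sum en`); big-M order constraints
#' `ord_v >= ord_u + 1 - N (1 - ep - en)` forbidding cycles. Objective:
#' sum over measurements of weight * |target - (up - dn)| (linear because
#' the target is +-1) plus beta * sum of node binaries.
#'
#' @param instance a `causal_instance`.
#' @return list with `variables` (data.frame name/type/lb/ub),
#'   `constraints` (list of `list(coef, dir, rhs)`), `objective`
#'   (named coefficients) and `objective_constant`.
#' @export
build_ilp <- function(instance) {
  pkn <- instance$pkn
  nodes <- instance$nodes
  N <- length(nodes)
  e <- pkn$edges
  up <- paste0("up_", nodes); dn <- paste0("dn_", nodes)
  ep <- paste0("ep_", seq_len(nrow(e))); en <- paste0("en_", seq_len(nrow(e)))
  ord <- paste0("ord_", nodes)
  variables <- rbind(
    data.frame(name = c(up, dn, ep, en), type = "binary", lb = 0, ub = 1,
               stringsAsFactors = FALSE),
    data.frame(name = ord, type = "continuous", lb = 0, ub = N,
               stringsAsFactors = FALSE))
  cons <- list()
  add <- function(coef, dir, rhs) {
    cons[[length(cons) + 1L]] <<- list(coef = coef, dir = dir, rhs = rhs)
  }
  for (i in seq_len(N)) {
    add(stats::setNames(c(1, 1), c(up[i], dn[i])), "<=", 1)
  }
  for (nm in names(instance$inputs)) {
    i <- match(nm, nodes)
    if (instance$inputs[[nm]] > 0) {
      add(stats::setNames(1, up[i]), "==", 1)
    } else {
      add(stats::setNames(1, dn[i]), "==", 1)
    }
  }
  inc_ep <- split(seq_len(nrow(e)), factor(e$target, levels = nodes))
  for (j in seq_len(nrow(e))) {
    ui <- match(e$source[j], nodes); vi <- match(e$target[j], nodes)
    src_pos <- if (e$sign[j] > 0) up[ui] else dn[ui]
    src_neg <- if (e$sign[j] > 0) dn[ui] else up[ui]
    add(stats::setNames(c(1, -1), c(ep[j], src_pos)), "<=", 0)
    add(stats::setNames(c(1, -1), c(en[j], src_neg)), "<=", 0)
    # ord_u - ord_v + N ep + N en <= N - 1
    add(stats::setNames(c(1, -1, N, N), c(ord[ui], ord[vi], ep[j], en[j])),
        "<=", N - 1)
  }
  for (i in seq_len(N)) {
    if (nodes[i] %in% names(instance$inputs)) next
    js <- inc_ep[[i]]
    add(stats::setNames(c(1, rep(-1, length(js))), c(up[i], ep[js])), "<=", 0)
    add(stats::setNames(c(1, rep(-1, length(js))), c(dn[i], en[js])), "<=", 0)
  }
  obj <- stats::setNames(rep(0, length(c(up, dn))), c(up, dn))
  obj[up] <- obj[up] + instance$beta
  obj[dn] <- obj[dn] + instance$beta
  const <- 0
  for (r in seq_len(nrow(instance$measurements))) {
    m <- instance$measurements[r, ]
    i <- match(m$node, nodes)
    const <- const + m$weight
    if (m$sign > 0) { # w (1 - up + dn)
      obj[up[i]] <- obj[up[i]] - m$weight
      obj[dn[i]] <- obj[dn[i]] + m$weight
    } else {
      obj[dn[i]] <- obj[dn[i]] - m$weight
      obj[up[i]] <- obj[up[i]] + m$weight
    }
  }
  list(variables = variables, constraints = cons, objective = obj,
       objective_constant = const)
}

# ---- solver internals -------------------------------------------------------

# signed-node encoding: node i with state +1 -> 2i-1, state -1 -> 2i
signed_id <- function(i, s) 2L * i - as.integer(s > 0)

# adjacency of the signed-split graph: out[[sid]] = target signed ids
signed_adjacency <- function(instance) {
  nodes <- instance$nodes
  e <- instance$pkn$edges
  from <- match(e$source, nodes); to <- match(e$target, nodes)
  out <- vector("list", 2L * length(nodes))
  for (j in seq_along(from)) {
    # source +1 propagates sign, source -1 flips it
    out[[signed_id(from[j], 1L)]] <-
      c(out[[signed_id(from[j], 1L)]], signed_id(to[j], e$sign[j]))
    out[[signed_id(from[j], -1L)]] <-
      c(out[[signed_id(from[j], -1L)]], signed_id(to[j], -e$sign[j]))
  }
  lapply(out, unique)
}

# BFS over signed nodes from the current closed set; returns distances
# (number of nodes to add) and BFS parents for path extraction.
signed_bfs <- function(adj, in_a, forb, state_of) {
  n2 <- length(adj)
  dist <- rep(Inf, n2); parent <- integer(n2)
  queue <- which(in_a)
  dist[queue] <- 0
  head <- 1L
  while (head <= length(queue)) {
    s <- queue[head]; head <- head + 1L
    for (t in adj[[s]]) {
      if (is.finite(dist[t]) || forb[t]) next
      v <- (t + 1L) %/% 2L
      sgn <- if (t %% 2L == 1L) 1L else -1L
      if (state_of[v] != 0L && state_of[v] != sgn) next # opposite state fixed
      dist[t] <- dist[s] + 1
      parent[t] <- s
      queue <- c(queue, t)
    }
  }
  list(dist = dist, parent = parent)
}

solve_bnb <- function(instance) {
  nodes <- instance$nodes
  n <- length(nodes)
  adj <- signed_adjacency(instance)
  meas <- instance$measurements
  beta <- instance$beta
  eps <- 1e-9
  m_idx <- match(meas$node, nodes)
  m_sid <- signed_id(m_idx, meas$sign)
  in_a <- rep(FALSE, 2L * n)
  state_of <- rep(0L, n)
  for (nm in names(instance$inputs)) {
    i <- match(nm, nodes)
    state_of[i] <- as.integer(instance$inputs[[nm]])
    in_a[signed_id(i, state_of[i])] <- TRUE
  }
  n_stated <- sum(state_of != 0L)
  forb <- rep(FALSE, 2L * n)
  # an input's opposite state can never be taken
  for (i in which(state_of != 0L)) forb[signed_id(i, -state_of[i])] <- TRUE

  best <- Inf
  found <- new.env(parent = emptyenv())
  n_found <- 0L
  max_keep <- max(1000L, 10L * instance$pool_cap)
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE

  current_cost <- function() {
    s <- state_of[m_idx]
    beta * n_stated + sum(meas$weight * abs(meas$sign - s))
  }
  record <- function(cost) {
    if (cost > best + eps) return(invisible())
    if (cost < best - eps) {
      best <<- cost
      for (k in ls(found)) if (found[[k]] > best + eps) rm(list = k,
                                                          envir = found)
      n_found <<- length(ls(found))
    }
    key <- paste(which(in_a), collapse = ",")
    if (is.null(found[[key]]) && n_found < max_keep) {
      found[[key]] <- cost
      n_found <<- n_found + 1L
    }
    invisible()
  }
  recurse <- function() {
    if (timed_out) return(invisible())
    if (proc.time()[["elapsed"]] - t0 > instance$time_limit_s) {
      timed_out <<- TRUE
      return(invisible())
    }
    bfs <- signed_bfs(adj, in_a, forb, state_of)
    unsat <- which(state_of[m_idx] == 0L)
    reach <- unsat[is.finite(bfs$dist[m_sid[unsat]])]
    unreach <- setdiff(unsat, reach)
    stated_m <- which(state_of[m_idx] != 0L)
    lb <- beta * n_stated +
      sum(meas$weight[stated_m] *
            abs(meas$sign[stated_m] - state_of[m_idx[stated_m]])) +
      sum(meas$weight[unreach])
    lb <- lb + if (length(reach) == 1L) {
      min(meas$weight[reach], beta * bfs$dist[m_sid[reach]])
    } else {
      sum(pmin(meas$weight[reach], beta))
    }
    if (lb > best + eps) return(invisible())
    if (!length(reach)) {
      record(current_cost())
      return(invisible())
    }
    # branch on the first new signed node of a shortest path to the
    # heaviest reachable unsatisfied measurement
    pick <- reach[order(-meas$weight[reach], m_idx[reach])][1L]
    path <- integer(0)
    cur <- m_sid[pick]
    while (!in_a[cur]) {
      path <- c(cur, path)
      cur <- bfs$parent[cur]
    }
    x <- path[1L]
    xv <- (x + 1L) %/% 2L
    xs <- if (x %% 2L == 1L) 1L else -1L
    # include x
    in_a[x] <<- TRUE; state_of[xv] <<- xs; n_stated <<- n_stated + 1L
    recurse()
    in_a[x] <<- FALSE; state_of[xv] <<- 0L; n_stated <<- n_stated - 1L
    # forbid x
    forb[x] <<- TRUE
    recurse()
    forb[x] <<- FALSE
    invisible()
  }
  record(current_cost()) # the inputs-only network is always feasible
  recurse()
  keys <- ls(found)
  keep <- keys[vapply(keys, function(k) found[[k]] <= best + eps, TRUE)]
  state_sets <- lapply(keep, function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  list(best = best, state_sets = state_sets,
       status = if (timed_out) "time_limit" else "optimal")
}

# enumerate minimal edge certificates for one optimal state assignment:
# every non-input stated node takes exactly one supporting in-edge; the
# chosen edges must let every stated node be reached from the inputs
# (which also guarantees acyclicity of the active subgraph).
enumerate_certificates <- function(instance, sid_set, cap) {
  nodes <- instance$nodes
  e <- instance$pkn$edges
  state_of <- rep(0L, length(nodes))
  for (s in sid_set) {
    state_of[(s + 1L) %/% 2L] <- if (s %% 2L == 1L) 1L else -1L
  }
  stated <- which(state_of != 0L)
  non_input <- stated[!(nodes[stated] %in% names(instance$inputs))]
  cand <- lapply(non_input, function(v) {
    which(e$target == nodes[v] &
            state_of[match(e$source, nodes)] != 0L &
            e$sign * state_of[match(e$source, nodes)] == state_of[v])
  })
  if (any(lengths(cand) == 0L) && length(non_input)) return(list())
  sols <- list()
  choice <- integer(length(non_input))
  valid_choice <- function() {
    known <- stats::setNames(rep(FALSE, length(stated)), nodes[stated])
    known[names(instance$inputs)] <- TRUE
    repeat {
      changed <- FALSE
      for (i in seq_along(non_input)) {
        v <- nodes[non_input[i]]
        if (known[[v]]) next
        src <- e$source[choice[i]]
        if (known[[src]]) {
          known[[v]] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    all(known)
  }
  rec <- function(i) {
    if (length(sols) >= cap) return(invisible())
    if (i > length(non_input)) {
      if (valid_choice()) {
        active <- e[choice, c("source", "sign", "target"), drop = FALSE]
        active <- active[order(active$source, active$target, active$sign), ,
                         drop = FALSE]
        rownames(active) <- NULL
        sols[[length(sols) + 1L]] <<- list(
          node_state = stats::setNames(as.numeric(state_of[stated]),
                                       nodes[stated]),
          active_edges = active)
      }
      return(invisible())
    }
    for (j in cand[[i]]) {
      choice[i] <<- j
      rec(i + 1L)
      if (length(sols) >= cap) return(invisible())
    }
    invisible()
  }
  if (!length(non_input)) {
    sols[[1L]] <- list(
      node_state = stats::setNames(as.numeric(state_of[stated]),
                                   nodes[stated]),
      active_edges = e[integer(0), c("source", "sign", "target")])
  } else {
    rec(1L)
  }
  sols
}

make_pool <- function(instance, solutions, objective, status) {
  for (i in seq_along(solutions)) {
    solutions[[i]]$objective <- objective
    st <- solutions[[i]]$node_state
    solutions[[i]]$node_state <- st[order(names(st))]
  }
  # deterministic order by canonical solution key
  keyf <- function(s) paste(
    paste(names(s$node_state), s$node_state, collapse = ";"),
    paste(edge_key(s$active_edges), collapse = ";"), sep = "|")
  keys <- vapply(solutions, keyf, "")
  solutions <- solutions[order(keys)]
  truncated <- length(solutions) > instance$pool_cap
  if (truncated) solutions <- solutions[seq_len(instance$pool_cap)]
  ew <- if (length(solutions)) {
    all_e <- do.call(rbind, lapply(solutions, function(s) s$active_edges))
    if (nrow(all_e)) {
      k <- edge_key(all_e)
      cnt <- table(k)
      uniq <- all_e[!duplicated(k), , drop = FALSE]
      uniq$weight <- 100 * as.numeric(cnt[edge_key(uniq)]) / length(solutions)
      uniq <- uniq[order(uniq$source, uniq$target, uniq$sign), , drop = FALSE]
      rownames(uniq) <- NULL
      uniq
    } else {
      data.frame(source = character(), sign = integer(), target = character(),
                 weight = numeric(), stringsAsFactors = FALSE)
    }
  } else {
    data.frame(source = character(), sign = integer(), target = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  stated_any <- unique(unlist(lapply(solutions, function(s)
    names(s$node_state))))
  unreachable <- c(instance$missing_measurements,
                   setdiff(instance$measurements$node, stated_any))
  structure(list(
    solutions = solutions, edge_weight = ew, status = status,
    objective = objective, n_solutions = length(solutions),
    truncated = truncated, instance = instance,
    unreachable_measurements = unreachable),
    class = "causal_solution_pool")
}

#' Solve a causal instance
#'
#' Finds the sign-consistent, loop-free subnetworks of minimum objective
#' (measurement mismatch + beta x network size) connecting the fixed-sign
#' inputs to the weighted measurements, and enumerates the pool of equally
#' optimal solutions. A solution is a node-state assignment together with
#' a minimal supporting edge set (each non-input stated node keeps exactly
#' one incoming active edge), so the active subgraph is an acyclic forest
#' rooted at the inputs.
#'
#' The `"bnb"` backend is an exact branch-and-bound over closed sets of
#' signed nodes (admissible lower bound; complete enumeration of optima);
#' the `"exhaustive"` backend delegates to [brute_force_solve()] and is
#' limited to 20 edges.
#'
#' @param instance a `causal_instance`.
#' @param backend `"bnb"` (default) or `"exhaustive"`.
#' @return a `causal_solution_pool`: solutions, per-edge pool frequencies
#'   (0-100), best objective and solver status (`"optimal"`,
#'   `"time_limit"` or `"infeasible"`).
#' @export
solve_instance <- function(instance, backend = c("bnb", "exhaustive")) {
  backend <- match.arg(backend)
  if (backend == "exhaustive") return(brute_force_solve(instance))
  if (!length(instance$inputs)) {
    return(make_pool(instance, list(), Inf, "infeasible"))
  }
  res <- solve_bnb(instance)
  sols <- list()
  for (ss in res$state_sets) {
    cap <- instance$pool_cap + 1L - length(sols)
    if (cap <= 0L) break
    sols <- c(sols, enumerate_certificates(instance, ss, cap = cap))
  }
  make_pool(instance, sols, res$best, res$status)
}

#' @rdname solve_instance
#' @param a a `causal_instance` (method for [base::solve()]).
#' @param b unused (required by the [base::solve()] generic).
#' @param ... passed on to [solve_instance()].
#' @export
solve.causal_instance <- function(a, b, ...) solve_instance(a, ...)

#' Exhaustive reference solver
#'
#' Enumerates every subset of PKN edges, keeps the subsets that form a
#' valid solution network (states propagate from the inputs without
#' conflict, every non-input stated node has exactly one supporting
#' in-edge, no active edge enters an input, the active subgraph is
#' acyclic) and returns all subsets attaining the global optimum. Serves
#' as the independent oracle for [solve_instance()].
#'
#' @param instance a `causal_instance` with at most 20 edges.
#' @return a `causal_solution_pool`.
#' @export
brute_force_solve <- function(instance) {
  e <- instance$pkn$edges
  m <- nrow(e)
  if (m > 20L) stop("brute-force solver is limited to 20 edges (got ", m, ")")
  if (!length(instance$inputs)) {
    return(make_pool(instance, list(), Inf, "infeasible"))
  }
  nodes <- instance$nodes
  input_nodes <- names(instance$inputs)
  meas <- instance$measurements
  beta <- instance$beta
  eps <- 1e-9
  best <- Inf
  opt <- list()
  for (mask in 0:(2^m - 1)) {
    act <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(act)) {
      tgt <- e$target[act]
      if (any(tgt %in% input_nodes)) next       # inputs need no support
      if (anyDuplicated(tgt)) next              # exactly one in-edge
    }
    state <- stats::setNames(as.numeric(instance$inputs), input_nodes)
    remaining <- act
    ok <- TRUE
    while (length(remaining)) {
      ready <- remaining[e$source[remaining] %in% names(state)]
      if (!length(ready)) {
        ok <- FALSE
        break
      }
      for (j in ready) {
        state[[e$target[j]]] <- e$sign[j] * state[[e$source[j]]]
      }
      remaining <- setdiff(remaining, ready)
    }
    if (!ok) next
    cost <- beta * length(state) + mismatch_cost(meas, state)
    if (cost > best + eps) next
    active <- e[act, c("source", "sign", "target"), drop = FALSE]
    active <- active[order(active$source, active$target, active$sign), ,
                     drop = FALSE]
    rownames(active) <- NULL
    sol <- list(node_state = state, active_edges = active)
    if (cost < best - eps) {
      best <- cost
      opt <- list(sol)
    } else {
      opt[[length(opt) + 1L]] <- sol
    }
  }
  make_pool(instance, opt, best, "optimal")
}

#' Check the structural invariants of a solution network
#'
#' Verifies that every node state is -1/+1 and matches the fixed inputs,
#' that every non-input stated node has at least one supporting active
#' in-edge (sign times upstream state equals its own state), that every
#' stated node is reachable from an input along active edges, and that
#' the active subgraph is acyclic.
#'
#' @param solution one element of `pool$solutions`.
#' @param instance the `causal_instance` it came from.
#' @return `TRUE`, or a character vector of violated invariants.
#' @export
check_solution <- function(solution, instance) {
  errs <- character(0)
  st <- solution$node_state
  ae <- solution$active_edges
  if (!all(st %in% c(-1, 1))) errs <- c(errs, "node states must be -1/+1")
  for (nm in names(instance$inputs)) {
    if (!is.null(st[[nm]]) && !is.na(st[nm]) &&
        st[[nm]] != instance$inputs[[nm]]) {
      errs <- c(errs, paste0("input state violated for ", nm))
    }
  }
  non_input <- setdiff(names(st), names(instance$inputs))
  for (v in non_input) {
    inc <- ae[ae$target == v, , drop = FALSE]
    sup <- any(inc$source %in% names(st) &
                 inc$sign * st[inc$source] == st[[v]])
    if (!sup) errs <- c(errs, paste0("no sign support for ", v))
  }
  if (nrow(ae)) {
    g <- igraph::graph_from_data_frame(ae[, c("source", "target")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) errs <- c(errs, "active subgraph has a cycle")
  }
  # reachability from inputs along active edges
  known <- names(instance$inputs)
  repeat {
    ready <- ae$target[ae$source %in% known & !(ae$target %in% known)]
    if (!length(ready)) break
    known <- c(known, unique(ready))
  }
  if (!all(names(st) %in% c(known, names(instance$inputs)))) {
    errs <- c(errs, "stated node unreachable from inputs")
  }
  if (length(errs)) errs else TRUE
}

#' @export
print.causal_solution_pool <- function(x, ...) {
  cat("Causal solution pool (status: ", x$status, ")\n", sep = "")
  cat("  objective:", format(x$objective), "\n")
  cat("  solutions:", x$n_solutions,
      if (isTRUE(x$truncated)) "(pool capped)" else "", "\n")
  cat("  edges with weight > 0:", nrow(x$edge_weight), "\n")
  if (length(x$unreachable_measurements)) {
    cat("  unreachable/absent measurements:",
        paste(x$unreachable_measurements, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.causal_solution_pool <- function(object, ...) {
  print(object)
  if (nrow(object$edge_weight)) {
    cat("  edge weight distribution:\n")
    print(summary(object$edge_weight$weight))
  }
  invisible(object)
}

#' Plot the summary network of a solution pool
#'
#' Draws the union of active edges; edge width scales with pool
#' frequency, color encodes sign (activating vs inhibiting), vertex color
#' the consensus node state.
#'
#' @param x a `causal_solution_pool`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.causal_solution_pool <- function(x, ...) {
  ew <- x$edge_weight
  if (!nrow(ew)) {
    plot.new()
    title("empty solution network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(ew[, c("source", "target")],
                                     directed = TRUE)
  st <- consensus_states(x)
  vcol <- ifelse(is.na(st[igraph::V(g)$name]), "grey80",
                 ifelse(st[igraph::V(g)$name] > 0, "tomato", "steelblue"))
  igraph::plot.igraph(
    g, edge.width = 0.5 + 3 * ew$weight / 100,
    edge.color = ifelse(ew$sign > 0, "darkgreen", "firebrick"),
    vertex.color = vcol, vertex.label.cex = 0.8, ...)
  invisible(x)
}

# mean node state across the pool (NA for never-stated nodes)
consensus_states <- function(pool) {
  all_nodes <- unique(unlist(lapply(pool$solutions, function(s)
    names(s$node_state))))
  if (!length(all_nodes)) return(stats::setNames(numeric(0), character(0)))
  acc <- stats::setNames(rep(0, length(all_nodes)), all_nodes)
  for (s in pool$solutions) acc[names(s$node_state)] <-
    acc[names(s$node_state)] + s$node_state
  acc / length(pool$solutions)
}

#' Write a solution pool as attribute tables
#'
#' `edges.tsv`: source, sign, target, weight (pool frequency 0-100);
#' `nodes.tsv`: id, state (mean over the pool), is_input, is_measurement.
#'
#' @param pool a `causal_solution_pool`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_solution_pool <- function(pool, dir, prefix = "solution") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(pool$edge_weight,
                     file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  st <- consensus_states(pool)
  inst <- pool$instance
  nodes <- data.frame(
    id = names(st), state = unname(st),
    is_input = names(st) %in% names(inst$inputs),
    is_measurement = names(st) %in% inst$measurements$node,
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  utils::write.table(nodes, file.path(dir, paste0(prefix, "_nodes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
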