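test_that("expression filter drops unexpressed gene products only", {
  pkn <- causal_pkn(data.frame(
    source = c("G1", "metab__x", "G3"),
    sign = 1L,
    target = c("G2", "metab__y", "metab__x"),
    provenance = c("ppi", "metabolic", "metabolic")))
  counts <- matrix(c(60, 10, 80), 3, 4,
                   dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4)))
  out <- filter_expressed(pkn, counts, min_mean_count = 50)
  # the G1 -> G2 edge dies with G2; metabolite-only edges survive
  expect_false(any(out$edges$target == "G2"))
  expect_true(any(out$edges$source == "metab__x"))
  expect_true(any(out$edges$source == "G3"))
  # all genes expressed: identity
  hi <- matrix(100, 3, 4, dimnames = dimnames(counts))
  expect_identical(filter_expressed(pkn, hi)$edges, pkn$edges)
  # complex node fails if any member gene fails
  cx <- causal_pkn(data.frame(source = "metab__a", sign = 1L,
                              target = "G1_G2__R1",
                              provenance = "metabolic"),
                   node_kind = c(G1_G2__R1 = "complex"))
  expect_warning(out2 <- filter_expressed(cx, counts), "every edge")
  expect_equal(nrow(out2$edges), 0L)
})

test_that("reachability reduction keeps exactly the k-step neighborhood", {
  chain <- causal_pkn(data.frame(source = paste0("N", 1:9), sign = 1L,
                                 target = paste0("N", 2:10)))
  red <- reduce_to_reachable(chain, "N1", k = 7)
  expect_equal(length(red$node_kind), 8L)
  expect_equal(nrow(red$edges), 7L)
  r0 <- reduce_to_reachable(chain, "N1", k = 0)
  expect_identical(names(r0$node_kind), "N1")
  expect_equal(nrow(r0$edges), 0L)
  expect_warning(reduce_to_reachable(chain, c("N1", "ZZ"), k = 2), "ZZ")
  # disconnected node never appears
  two <- causal_pkn(data.frame(source = c("A", "X"), sign = 1L,
                               target = c("B", "Y")))
  red2 <- reduce_to_reachable(two, "A", k = 5)
  expect_false(any(c("X", "Y") %in% names(red2$node_kind)))
})

test_that("reduction output is a vertex-induced subgraph within distance k", {
  for (seed in 1:15) {
    pkn <- generate_random_pkn(n_protein = 12, n_metabolite = 4,
                               n_edges = 30, seed = seed)
    src <- names(pkn$node_kind)[1:2]
    k <- sample(0:4, 1)
    red <- reduce_to_reachable(pkn, src, k = k)
    d <- bfs_distances(pkn$edges, intersect(src, names(pkn$node_kind)))
    expect_true(all(d[names(red$node_kind)] <= k))
    # induced: every original edge between kept nodes is kept
    keep <- names(red$node_kind)
    orig <- pkn$edges[pkn$edges$source %in% keep &
                        pkn$edges$target %in% keep, ]
    expect_equal(nrow(red$edges), nrow(orig))
  }
})

test_that("transcriptional correction removes only incoherent edges", {
  pkn <- causal_pkn(data.frame(
    source = c("TF1", "TF1", "TF2", "TF1"),
    sign = c(1L, 1L, -1L, 1L),
    target = c("g1", "g2", "g3", "g4"),
    provenance = c("transcriptional", "transcriptional", "transcriptional",
                   "ppi")))
  acts <- structure(data.frame(node = "TF1", nes = 2.5),
                    class = c("activity_table", "data.frame"))
  tx <- data.frame(feature_id = c("g1", "g2", "g3", "g4"),
                   statistic = c(-3, -1, 2, -4),
                   p_value = c(0.01, 0.5, 0.01, 0.001),
                   log_fc = c(-1.2, -0.5, 0.8, -2))
  out <- correct_transcriptional_edges(pkn, acts, tx, p_cut = 0.05)
  keys <- paste(out$edges$source, out$edges$target)
  # TF1(+) -> g1 with g1 down & significant: removed
  expect_false("TF1 g1" %in% keys)
  # g2 not significant: retained; TF2 has no activity: retained
  expect_true(all(c("TF1 g2", "TF2 g3") %in% keys))
  # non-transcriptional edge incoherent but untouched
  expect_true("TF1 g4" %in% keys)
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("a solver pre-run fixes TF states that correct the PKN", {
  # unique optimum forces TF = -1 (input I inhibits TF), so the
  # transcriptional edge TF -(+1)-> g with g significantly UP is removed
  pkn <- causal_pkn(data.frame(
    source = c("I", "TF", "TF", "E"),
    sign = c(-1L, 1L, 1L, 1L),
    target = c("TF", "E", "g", "metab__m"),
    provenance = c("ppi", "ppi", "transcriptional", "metabolic")))
  tx <- data.frame(feature_id = "g", statistic = 3, p_value = 0.01,
                   log_fc = 1.5)
  out <- ilp_prerun_correction(
    pkn, inputs = c(I = 1), measurements = c(metab__m = -1),
    transcript_stats = tx)
  expect_false(any(out$edges$target == "g"))
  # verify the forced state against the exhaustive oracle
  inst <- causal_instance(pkn, c(I = 1), c(metab__m = -1))
  bf <- brute_force_solve(inst)
  expect_true(all(vapply(bf$solutions,
                         function(s) s$node_state[["TF"]] == -1, TRUE)))
  # an already coherent PKN is a fixed point
  tx2 <- data.frame(feature_id = "g", statistic = -3, p_value = 0.01,
                    log_fc = -1.5)
  out2 <- ilp_prerun_correction(pkn, c(I = 1), c(metab__m = -1), tx2)
  expect_identical(out2$edges, pkn$edges)
  # infeasible pre-run leaves the PKN unchanged
  suppressWarnings(
    out3 <- ilp_prerun_correction(pkn, c(ZZ = 1), c(metab__m = -1), tx))
  expect_identical(out3$edges, pkn$edges)
})

test_that("pipeline stages only ever shrink the edge multiset", {
  for (seed in 1:10) {
    study <- generate_planted_study(seed = seed)
    e0 <- nrow(study$pkn$edges)
    p1 <- filter_expressed(study$pkn, study$counts)
    p2 <- reduce_to_reachable(p1, names(study$inputs), k = 8)
    acts <- structure(
      data.frame(node = names(study$inputs),
                 nes = 3 * unname(study$inputs)),
      class = c("activity_table", "data.frame"))
    p3 <- correct_transcriptional_edges(p2, acts,
                                        study$stat_tables$transcript)
    expect_true(e0 >= nrow(p1$edges))
    expect_true(nrow(p1$edges) >= nrow(p2$edges))
    expect_true(nrow(p2$edges) >= nrow(p3$edges))
    # correction removes transcriptional edges only
    removed <- setdiff(edge_keys_df(p2$edges), edge_keys_df(p3$edges))
    if (length(removed)) {
      prov <- p2$edges$provenance[edge_keys_df(p2$edges) %in% removed]
      expect_true(all(prov == "transcriptional"))
    }
  }
})
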