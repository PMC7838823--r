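test_that("degenerate and directional NES cases behave as expected", {
  # all statistics identical: every rank is the midpoint, NES must be 0
  stats_flat <- data.frame(feature_id = paste0("F", 1:50), statistic = 1,
                           p_value = 0.5)
  reg <- data.frame(regulator = "R1", target = paste0("F", 1:10),
                    mode = 1L, weight = 1)
  a <- estimate_activities(reg, stats_flat, min_targets = 5)
  expect_equal(a$nes, 0)
  # targets occupying the top ranks with +1 mode: NES strictly positive
  stats_top <- data.frame(feature_id = paste0("F", 1:50),
                          statistic = c(rep(5, 10), rnorm(40)),
                          p_value = 0.5)
  a2 <- estimate_activities(reg, stats_top, min_targets = 5)
  expect_gt(a2$nes, 0)
  expect_equal(a2$n_targets, 10L)
})

test_that("regulators below the target floor are omitted, empty warn", {
  stats <- data.frame(feature_id = paste0("F", 1:30),
                      statistic = rnorm(30), p_value = 0.5)
  reg <- rbind(
    data.frame(regulator = "big", target = paste0("F", 1:10), mode = 1L,
               weight = 1),
    data.frame(regulator = "small", target = paste0("F", 1:3), mode = 1L,
               weight = 1),
    data.frame(regulator = "ghost", target = paste0("X", 1:5), mode = 1L,
               weight = 1))
  expect_warning(a <- estimate_activities(reg, stats, min_targets = 5),
                 "ghost")
  expect_identical(a$node, "big")
})

test_that("analytic NES matches the permutation-null z-score", {
  set.seed(10)
  stats <- data.frame(feature_id = sprintf("F%03d", 1:200),
                      statistic = rnorm(200), p_value = 0.5)
  for (seed in 1:5) {
    set.seed(seed + 100)
    targets <- sample(stats$feature_id, 10)
    modes <- sample(c(-1L, 1L), 10, replace = TRUE)
    w <- runif(10, 0.5, 1)
    reg <- data.frame(regulator = "R", target = targets, mode = modes,
                      weight = w)
    nes <- estimate_activities(reg, stats, min_targets = 5)$nes
    z_emp <- perm_null_z(targets, modes, w, stats, n_perm = 2e4,
                         seed = seed)
    expect_lt(abs(nes - z_emp), 0.15)
  }
})

test_that("NES is sign-equivariant and monotone in target rank", {
  set.seed(3)
  stats <- data.frame(feature_id = paste0("F", 1:100),
                      statistic = rnorm(100), p_value = 0.5)
  reg <- data.frame(regulator = "R", target = paste0("F", 1:8),
                    mode = sample(c(-1L, 1L), 8, replace = TRUE), weight = 1)
  a <- estimate_activities(reg, stats, min_targets = 5)$nes
  neg <- stats
  neg$statistic <- -neg$statistic
  expect_equal(estimate_activities(reg, neg, min_targets = 5)$nes, -a)
  # raising a +1-mode target's statistic never lowers the NES
  reg1 <- data.frame(regulator = "R", target = paste0("F", 1:8),
                     mode = 1L, weight = 1)
  base <- estimate_activities(reg1, stats, min_targets = 5)$nes
  for (bump in c(0.5, 2, 10)) {
    up <- stats
    up$statistic[1] <- up$statistic[1] + bump
    expect_gte(estimate_activities(reg1, up, min_targets = 5)$nes,
               base - 1e-12)
  }
})

test_that("null NES distribution is standard-normal calibrated", {
  set.seed(42)
  stats <- data.frame(feature_id = sprintf("F%03d", 1:300),
                      statistic = rnorm(300), p_value = 0.5)
  nes <- vapply(1:300, function(i) {
    targets <- sample(stats$feature_id, 10)
    reg <- data.frame(regulator = "R", target = targets,
                      mode = sample(c(-1L, 1L), 10, TRUE), weight = 1)
    estimate_activities(reg, stats, min_targets = 5)$nes
  }, 0)
  expect_lt(abs(mean(nes)), 0.1)
  expect_lt(abs(sd(nes) - 1), 0.1)
})

test_that("per-sample activities scale rows and recover planted shifts", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 4))
  # row (1,2,3) scales to (-1, 0, 1); constant rows are dropped
  sc <- t(scale(t(m[c("a", "c"), ])))
  expect_equal(unname(sc["a", ]), c(-1, 0, 1))
  expect_error(per_sample_activities(m[, 1:2, drop = FALSE],
                                     data.frame(regulator = "R",
                                                target = "a", mode = 1L,
                                                weight = 1)),
               "3 samples")
  # planted +2 sigma shift on regulator R01's targets in sample 3
  set.seed(7)
  n_reg <- 20; k <- 10; n_feat <- 400; n_smp <- 6
  feats <- sprintf("F%03d", 1:n_feat)
  regs <- do.call(rbind, lapply(1:n_reg, function(i) {
    data.frame(regulator = sprintf("R%02d", i),
               target = feats[((i - 1) * k + 1):(i * k)], mode = 1L,
               weight = 1)
  }))
  dat <- matrix(rnorm(n_feat * n_smp), n_feat, n_smp,
                dimnames = list(feats, paste0("S", 1:n_smp)))
  dat[regs$target[regs$regulator == "R01"], 3] <-
    dat[regs$target[regs$regulator == "R01"], 3] + 2
  act <- per_sample_activities(dat, regs, min_targets = 5)
  expect_equal(rownames(act)[which.max(act[, 3])], "R01")
})

test_that("input selection applies strict cutoffs", {
  acts <- structure(data.frame(node = c("A", "B", "C"),
                               nes = c(2.0, 1.5, -1.8)),
                    class = c("activity_table", "data.frame"))
  met <- data.frame(feature_id = c("m1", "m2", "m3"),
                    statistic = c(3, -2, 1), p_value = c(0.01, 0.05, 0.2))
  sel <- select_inputs(acts, met, nes_cut = 1.7, p_cut = 0.05)
  expect_setequal(sel$signaling$node, c("A", "C"))
  expect_equal(sel$signaling$value[sel$signaling$node == "C"], -1.8)
  # p = 0.05 exactly is excluded (strict inequality)
  expect_identical(sel$metabolites$node, "m1")
  expect_equal(sel$metabolites$value, 1)
  expect_warning(select_inputs(acts, met, nes_cut = 10, p_cut = 1e-6),
                 "no deregulated")
})

test_that("GMT gene sets load as unsigned regulons", {
  d <- withr::local_tempdir()
  writeLines(c("SET1\tdesc\tG1\tG2\tG3", "SET2\tdesc\tG2\tG4"),
             file.path(d, "sets.gmt"))
  sets <- read_gmt(file.path(d, "sets.gmt"))
  expect_equal(sets$SET1, c("G1", "G2", "G3"))
  reg <- gmt_to_regulons(sets)
  expect_true(all(reg$mode == 1L) && all(reg$weight == 1))
  expect_equal(nrow(reg), 5L)
})
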