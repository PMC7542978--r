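test_that("run correlations have the expected structure and signs", {
  t <- (0:799) / 50
  a <- harmonic_pulse(t, 1)
  X <- cbind(a, a, -a + 0.001 * sin(t), smooth_series(800))
  run <- run_from_signal(X)
  C <- run_correlation(run)
  expect_equal(diag(C), rep(0, 4), ignore_attr = TRUE)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)       # identical channels
  expect_lt(C[1, 3], -0.99)                         # anti-phase pair
  Xz <- X
  Xz[, 4] <- 0
  expect_error(run_correlation(run_from_signal(Xz)),
               colnames(run$data)[4])
})

test_that("mean network averages and cancels", {
  p <- planted_network()
  M <- p$net$weights
  expect_equal(mean_network(list(M))$weights, M)
  expect_equal(max(abs(mean_network(list(M, -M))$weights)), 0)
  expect_equal(sum(upper.tri(M)), 66)  # 12 nodes, 66 edges
})

test_that("thresholding keeps the requested edges and never helps efficiency", {
  p <- planted_network(win = 0.8, bet = -0.4)
  pos <- threshold_network(p$net, 0.35, "positive")
  expect_true(all(pos$weights[pos$weights != 0] >= 0.35))
  # within-module edges survive, between-module do not
  same <- outer(p$groups, p$groups, `==`)
  diag(same) <- NA
  expect_true(all(pos$weights[same & !is.na(same)] == 0.8))
  expect_true(all(pos$weights[!same & !is.na(same)] == 0))
  neg <- threshold_network(p$net, 0.35, "negative")
  expect_true(all(neg$weights[neg$weights != 0] <= -0.35))
  empty <- threshold_network(p$net, 0.85, "positive")
  expect_equal(sum(empty$weights != 0), 0)
  # monotonicity of global efficiency under thresholding
  for (tau in seq(0, 0.8, by = 0.05))
    expect_lte(global_efficiency(threshold_network(p$net, tau, "positive")),
               global_efficiency(p$net) + 1e-12)
})

test_that("global efficiency matches hand-enumerated values", {
  Wc <- 1 - diag(5)
  expect_equal(global_efficiency(joint_network(Wc)), 1.0)
  expect_equal(global_efficiency(joint_network(matrix(0, 2, 2))), 0)
  # 4-node path graph: pairs at distance 1,1,1,2,2,3
  Wp <- matrix(0, 4, 4)
  Wp[cbind(1:3, 2:4)] <- 1
  Wp <- Wp + t(Wp)
  expect_equal(global_efficiency(joint_network(Wp)),
               (3 * 1 + 2 * (1 / 2) + 1 * (1 / 3)) / 6)
})

test_that("null ensemble preserves the weight multiset and is seeded", {
  p <- planted_network(0.7, -0.3)
  ens <- null_ensemble(p$net, n_graphs = 20, iterations = 200, seed = 4)
  w0 <- sort(p$net$weights[upper.tri(p$net$weights)])
  for (g in ens$graphs)
    expect_equal(sort(g$weights[upper.tri(g$weights)]), w0)
  ens2 <- null_ensemble(p$net, n_graphs = 20, iterations = 200, seed = 4)
  expect_identical(lapply(ens$graphs, `[[`, "weights"),
                   lapply(ens2$graphs, `[[`, "weights"))
})

test_that("a weight-shuffled graph is indistinguishable from its ensemble", {
  set.seed(31)
  W <- matrix(0, 12, 12)
  W[upper.tri(W)] <- runif(66, -1, 1)
  net <- joint_network(W + t(W))
  shuffled <- null_ensemble(net, n_graphs = 1, iterations = 500, seed = 9)$graphs[[1]]
  ens <- null_ensemble(shuffled, n_graphs = 100, iterations = 500, seed = 10)
  cmp <- null_compare(shuffled, ens)
  expect_gt(cmp$p, 0.05)
})

test_that("small-world metrics behave on reference constructions", {
  set.seed(33)
  # ring lattice with shortcuts: sigma > 1
  n <- 12
  W <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  W[1, 7] <- W[7, 1] <- 1
  W[3, 9] <- W[9, 3] <- 1
  latt <- joint_network(W)
  ens <- null_ensemble(latt, n_graphs = 50, iterations = 500, seed = 5)
  sw <- small_world(latt, ens)
  expect_gt(sw$swi, 1)
  expect_gte(sw$swp, 0)
  expect_lte(sw$swp, 1)
  # dense random weighted graph vs its own null: sigma ~ 1
  Wr <- matrix(0, n, n)
  Wr[upper.tri(Wr)] <- runif(66, 0.2, 1)
  rnd <- joint_network(Wr + t(Wr))
  ensr <- null_ensemble(rnd, n_graphs = 50, iterations = 500, seed = 6)
  swr <- small_world(rnd, ensr)
  expect_equal(swr$swi, 1, tolerance = 0.15)
  expect_error(small_world(joint_network(matrix(0, 3, 3)), ens), "disconnected")
})

test_that("Louvain recovers planted communities", {
  # two disconnected positive cliques
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 0.9
  W[5:8, 5:8] <- 0.9
  diag(W) <- 0
  lv <- louvain_modules(joint_network(W), seed = 3)
  expect_equal(length(unique(lv$modules)), 2)
  expect_equal(adjusted_rand_index(lv$modules, rep(1:2, each = 4)), 1)
  # planted 3-group signed network
  p <- planted_network(0.8, -0.4)
  lv3 <- louvain_modules(p$net, seed = 4)
  expect_equal(adjusted_rand_index(lv3$modules, p$groups), 1)
  # all-zero network: every node its own module
  z <- louvain_modules(joint_network(matrix(0, 5, 5)), seed = 1)
  expect_equal(length(unique(z$modules)), 5)
})

test_that("Louvain partitions are invariant under node relabeling", {
  p <- planted_network(0.8, -0.4)
  perm <- c(4, 1, 9, 12, 2, 7, 5, 11, 3, 8, 10, 6)
  Wp <- p$net$weights[perm, perm]
  lv1 <- louvain_modules(p$net, seed = 8)
  lv2 <- louvain_modules(joint_network(Wp), seed = 8)
  expect_equal(adjusted_rand_index(lv1$modules[perm], lv2$modules), 1)
})

test_that("generator cohorts with disjoint loading groups give 3 exact modules", {
  spec <- synthetic_spec(loadings = module_loadings(), n_subjects = 2,
                         n_runs = 3, seed = 44)
  sim <- simulate_runs(spec)
  g12 <- default_layout()$graph12
  mats <- lapply(sim$runs, function(r)
    run_correlation(select_channels(r, g12)))
  net <- mean_network(mats)
  truth <- apply(abs(spec$loadings[, g12]), 2, which.max)
  # sign pattern of the mean matrix matches the planted block pattern
  same <- outer(truth, truth, `==`)
  diag(same) <- NA
  expect_gt(mean(sign(net$weights[same & !is.na(same)]) == 1, na.rm = TRUE), 0.95)
  lv <- louvain_modules(net, seed = 21)
  expect_equal(adjusted_rand_index(lv$modules, truth), 1)
})
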