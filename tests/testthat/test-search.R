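# helpers to run the local-graph -> instance -> solve chain on small fixtures
whole_graph_instance <- function(mx, walk, lfdr, seed, B) {
  K <- mx$n_genes * mx$n_layers
  lg <- suppressWarnings(extract_local_graph(walk, mx, seed, K = max(K, mx$n_layers)))
  build_instance(lg, mx, walk, lfdr, B)
}

test_that("instance coefficients reproduce conductance exactly (toy and random)", {
  # toy: 2 layers over {A, B}, one edge in layer 1, interlayer weight 1
  l1 <- layer_network(rbind(c("A", "B")), name = "L1")
  l2 <- layer_network(matrix(character(), ncol = 2), name = "L2", genes = c("A", "B"))
  mx <- build_multiplex(list(l1, l2))
  walk <- walk_model(mx)
  inst <- whole_graph_instance(mx, walk, c(A = 0.01, B = 0.5), "A", 0.1)
  expect_equal(inst$pair_c, 1)
  expect_equal(inst$b, c(0, 0))
  expect_equal(inst$d, c(3, 3))
  cv <- mplexfdr:::instance_cut_volume(inst, match("A", inst$genes))
  expect_equal(unname(cv["cut"] / cv["volume"]), 1/3)
  expect_equal(unname(cv["cut"] / cv["volume"]),
               conductance(walk, cover_states(mx, "A")))
  # all genes, no outside edges: zero cut
  cv_all <- mplexfdr:::instance_cut_volume(inst, 1:2)
  expect_equal(unname(cv_all["cut"]), 0)

  # random instances: N/D == conductance of the covered state set
  set.seed(41)
  for (rep in 1:6) {
    mxr <- random_multiplex(sample(6:10, 1), sample(1:3, 1), p_edge = 0.4,
                            weights = stats::runif(3, 0.5, 2)[seq_len(3)])
    wr <- suppressWarnings(walk_model(mxr))
    lf <- stats::setNames(stats::runif(mxr$n_genes), mxr$genes)
    inst <- whole_graph_instance(mxr, wr, lf, mxr$genes[1], 0.9)
    for (k in 1:5) {
      sel <- sort(sample(seq_along(inst$genes), sample(mxr$n_genes - 1, 1)))
      cv <- mplexfdr:::instance_cut_volume(inst, sel)
      expect_equal(unname(cv["cut"] / cv["volume"]),
                   conductance(wr, cover_states(mxr, inst$genes[sel])),
                   tolerance = 1e-12)
    }
  }
})

test_that("boundary coefficients pick up weighted edges leaving the local graph", {
  edges1 <- rbind(c("A", "B"), c("B", "C"), c("A", "C"), c("C", "X"))
  edges2 <- rbind(c("A", "B"), c("B", "X"))
  mx <- build_multiplex(list(layer_network(edges1, name = "L1"),
                             layer_network(edges2, name = "L2", weight = 2,
                                           genes = c("A", "B", "C", "X"))))
  walk <- walk_model(mx)
  lg <- structure(list(seed = "A", genes = c("A", "B", "C"),
                       state_nodes = cover_states(mx, c("A", "B", "C")),
                       K = 6, scores = NULL,
                       boundary = c(A = 0, B = 2, C = 1), truncated = TRUE),
                  class = "local_graph")
  inst <- build_instance(lg, mx, walk, c(A = 0.1, B = 0.1, C = 0.1, X = 0.9), 0.2)
  expect_equal(inst$b[match("B", inst$genes)], 2)   # layer-2 edge B-X, weight 2
  expect_equal(inst$b[match("C", inst$genes)], 1)   # layer-1 edge C-X
})

test_that("planted clique is recovered exactly and matches exhaustive search", {
  clique <- sprintf("c%d", 1:6)
  path <- sprintf("p%d", 1:6)
  edges <- rbind(t(utils::combn(clique, 2)),
                 cbind(path[-6], path[-1]),
                 c(clique[1], path[1]))
  mx <- build_multiplex(list(layer_network(edges, name = "L1"),
                             layer_network(edges, name = "L2")))
  walk <- walk_model(mx)
  lfdr <- stats::setNames(c(rep(0.01, 6), rep(0.9, 6)), c(clique, path))
  inst <- whole_graph_instance(mx, walk, lfdr, "c3", 0.1)
  sn <- solve_subnetwork(inst)
  expect_setequal(sn$genes, clique)
  expect_equal(sn$status, "optimal")
  expect_lte(sn$est_fdr, 0.1 + 1e-12)
  oracle <- oracle_best_subnetwork(mx, walk, c(clique, path), "c3", lfdr, 0.1)
  expect_equal(sn$conductance, oracle$phi, tolerance = 1e-9)
  expect_setequal(sn$genes, oracle$genes)
  # Dinkelbach certificate and monotone lambdas
  expect_gte(sn$certificate, -1e-7)
  expect_true(all(diff(sn$lambdas) <= 1e-12))
  expect_lte(sn$iterations, 50L)
})

test_that("a seed surrounded by surely-null genes stays a singleton", {
  edges <- rbind(c("s", "n1"), c("s", "n2"), c("n1", "n2"))
  mx <- build_multiplex(list(layer_network(edges, name = "L1")))
  walk <- walk_model(mx)
  lfdr <- c(s = 0.05, n1 = 1, n2 = 1)
  inst <- whole_graph_instance(mx, walk, lfdr, "s", 0.1)
  sn <- solve_subnetwork(inst)
  expect_equal(sn$genes, "s")
  # and a seed with lfdr above the bound is reported infeasible
  inst2 <- whole_graph_instance(mx, walk, c(s = 0.5, n1 = 1, n2 = 1), "s", 0.1)
  expect_warning(sn2 <- solve_subnetwork(inst2), "infeasible")
  expect_equal(sn2$status, "infeasible")
  expect_equal(length(sn2$genes), 0L)
})

test_that("MILP solution equals brute-force enumeration on random small instances", {
  set.seed(52)
  n_checked <- 0
  while (n_checked < 12) {
    n <- sample(8:12, 1)
    L <- sample(1:2, 1)
    mx <- random_multiplex(n, L, p_edge = stats::runif(1, 0.25, 0.5))
    walk <- suppressWarnings(walk_model(mx))
    lfdr <- stats::setNames(
      ifelse(stats::runif(n) < 0.4, stats::runif(n, 0, 0.1), stats::runif(n, 0.2, 1)),
      mx$genes)
    B <- sample(c(0.1, 0.15, 0.25), 1)
    unwalk <- unique(mx$genes[mplexfdr:::state_gene(mx, which(walk$unwalkable))])
    cand <- setdiff(names(lfdr)[lfdr < B], unwalk)
    if (length(cand) == 0) next
    seed <- sample(cand, 1)
    inst <- whole_graph_instance(mx, walk, lfdr, seed, B)
    sn <- solve_subnetwork(inst)
    oracle <- oracle_best_subnetwork(mx, walk, inst$genes, seed, lfdr, B)
    expect_equal(sn$conductance, oracle$phi, tolerance = 1e-9,
                 label = sprintf("instance %d conductance", n_checked))
    # feasibility and fidelity of every returned subnetwork
    expect_lte(sn$est_fdr, B + 1e-12)
    expect_true(seed %in% sn$genes)
    expect_equal(sn$conductance,
                 conductance(walk, cover_states(mx, sn$genes)),
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("detection loop skips seeds already absorbed in earlier subnetworks", {
  clique <- sprintf("c%d", 1:5)
  edges <- rbind(t(utils::combn(clique, 2)), c("c1", "far"), c("far", "far2"))
  mx <- build_multiplex(list(layer_network(edges, name = "L1")))
  walk <- walk_model(mx)
  lfdr <- stats::setNames(c(rep(0.01, 5), 0.9, 0.9), c(clique, "far", "far2"))
  seeds <- select_seeds(lfdr, 0.1, mx, walk)
  expect_setequal(seeds$seed, clique)
  res <- detect_all(mx, walk, lfdr, seeds, B = 0.1, K = 14)
  expect_equal(length(res), 1L)
  expect_setequal(res[[1]]$genes, clique)
  log <- attr(res, "log")
  expect_equal(sum(log$action == "skipped"), 4L)
  # disjoint solutions produce separate subnetworks
  e2 <- rbind(t(utils::combn(c("a1", "a2", "a3"), 2)),
              t(utils::combn(c("b1", "b2", "b3"), 2)))
  mx2 <- build_multiplex(list(layer_network(e2, name = "L1")))
  w2 <- walk_model(mx2)
  lf2 <- stats::setNames(rep(0.01, 6), c("a1", "a2", "a3", "b1", "b2", "b3"))
  res2 <- detect_all(mx2, w2, lf2, select_seeds(lf2, 0.1, mx2, w2), B = 0.1, K = 6)
  expect_equal(length(res2), 2L)
  # empty seed list
  expect_equal(length(detect_all(mx2, w2, lf2, character(0), B = 0.1, K = 6)), 0L)
})
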