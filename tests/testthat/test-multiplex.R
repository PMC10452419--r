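test_that("multiplex construction: union of genes, state space, edge dedup", {
  l1 <- layer_network(rbind(c("A", "B")), name = "L1")
  l2 <- layer_network(rbind(c("B", "C")), name = "L2")
  mx <- build_multiplex(list(l1, l2))
  expect_equal(mx$genes, c("A", "B", "C"))
  expect_equal(mx$n_genes * mx$n_layers, 6L)
  expect_equal(nrow(mx$layers$L1$edges), 1L)
  expect_equal(nrow(mx$layers$L2$edges), 1L)

  # single layer: no interlayer structure
  mx1 <- build_multiplex(list(l1))
  expect_equal(mx1$n_genes * mx1$n_layers, 2L)
  w1 <- walk_model(mx1)
  expect_equal(Matrix::nnzero(w1$adjacency), 2L)  # one undirected edge

  # undirected dedup regardless of orientation
  ld <- layer_network(rbind(c("A", "B"), c("B", "A")), name = "d")
  expect_equal(nrow(ld$edges), 1L)

  expect_error(build_multiplex(list()), "nonempty")
  expect_error(build_multiplex(list(l1, layer_network(rbind(c("X", "Y")), name = "L1"))),
               "duplicate layer names")
  expect_error(layer_network(rbind(c("A", "B")), weight = -1), "positive")
})

test_that("self-loops are dropped at layer construction", {
  l <- layer_network(rbind(c("A", "A"), c("A", "B")), name = "s")
  expect_equal(nrow(l$edges), 1L)
  expect_equal(l$n_self_loops_dropped, 1L)
})

test_that("classic walk on the two-layer toy matches hand/power-iteration values", {
  l1 <- layer_network(rbind(c("A", "B")), name = "L1")
  l2 <- layer_network(matrix(character(), ncol = 2), name = "L2",
                      genes = c("A", "B"))
  mx <- build_multiplex(list(l1, l2), interlayer_weight = 1)
  walk <- walk_model(mx)
  # states ordered A1 B1 A2 B2; deg = 2 2 1 1
  expect_equal(walk$deg, c(2, 2, 1, 1))
  expect_equal(walk$stationary, c(1/3, 1/3, 1/6, 1/6))
  T <- as.matrix(transition_matrix(walk))
  expect_equal(unname(T[1, ]), c(0, 1/2, 1/2, 0))
  expect_equal(unname(Matrix::rowSums(transition_matrix(walk))), rep(1, 4))
  # oracle: lazy power iteration
  expect_lt(max(abs(oracle_stationary(walk) - walk$stationary)), 1e-10)

  # cover-respecting S = {A1, A2}: one cut edge of weight 1, volume 3
  S <- cover_states(mx, "A")
  expect_equal(conductance(walk, S), 1/3)
  expect_equal(oracle_conductance(walk, S), 1/3, tolerance = 1e-12)
})

test_that("stationarity, row-stochasticity and conductance identities on random multiplexes", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    L <- sample(1:3, 1)
    w <- stats::runif(L, 0.5, 3)
    mx <- random_multiplex(n, L, p_edge = 0.4, weights = w,
                           interlayer_weight = stats::runif(1, 0.5, 2))
    walk <- suppressWarnings(walk_model(mx))
    stopifnot(n * L <= 200)
    T <- transition_matrix(walk)
    ok <- !walk$unwalkable
    expect_true(all(abs(Matrix::rowSums(T)[ok] - 1) <= 1e-12))
    # p invariant under T and matched by power iteration
    p <- walk$stationary
    expect_lt(max(abs(as.vector(Matrix::t(T) %*% p) - p)), 1e-10)
    expect_lt(max(abs(oracle_stationary(walk) - p)), 1e-10)
    expect_equal(sum(p), 1)
    # random cover-respecting subsets: Eq-style evaluation == cut/volume
    for (k in 1:5) {
      sel <- sample(mx$genes, sample(seq_len(n - 1), 1))
      S <- cover_states(mx, sel)
      if (all(walk$deg[S] == 0)) next
      phi <- conductance(walk, S)
      expect_gte(phi, 0); expect_lte(phi, 1)
      expect_equal(phi, oracle_conductance(walk, S), tolerance = 1e-12)
      # cut symmetry: phi(S) vol(S) == phi(~S) vol(~S)
      Sc <- setdiff(seq_along(p), S)
      expect_equal(phi * sum(walk$deg[S]),
                   conductance(walk, Sc) * sum(walk$deg[Sc]),
                   tolerance = 1e-9)
    }
  }
})

test_that("single-layer multiplex reduces to standard graph conductance", {
  set.seed(5)
  mx <- random_multiplex(10, 1, p_edge = 0.35)
  walk <- suppressWarnings(walk_model(mx))
  e <- mx$layers[[1]]$edges
  sel <- sample(mx$genes, 4)
  S <- cover_states(mx, sel)
  inside <- function(g) g %in% sel
  cut <- sum(xor(inside(e[, 1]), inside(e[, 2])))
  degs <- table(factor(c(e[, 1], e[, 2]), levels = mx$genes))
  vol <- sum(degs[sel])
  if (vol > 0) expect_equal(conductance(walk, S), cut / vol)
})

test_that("layer weights scale adjacency but leave proportional conductances intact", {
  set.seed(7)
  l1e <- rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D"))
  mk <- function(w1) build_multiplex(list(
    layer_network(l1e, name = "L1", weight = w1),
    layer_network(l1e, name = "L2", weight = 1)))
  # identical topology in both layers: scaling layer 1 scales cut and volume
  # of any cover-respecting S within that layer proportionally
  for (sel in list("A", c("A", "B"), c("A", "B", "C"))) {
    phis <- vapply(c(1, 5), function(w1) {
      mxw <- mk(w1)
      ww <- walk_model(mxw)
      conductance(ww, cover_states(mxw, sel))
    }, numeric(1))
    w <- walk_model(mk(5))
    expect_equal(phis[2], oracle_conductance(w, cover_states(mk(5), sel)),
                 tolerance = 1e-12)
  }
})

test_that("a gene with no intralayer edges has zero conductance alone (interlayer edges internal)", {
  l1 <- layer_network(rbind(c("A", "B")), name = "L1", genes = c("A", "B", "Z"))
  l2 <- layer_network(rbind(c("A", "B")), name = "L2", genes = c("A", "B", "Z"))
  mx <- build_multiplex(list(l1, l2))
  walk <- walk_model(mx)
  expect_equal(conductance(walk, cover_states(mx, "Z")), 0)
})

test_that("aggregate network is the unweighted union of layer edge sets", {
  l1 <- layer_network(rbind(c("A", "B")), name = "L1", weight = 3)
  l2 <- layer_network(rbind(c("B", "C")), name = "L2")
  agg <- aggregate_network(build_multiplex(list(l1, l2)))
  expect_equal(agg$edges, rbind(c("A", "B"), c("B", "C")),
               ignore_attr = TRUE)
  expect_equal(agg$weight, 1)
  # idempotence / dedup across layers with different weights
  agg2 <- aggregate_network(build_multiplex(list(
    layer_network(rbind(c("A", "B")), name = "x", weight = 2),
    layer_network(rbind(c("A", "B")), name = "y", weight = 7))))
  expect_equal(nrow(agg2$edges), 1L)
})
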