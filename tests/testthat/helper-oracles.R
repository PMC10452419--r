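# Independent oracles: everything here recomputes quantities by a different
# route than the implementation (dense algebra, enumeration, iteration).

# stationary distribution by power iteration on the lazy walk (I + T) / 2,
# which shares the stationary distribution of T and converges even on
# bipartite graphs
oracle_stationary <- function(walk, n_steps = 10000) {
  T <- as.matrix(transition_matrix(walk))
  ok <- !walk$unwalkable
  T <- T[ok, ok, drop = FALSE]
  Tl <- (T + diag(nrow(T))) / 2
  p <- rep(1 / nrow(Tl), nrow(Tl))
  for (i in seq_len(n_steps)) p <- drop(p %*% Tl)
  out <- numeric(length(walk$deg))
  out[ok] <- p
  out
}

# Eq-style conductance: outflow of stationary walkers over inside mass,
# evaluated term by term from T and p
oracle_conductance <- function(walk, S) {
  T <- as.matrix(transition_matrix(walk))
  p <- walk$stationary
  outside <- setdiff(seq_along(p), S)
  sum(T[S, outside, drop = FALSE] * p[S]) / sum(p[S])
}

# dense PPR: solve (I - c * t(T)) p = (1 - c) r0
oracle_ppr <- function(walk, r0, c) {
  T <- as.matrix(transition_matrix(walk))
  drop(solve(diag(length(r0)) - c * t(T), (1 - c) * r0))
}

ppr_state_as_vector <- function(state, n_states, field = "scores") {
  v <- numeric(n_states)
  x <- state[[field]]
  v[as.integer(names(x))] <- x
  v
}

# exhaustive minimum-conductance search: all seed-containing, connected,
# FDR-feasible gene subsets, conductance via the walk adjacency directly
oracle_best_subnetwork <- function(mx, walk, genes, seed, lfdr, B) {
  stopifnot(length(genes) <= 16)
  agg <- aggregate_network(mx)
  e <- agg$edges
  keep <- e[, 1] %in% genes & e[, 2] %in% genes
  adj <- lapply(genes, function(g)
    unique(c(e[keep & e[, 1] == g, 2], e[keep & e[, 2] == g, 1])))
  names(adj) <- genes
  is_connected <- function(set) {
    if (length(set) == 1) return(TRUE)
    seen <- set[1]; frontier <- set[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(intersect(unlist(adj[frontier]), set), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(set)
  }
  others <- setdiff(genes, seed)
  best_phi <- Inf; best_set <- NULL
  for (mask in 0:(2^length(others) - 1)) {
    set <- c(seed, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    if (mean(lfdr[set]) > B + 1e-12) next
    if (!is_connected(set)) next
    S <- cover_states(mx, set)
    phi <- if (length(S) == length(walk$deg)) next else conductance(walk, S)
    if (phi < best_phi - 1e-15) { best_phi <- phi; best_set <- sort(set) }
  }
  list(phi = best_phi, genes = best_set)
}

# small random multiplex for property tests
random_multiplex <- function(n_genes = 8, n_layers = 2, p_edge = 0.35,
                             weights = NULL, interlayer_weight = 1) {
  genes <- sprintf("t%02d", seq_len(n_genes))
  layers <- lapply(seq_len(n_layers), function(a) {
    cmb <- t(utils::combn(genes, 2))
    keep <- stats::runif(nrow(cmb)) < p_edge
    if (!any(keep)) keep[sample.int(nrow(cmb), 2)] <- TRUE
    layer_network(cmb[keep, , drop = FALSE], name = sprintf("L%d", a),
                  weight = if (is.null(weights)) 1 else weights[a],
                  genes = genes)
  })
  build_multiplex(layers, interlayer_weight = interlayer_weight)
}
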