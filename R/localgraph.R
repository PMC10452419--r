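#' Approximate personalized PageRank on the multiplex walk
#'
#' Runs the push algorithm for the PPR problem
#' `p = (1 - c) r0 + c T' p` with continuation (teleportation) parameter
#' `c`, starting from residual mass `1/|L|` on each of the seed gene's state
#' nodes. Pushing stops when every residual satisfies
#' `r(u) <= epsilon * deg(u)`, which bounds the per-state-node score error by
#' `epsilon * deg(u)`. The computation is resumable: passing a previous
#' `ppr_state` continues the same push at a smaller `epsilon` without
#' restarting.
#'
#' Scores and residuals are kept sparse throughout; only the neighbourhood
#' actually reached by the push is ever touched.
#'
#' @param walk a [walk_model()].
#' @param seed seed gene identifier (must be walkable).
#' @param teleport continuation probability `c` in (0, 1); default 0.998
#'   (restart probability 0.002).
#' @param epsilon push threshold (> 0).
#' @param state optional `ppr_state` from a previous call to resume from.
#' @return An object of class `ppr_state`: sparse `scores` and `residual`
#'   (named numeric, names are state indices), `epsilon`, `teleport`,
#'   cumulative push count `n_push`.
#' @export
approximate_ppr <- function(walk, seed, teleport = 0.998, epsilon, state = NULL) {
  stopifnot(inherits(walk, "walk_model"))
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (teleport <= 0 || teleport >= 1) stop("teleport must be in (0, 1)", call. = FALSE)
  gi <- match(seed, walk$genes)
  if (is.na(gi)) stop("seed gene not in network: ", seed, call. = FALSE)
  L <- walk$n_layers
  if (is.null(state)) {
    sstates <- (seq_len(L) - 1L) * walk$n_genes + gi
    if (any(walk$unwalkable[sstates]))
      stop("seed gene is unwalkable (isolated in a single-layer multiplex): ",
           seed, call. = FALSE)
    s_idx <- integer(0); s_val <- numeric(0)
    r_idx <- sstates; r_val <- rep(1 / L, L)
    n_push0 <- 0
  } else {
    stopifnot(inherits(state, "ppr_state"))
    s_idx <- as.integer(names(state$scores)); s_val <- unname(state$scores)
    r_idx <- as.integer(names(state$residual)); r_val <- unname(state$residual)
    n_push0 <- state$n_push
  }
  A <- walk$adjacency
  res <- ppr_push_cpp(A@p, A@i, A@x, walk$deg,
                      s_idx - 1L, s_val, r_idx - 1L, r_val,
                      epsilon, teleport)
  sc <- stats::setNames(res$score_val, res$score_idx + 1L)
  rs <- stats::setNames(res$resid_val, res$resid_idx + 1L)
  sc <- sc[order(as.integer(names(sc)))]
  rs <- rs[order(as.integer(names(rs)))]
  structure(
    list(scores = sc, residual = rs, epsilon = epsilon, teleport = teleport,
         seed = seed, n_push = n_push0 + res$n_push),
    class = "ppr_state")
}

#' @export
print.ppr_state <- function(x, ...) {
  cat(sprintf("<ppr_state seed '%s'>  %d scored state nodes, residual mass %.3g, eps %.3g\n",
              x$seed, length(x$scores), sum(x$residual), x$epsilon))
  invisible(x)
}

#' Extract a layer-complete local graph around a seed
#'
#' Repeatedly runs [approximate_ppr()] on a geometric epsilon schedule
#' (start `1 / (50 K)`, divide by 10, floor `eps_floor`) until the PPR score
#' vector has at least `K` nonzero entries or the floor is reached (the
#' seed's reachable component may simply be smaller than `K`, in which case
#' the whole component is returned with a warning). The `K` state nodes with
#' the largest scores are retained (ties by gene identifier, then layer
#' index) and the selection is augmented to layer-completeness: whenever any
#' state node of a gene is kept, all its state nodes are. Per-gene boundary
#' weights (total intralayer edge weight leaving the local graph) are
#' recorded for the conductance bookkeeping of the search step.
#'
#' @param walk a [walk_model()].
#' @param mx the parent `multiplex`.
#' @param seed seed gene identifier.
#' @param K exploration size in state nodes (default 400, must be >= number
#'   of layers).
#' @param teleport continuation parameter, default 0.998.
#' @param eps_floor smallest epsilon tried, default 1e-10.
#' @param rank_by `"score"` (default, raw PPR scores) or `"score_over_degree"`
#'   (degree-normalized ranking).
#' @return An object of class `local_graph`: `seed`, `genes` (P_L),
#'   `state_nodes`, `K`, `scores` (final `ppr_state`), `boundary`
#'   (named per-gene outward intralayer weight), `truncated` (logical: FALSE
#'   when the whole reachable component was smaller than `K`).
#' @export
extract_local_graph <- function(walk, mx, seed, K = 400, teleport = 0.998,
                                eps_floor = 1e-10,
                                rank_by = c("score", "score_over_degree")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(mx, "multiplex"))
  L <- mx$n_layers
  if (K < L) stop("K must be at least the number of layers", call. = FALSE)
  eps <- 1 / (50 * K)
  state <- approximate_ppr(walk, seed, teleport, eps)
  while (length(state$scores) < K && eps > eps_floor) {
    eps <- eps / 10
    state <- approximate_ppr(walk, seed, teleport, max(eps, eps_floor), state)
  }
  truncated <- length(state$scores) >= K
  if (!truncated)
    warning(sprintf("reachable component around seed '%s' has only %d state nodes (< K = %d)",
                    seed, length(state$scores), K), call. = FALSE)

  idx <- as.integer(names(state$scores))
  val <- if (rank_by == "score") unname(state$scores)
         else unname(state$scores) / walk$deg[idx]
  g <- state_gene(mx, idx)
  l <- state_layer(mx, idx)
  ord <- order(-val, mx$genes[g], l)
  keep <- idx[ord][seq_len(min(K, length(idx)))]
  genes <- sort(unique(mx$genes[state_gene(mx, keep)]))
  genes <- union(genes, seed)
  genes <- sort(genes)
  states <- cover_states(mx, genes)

  # per-gene total intralayer weight to genes outside the local graph
  boundary <- stats::setNames(numeric(length(genes)), genes)
  for (lay in mx$layers) {
    e <- lay$edges
    if (nrow(e) == 0L) next
    in1 <- e[, 1L] %in% genes
    in2 <- e[, 2L] %in% genes
    out1 <- e[in1 & !in2, 1L]
    out2 <- e[!in1 & in2, 2L]
    if (length(out1)) {
      t1 <- table(out1); boundary[names(t1)] <- boundary[names(t1)] + lay$weight * as.integer(t1)
    }
    if (length(out2)) {
      t2 <- table(out2); boundary[names(t2)] <- boundary[names(t2)] + lay$weight * as.integer(t2)
    }
  }
  structure(
    list(seed = seed, genes = genes, state_nodes = states, K = K,
         scores = state, boundary = boundary, truncated = truncated),
    class = "local_graph")
}

#' @export
print.local_graph <- function(x, ...) {
  cat(sprintf("<local_graph seed '%s'>  %d genes (%d state nodes), K = %d%s\n",
              x$seed, length(x$genes), length(x$state_nodes), x$K,
              if (!x$truncated) " [whole component]" else ""))
  invisible(x)
}
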