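#' Construct a single network layer
#'
#' A layer is one undirected, unweighted PPI network: an edge list over gene
#' symbols plus an optional per-layer weight applied uniformly to all its
#' edges when the layer is emphasized inside a multiplex (weight `w > 1`
#' focuses the random walk on that network's structure).
#'
#' Gene identifiers are whitespace-trimmed and matched case-sensitively; no
#' alias resolution is attempted. Self-loops are dropped and duplicate edges
#' (in either orientation) are stored once.
#'
#' @param edges two-column character matrix or data frame of gene pairs.
#' @param name layer label (must be unique within a multiplex).
#' @param weight positive layer weight, default 1.
#' @param genes optional character vector of additional (isolated) genes to
#'   declare as present in the layer.
#' @return An object of class `layer_network` with elements `name`, `weight`,
#'   `edges` (m x 2 character matrix, each row sorted), and `genes`.
#' @examples
#' layer_network(cbind(c("TP53", "MDM2"), c("MDM2", "TP53")), name = "toy")
#' @export
layer_network <- function(edges, name = "layer", weight = 1, genes = NULL) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight <= 0)
    stop("layer weight must be a single positive number", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L)
    stop("edges must have exactly two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  edges[] <- trimws(edges)
  if (any(edges == "" | is.na(edges)))
    stop("empty or missing gene identifier in edge list", call. = FALSE)
  loops <- edges[, 1L] == edges[, 2L]
  n_loops <- sum(loops)
  if (n_loops > 0L) {
    edges <- edges[!loops, , drop = FALSE]
  }
  # undirected dedup: canonical orientation, then unique rows
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  edges <- cbind(a[keep], b[keep])
  colnames(edges) <- c("gene_a", "gene_b")
  genes <- sort(unique(c(as.character(edges), if (!is.null(genes)) trimws(genes))))
  structure(
    list(name = as.character(name)[1L], weight = as.numeric(weight),
         edges = edges, genes = genes, n_self_loops_dropped = n_loops),
    class = "layer_network")
}

#' @export
print.layer_network <- function(x, ...) {
  cat(sprintf("<layer_network '%s'>  %d genes, %d edges, weight %g\n",
              x$name, length(x$genes), nrow(x$edges), x$weight))
  invisible(x)
}

#' Build a multiplex network from a list of layers
#'
#' The physical node set `V` is the union of all layer gene sets; every gene
#' owns one state node per layer (`VM = V x L`), whether or not it appears in
#' that layer's input. Intralayer edges are copied verbatim from the layers;
#' interlayer edges between all pairs of a gene's state nodes are implicit and
#' materialized only in the walk adjacency (see [walk_model()]).
#'
#' @param layers list of [layer_network()] objects (at least one, all
#'   nonempty, unique names).
#' @param interlayer_weight positive weight of the implicit coupling edges
#'   between a gene's state nodes in different layers; default 1.
#' @return An object of class `multiplex` with elements `genes` (ordered V),
#'   `layers`, `interlayer_weight`, and sizes `n_genes` / `n_layers`.
#' @export
build_multiplex <- function(layers, interlayer_weight = 1) {
  if (inherits(layers, "layer_network")) layers <- list(layers)
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a nonempty list of layer_network objects", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1L), "layer_network")))
    stop("all elements of 'layers' must be layer_network objects", call. = FALSE)
  if (any(vapply(layers, function(l) length(l$genes), integer(1L)) == 0L))
    stop("empty layer: every layer must contain at least one gene", call. = FALSE)
  nms <- vapply(layers, function(l) l$name, character(1L))
  if (anyDuplicated(nms))
    stop("duplicate layer names: ", paste(nms[duplicated(nms)], collapse = ", "),
         call. = FALSE)
  if (!is.numeric(interlayer_weight) || interlayer_weight <= 0)
    stop("interlayer_weight must be positive", call. = FALSE)
  genes <- sort(unique(unlist(lapply(layers, function(l) l$genes))))
  names(layers) <- nms
  structure(
    list(genes = genes, layers = layers,
         interlayer_weight = as.numeric(interlayer_weight),
         n_genes = length(genes), n_layers = length(layers)),
    class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("<multiplex>  %d genes x %d layers = %d state nodes\n",
              x$n_genes, x$n_layers, x$n_genes * x$n_layers))
  for (l in x$layers)
    cat(sprintf("  layer '%s': %d genes, %d edges, weight %g\n",
                l$name, length(l$genes), nrow(l$edges), l$weight))
  invisible(x)
}

# state node indexing: state (i, alpha) -> (alpha - 1) * n_genes + i
state_index <- function(mx, gene_idx, layer_idx) {
  (layer_idx - 1L) * mx$n_genes + gene_idx
}

state_gene <- function(mx, state_idx) ((state_idx - 1L) %% mx$n_genes) + 1L
state_layer <- function(mx, state_idx) ((state_idx - 1L) %/% mx$n_genes) + 1L

#' State-node labels of a multiplex
#'
#' @param mx a `multiplex` object.
#' @return Character vector of length `n_genes * n_layers`, gene::layer.
#' @keywords internal
state_labels <- function(mx) {
  as.vector(outer(mx$genes, names(mx$layers), paste, sep = "::"))
}

#' Classic random walk model of a multiplex network
#'
#' Assembles the weighted state-node adjacency `A` (intralayer edges at their
#' layer weight, plus interlayer edges of weight `interlayer_weight` between
#' every pair of state nodes of the same gene), the row-stochastic transition
#' matrix `T = D^-1 A`, and the stationary distribution of the walk. For a
#' classic (undirected, reversible) walk the stationary distribution is
#' degree-proportional, `p(i_a) = deg(i_a) / sum(deg)`, so it is computed in
#' closed form; power iteration is used only as an independent check in the
#' test suite.
#'
#' With a single layer, genes that are isolated have zero degree: their walk
#' row is undefined, and they are flagged unwalkable and excluded from local
#' graphs. With two or more layers every state node is walkable through the
#' interlayer coupling.
#'
#' @param mx a `multiplex` object from [build_multiplex()].
#' @return An object of class `walk_model`: sparse symmetric `adjacency`,
#'   `deg` (weighted state-node degrees), `stationary` (p, sums to 1),
#'   `unwalkable` (logical per state node), and the parent dimensions.
#' @export
walk_model <- function(mx) {
  stopifnot(inherits(mx, "multiplex"))
  n <- mx$n_genes
  L <- mx$n_layers
  nm <- n * L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in seq_len(L)) {
    lay <- mx$layers[[a]]
    if (nrow(lay$edges) > 0L) {
      gi <- match(lay$edges[, 1L], mx$genes)
      gj <- match(lay$edges[, 2L], mx$genes)
      ii <- c(ii, state_index(mx, gi, a))
      jj <- c(jj, state_index(mx, gj, a))
      xx <- c(xx, rep(lay$weight, length(gi)))
    }
  }
  if (L >= 2L) {
    pairs <- utils::combn(L, 2L)
    for (k in seq_len(ncol(pairs))) {
      ii <- c(ii, state_index(mx, seq_len(n), pairs[1L, k]))
      jj <- c(jj, state_index(mx, seq_len(n), pairs[2L, k]))
      xx <- c(xx, rep(mx$interlayer_weight, n))
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nm),
                            symmetric = FALSE)
  A <- A + Matrix::t(A)
  deg <- Matrix::rowSums(A)
  unwalkable <- deg == 0
  if (any(unwalkable)) {
    bad_genes <- unique(mx$genes[state_gene(mx, which(unwalkable))])
    warning(sprintf("%d isolated gene(s) are unwalkable (single-layer multiplex): %s",
                    length(bad_genes),
                    paste(utils::head(bad_genes, 5L), collapse = ", ")),
            call. = FALSE)
  }
  p <- deg / sum(deg)
  structure(
    list(adjacency = A, deg = deg, stationary = p, unwalkable = unwalkable,
         n_genes = n, n_layers = L, genes = mx$genes,
         total_weight = sum(deg)),
    class = "walk_model")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("<walk_model>  %d state nodes, total weighted degree %g, %d unwalkable\n",
              length(x$deg), x$total_weight, sum(x$unwalkable)))
  invisible(x)
}

#' Row-stochastic transition matrix of the walk
#'
#' @param walk a `walk_model`.
#' @return Sparse row-stochastic matrix T (rows of unwalkable state nodes are
#'   zero and flagged in `walk$unwalkable`).
#' @export
transition_matrix <- function(walk) {
  d <- ifelse(walk$deg > 0, 1 / walk$deg, 0)
  Matrix::Diagonal(x = d) %*% walk$adjacency
}

#' Generalized conductance of a state-node set
#'
#' The outflow of stationary random-walk probability from `S` relative to the
#' stationary mass inside `S`. For the classic walk this equals
#' `cut(S) / volume(S)`: the total adjacency weight crossing the boundary of
#' `S` divided by the summed weighted degree of `S` (the walk normalizers
#' cancel), which is how it is computed here.
#'
#' @param walk a `walk_model`.
#' @param S integer vector of state-node indices (nonempty, proper subset).
#' @return Conductance in `[0, 1]`.
#' @export
conductance <- function(walk, S) {
  S <- unique(as.integer(S))
  nm <- length(walk$deg)
  if (length(S) == 0L) stop("S must be nonempty", call. = FALSE)
  if (any(S < 1L | S > nm)) stop("state index out of range", call. = FALSE)
  if (length(S) == nm) stop("S must be a proper subset of the state nodes", call. = FALSE)
  vol <- sum(walk$deg[S])
  if (vol == 0) return(0)
  internal <- sum(walk$adjacency[S, S, drop = FALSE])
  cut <- sum(walk$deg[S]) - internal
  cut / vol
}

#' State-node set of a physical gene set (cover constraint)
#'
#' @param mx a `multiplex`.
#' @param genes character vector of gene identifiers.
#' @return Integer state-node indices of `genes x layers`.
#' @export
cover_states <- function(mx, genes) {
  gi <- match(genes, mx$genes)
  if (anyNA(gi)) stop("gene(s) not in multiplex: ",
                      paste(genes[is.na(gi)], collapse = ", "), call. = FALSE)
  as.integer(outer(gi, (seq_len(mx$n_layers) - 1L) * mx$n_genes, `+`))
}

#' Aggregated network of a multiplex
#'
#' One undirected, unweighted network on the physical genes whose edge set is
#' the union of all layer edge sets. Used for seed ordering (count of seed
#' neighbours) and available as a single-network baseline.
#'
#' @param mx a `multiplex`.
#' @return A `layer_network` named "aggregate" with weight 1.
#' @export
aggregate_network <- function(mx) {
  stopifnot(inherits(mx, "multiplex"))
  edges <- do.call(rbind, lapply(mx$layers, function(l) l$edges))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  layer_network(edges, name = "aggregate", weight = 1, genes = mx$genes)
}
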