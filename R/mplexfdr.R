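#' Detect significantly perturbed subnetworks on a multiplex of PPI networks
#'
#' End-to-end driver. The input networks become layers of a multiplex
#' network sharing one physical gene set; gene p-values are converted to
#' local FDRs by an empirical Bayes two-groups fit (unless precomputed lfdrs
#' are supplied); genes with lfdr below `B` become seeds, ordered by how many
#' other seeds they neighbour in the aggregated network; and for each seed
#' not yet absorbed by an earlier result, the connected, layer-covering,
#' FDR-bounded subnetwork of minimum random-walk conductance is found inside
#' a personalized-PageRank local graph.
#'
#' @param layers list of [layer_network()] objects, or a character vector of
#'   edge-list TSV paths (read with [read_layer()]).
#' @param scores gene scores: an `lfdr_fit`, a `data.frame(gene, pvalue)` or
#'   named p-value vector (lfdrs are then estimated), or - with
#'   `scores_are_lfdr = TRUE` - a `data.frame(gene, lfdr)` / named lfdr
#'   vector.
#' @param B subnetwork FDR bound, default 0.1.
#' @param K local exploration size in state nodes, default 400.
#' @param teleport PPR continuation parameter, default 0.998.
#' @param layer_weights optional numeric vector recycled over the layers
#'   (overrides the weights stored in the `layer_network` objects); a weight
#'   above 1 emphasizes that network's structure.
#' @param interlayer_weight weight of the implicit coupling edges, default 1.
#' @param scores_are_lfdr set TRUE when `scores` already holds local FDRs.
#' @param time_limit per-seed solver budget in seconds, default 600.
#' @param restrict_seeds optional character vector: only genes in it are
#'   used as seeds (e.g. genes of a context-specific layer).
#' @param verbose print per-seed progress, default FALSE.
#' @return An object of class `mplexfdr_result` with elements `subnetworks`
#'   (list of `subnetwork`), `seeds`, `scores` (the lfdr table used),
#'   `multiplex`, `config`, `log`, and `unmatched_genes` (scored genes absent
#'   from every layer). Methods: `print`, `summary`, `as.data.frame`, `plot`.
#' @examples
#' \donttest{
#' sc <- generate_scenario(n_genes = 120, n_modules = 2,
#'                         module_size = c(8, 10), rng_seed = 1)
#' fit <- estimate_local_fdr(sc$pvalues)
#' res <- mplexfdr(sc$layers, fit, B = 0.1, K = 60)
#' res
#' }
#' @export
mplexfdr <- function(layers, scores, B = 0.1, K = 400, teleport = 0.998,
                     layer_weights = NULL, interlayer_weight = 1,
                     scores_are_lfdr = FALSE, time_limit = 600,
                     restrict_seeds = NULL, verbose = FALSE) {
  if (is.character(layers))
    layers <- lapply(layers, read_layer)
  if (inherits(layers, "layer_network")) layers <- list(layers)
  if (!is.null(layer_weights)) {
    layer_weights <- rep_len(layer_weights, length(layers))
    for (k in seq_along(layers)) layers[[k]]$weight <- layer_weights[k]
  }
  mx <- build_multiplex(layers, interlayer_weight = interlayer_weight)
  walk <- walk_model(mx)

  if (scores_are_lfdr) {
    lmap <- lfdr_lookup(scores)
    score_tab <- data.frame(gene = names(lmap), pvalue = NA_real_,
                            z = NA_real_, lfdr = unname(lmap),
                            stringsAsFactors = FALSE)
    fit <- NULL
  } else if (inherits(scores, "lfdr_fit")) {
    fit <- scores
    score_tab <- fit$table
  } else {
    fit <- estimate_local_fdr(scores)
    score_tab <- fit$table
  }
  unmatched <- setdiff(score_tab$gene, mx$genes)

  seeds <- select_seeds(score_tab, B, mx, walk)
  if (!is.null(restrict_seeds))
    seeds <- seeds[seeds$seed %in% restrict_seeds, , drop = FALSE]
  subnets <- detect_all(mx, walk, score_tab, seeds, B = B, K = K,
                        teleport = teleport, time_limit = time_limit,
                        verbose = verbose)
  structure(
    list(subnetworks = subnets, seeds = seeds, scores = score_tab,
         lfdr_fit = fit, multiplex = mx,
         config = list(B = B, K = K, teleport = teleport,
                       interlayer_weight = interlayer_weight,
                       layer_weights = vapply(mx$layers, `[[`, numeric(1L), "weight"),
                       time_limit = time_limit),
         log = attr(subnets, "log"), unmatched_genes = unmatched),
    class = "mplexfdr_result")
}

#' @export
print.mplexfdr_result <- function(x, ...) {
  ns <- length(x$subnetworks)
  ng <- length(unique(unlist(lapply(x$subnetworks, `[[`, "genes"))))
  cat(sprintf("<mplexfdr_result>  %d subnetworks, %d genes (B = %g, K = %d, %d layers)\n",
              ns, ng, x$config$B, x$config$K, x$multiplex$n_layers))
  if (ns > 0L) {
    fdrs <- vapply(x$subnetworks, `[[`, numeric(1L), "est_fdr")
    cat(sprintf("  mean estimated FDR %.3f (max %.3f)\n", mean(fdrs), max(fdrs)))
  }
  invisible(x)
}

#' @export
summary.mplexfdr_result <- function(object, ...) {
  print(object)
  for (sn in object$subnetworks) print(sn)
  invisible(object)
}

#' Flat per-gene view of a detection result
#'
#' @param x an `mplexfdr_result`.
#' @param ... unused.
#' @return Data frame with columns `subnetwork_id`, `seed`, `gene`, `lfdr`,
#'   `conductance`, `est_fdr`, `status`; one row per (subnetwork, gene).
#' @export
as.data.frame.mplexfdr_result <- function(x, ...) {
  if (length(x$subnetworks) == 0L)
    return(data.frame(subnetwork_id = integer(), seed = character(),
                      gene = character(), lfdr = numeric(),
                      conductance = numeric(), est_fdr = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  w <- stats::setNames(x$scores$lfdr, x$scores$gene)
  do.call(rbind, lapply(seq_along(x$subnetworks), function(k) {
    sn <- x$subnetworks[[k]]
    data.frame(subnetwork_id = k, seed = sn$seed, gene = sn$genes,
               lfdr = unname(w[sn$genes]), conductance = sn$conductance,
               est_fdr = sn$est_fdr, status = sn$status,
               stringsAsFactors = FALSE)
  }))
}

#' Plot detected subnetworks on the aggregated network
#'
#' @param x an `mplexfdr_result`.
#' @param max_subnetworks draw at most this many subnetworks (default 9).
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.mplexfdr_result <- function(x, max_subnetworks = 9, ...) {
  sns <- utils::head(x$subnetworks, max_subnetworks)
  if (length(sns) == 0L) {
    message("nothing to plot: no subnetworks detected")
    return(invisible(x))
  }
  agg <- aggregate_network(x$multiplex)
  genes <- unique(unlist(lapply(sns, `[[`, "genes")))
  e <- agg$edges
  keep <- e[, 1L] %in% genes & e[, 2L] %in% genes
  g <- igraph::graph_from_data_frame(as.data.frame(e[keep, , drop = FALSE]),
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  memb <- rep(NA_integer_, length(genes)); names(memb) <- genes
  for (k in seq_along(sns)) memb[sns[[k]]$genes] <- k
  pal <- grDevices::hcl.colors(max(memb, na.rm = TRUE), "Dark 3")
  igraph::plot.igraph(g, vertex.color = pal[memb[igraph::V(g)$name]],
                      vertex.size = 8, vertex.label.cex = 0.6, ...)
  invisible(x)
}
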