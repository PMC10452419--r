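#' Generate a planted-module multiplex benchmark scenario
#'
#' Builds a scaffold graph with disjoint dense planted modules
#' (Erdős–Rényi blocks with intra-module edge probability `module_density`)
#' on top of a sparse random background (mean degree `bg_degree`), derives
#' each layer by independently rewiring a fraction of the scaffold's edges
#' with degree preservation, and draws gene p-values from the
#' signal-to-noise decomposition: `Beta(a, 1)` for module (target) genes and
#' `U(0, 1)` for the rest — smaller `a` means stronger signal.
#'
#' Defaults reproduce the reference simulation conditions used throughout
#' the package's tests: 500 genes, 3 layers at 10% rewiring, 5 modules of
#' 10–20 genes, `a = 0.01`.
#'
#' @param n_genes number of genes, default 500.
#' @param n_layers number of layers, default 3.
#' @param n_modules number of planted modules, default 5.
#' @param module_size integer range (min, max) of module sizes, default
#'   `c(10, 20)`.
#' @param a beta-distribution signal parameter (> 0), default 0.01.
#' @param rewire_fraction per-layer fraction of scaffold edges rewired,
#'   default 0.1.
#' @param bg_degree mean background degree, default 4.
#' @param module_density intra-module edge probability, default 0.6.
#' @param rng_seed integer seed; fixed seed gives bit-identical output.
#' @return List with `layers` (list of `layer_network`), `truth` (list of
#'   module gene sets), `pvalues` (named vector), `scaffold`
#'   (`layer_network`), and the scenario parameters in `params`.
#' @export
generate_scenario <- function(n_genes = 500, n_layers = 3, n_modules = 5,
                              module_size = c(10, 20), a = 0.01,
                              rewire_fraction = 0.1, bg_degree = 4,
                              module_density = 0.6, rng_seed = NULL) {
  if (a <= 0) stop("'a' must be positive", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  size_range <- seq.int(module_size[1L], module_size[2L])
  sizes <- size_range[sample.int(length(size_range), n_modules, replace = TRUE)]
  if (sum(sizes) > n_genes)
    stop("planted modules need ", sum(sizes), " genes but n_genes = ", n_genes,
         call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  pool <- sample(genes)
  truth <- vector("list", n_modules)
  off <- 0L
  for (k in seq_len(n_modules)) {
    truth[[k]] <- sort(pool[(off + 1L):(off + sizes[k])])
    off <- off + sizes[k]
  }

  # sparse background: ER with edge probability bg_degree / (n - 1)
  p_bg <- bg_degree / (n_genes - 1)
  n_bg <- stats::rbinom(1L, choose(n_genes, 2L), p_bg)
  bg <- matrix(genes[random_pairs(n_genes, n_bg)], ncol = 2L)
  # dense module blocks
  blocks <- lapply(truth, function(mod) {
    cmb <- utils::combn(mod, 2L)
    keep <- stats::runif(ncol(cmb)) < module_density
    t(cmb[, keep, drop = FALSE])
  })
  scaffold <- layer_network(rbind(bg, do.call(rbind, blocks)),
                            name = "scaffold", genes = genes)

  m <- nrow(scaffold$edges)
  layers <- lapply(seq_len(n_layers), function(k) {
    lay <- rewire_degree_preserving(scaffold,
                                    n_swaps = ceiling(rewire_fraction * m / 2))
    lay$name <- sprintf("layer%d", k)
    lay$genes <- genes
    lay
  })

  target <- unlist(truth)
  pvalues <- stats::setNames(stats::runif(n_genes), genes)
  pvalues[target] <- stats::rbeta(length(target), a, 1)

  list(layers = layers, truth = truth, pvalues = pvalues, scaffold = scaffold,
       params = list(n_genes = n_genes, n_layers = n_layers,
                     n_modules = n_modules, sizes = sizes, a = a,
                     rewire_fraction = rewire_fraction, bg_degree = bg_degree,
                     module_density = module_density, rng_seed = rng_seed))
}

# n_pairs distinct unordered pairs from n items (index matrix rows)
random_pairs <- function(n, n_pairs) {
  seen <- character(0)
  out <- matrix(integer(0), ncol = 2L)
  while (nrow(out) < n_pairs) {
    need <- n_pairs - nrow(out)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(n, 2L * need, replace = TRUE)
    ok <- i != j
    a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
    key <- paste(a, b)
    new <- !(key %in% seen) & !duplicated(key)
    seen <- c(seen, key[new])
    out <- rbind(out, cbind(a[new], b[new]))
  }
  out[seq_len(n_pairs), , drop = FALSE]
}

#' Degree-preserving randomization of a layer
#'
#' Repeated double-edge swaps: two edges (a, b) and (c, d) are replaced by
#' (a, d) and (c, b); proposals creating self-loops or duplicate edges are
#' rejected. The degree sequence is invariant by construction. `n_swaps`
#' counts successful swaps; attempts are capped at `20 * n_swaps + 100`, so
#' rigid graphs (few valid swaps) return early.
#'
#' @param layer a `layer_network` with at least 2 edges.
#' @param n_swaps number of successful swaps to perform.
#' @param rng_seed optional integer seed.
#' @return A new `layer_network` with the same name, weight, genes and
#'   degree sequence.
#' @export
rewire_degree_preserving <- function(layer, n_swaps, rng_seed = NULL) {
  stopifnot(inherits(layer, "layer_network"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  e <- layer$edges
  m <- nrow(e)
  if (m < 2L) stop("layer must have at least 2 edges", call. = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  present <- new.env(parent = emptyenv())
  for (k in seq_len(m)) assign(key(e[k, 1L], e[k, 2L]), TRUE, envir = present)
  done <- 0L
  tries <- 0L
  max_tries <- 20L * n_swaps + 100L
  while (done < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    kk <- sample.int(m, 2L)
    a <- e[kk[1L], 1L]; b <- e[kk[1L], 2L]
    c_ <- e[kk[2L], 1L]; d <- e[kk[2L], 2L]
    # propose (a,d) and (c,b); reject self-loops and multi-edges
    if (a == d || c_ == b) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (k1 == k2) next
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(a, b), key(c_, d)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    e[kk[1L], ] <- c(a, d)
    e[kk[2L], ] <- c(c_, b)
    done <- done + 1L
  }
  layer_network(e, name = layer$name, weight = layer$weight, genes = layer$genes)
}

#' F score between two gene sets
#'
#' Harmonic mean of precision and recall of `detected` against `target`;
#' 0 when `detected` is empty or the sets are disjoint.
#'
#' @param target nonempty character vector (ground-truth genes).
#' @param detected character vector of detected genes.
#' @return F score in `[0, 1]`.
#' @export
f_score <- function(target, detected) {
  target <- unique(target); detected <- unique(detected)
  if (length(target) == 0L) stop("target set must be nonempty", call. = FALSE)
  if (length(detected) == 0L) return(0)
  tp <- length(intersect(target, detected))
  if (tp == 0L) return(0)
  prec <- tp / length(detected)
  rec <- tp / length(target)
  2 * prec * rec / (prec + rec)
}

#' Symmetric Fsub score between two collections of gene sets
#'
#' Size-weighted best-match F score in both directions, averaged:
#' `Fsub(A, B) = 1/2 [ sum_i |A_i| max_j F(A_i, B_j) / sum_i |A_i|
#'                   + sum_i |B_i| max_j F(B_i, A_j) / sum_i |B_i| ]`.
#' Symmetric by construction; 1 iff the collections match exactly.
#'
#' @param A,B nonempty lists of nonempty gene sets.
#' @return Fsub in `[0, 1]`.
#' @export
fsub_score <- function(A, B) {
  if (length(A) == 0L || length(B) == 0L)
    stop("both collections must be nonempty", call. = FALSE)
  one_way <- function(X, Y) {
    sizes <- lengths(X)
    best <- vapply(X, function(x)
      max(vapply(Y, function(y) f_score(x, y), numeric(1L))), numeric(1L))
    sum(sizes * best) / sum(sizes)
  }
  (one_way(A, B) + one_way(B, A)) / 2
}

#' Evaluate a detection result against planted ground truth
#'
#' @param detected an `mplexfdr_result`, a list of `subnetwork` objects, or
#'   a list of gene sets.
#' @param truth nonempty list of ground-truth module gene sets.
#' @param scores optional lfdr source for estimated FDRs.
#' @return An object of class `evaluation_report`: pooled-gene `f_score`,
#'   `fsub`, per-subnetwork `exact_fdr` (proportion of non-target genes) and
#'   `est_fdr` (mean lfdr), and counts.
#' @export
evaluate_detection <- function(detected, truth, scores = NULL) {
  if (length(truth) == 0L) stop("truth must be nonempty", call. = FALSE)
  if (inherits(detected, "mplexfdr_result")) detected <- detected$subnetworks
  sets <- lapply(detected, function(d) if (inherits(d, "subnetwork")) d$genes else d)
  sets <- Filter(length, sets)
  target <- unique(unlist(truth))
  pooled <- unique(unlist(sets))
  f <- f_score(target, pooled)
  fsub <- if (length(sets) > 0L) fsub_score(truth, sets) else 0
  exact_fdr <- vapply(sets, function(s) mean(!(s %in% target)), numeric(1L))
  est_fdr <- if (!is.null(scores) && length(sets) > 0L)
    vapply(sets, subnetwork_fdr, numeric(1L), scores = scores)
  else rep(NA_real_, length(sets))
  structure(
    list(f_score = f, fsub = fsub, exact_fdr = exact_fdr, est_fdr = est_fdr,
         n_detected = length(sets), n_truth = length(truth),
         zero_detections = length(sets) == 0L),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>  F = %.3f, Fsub = %.3f, %d/%d subnetworks\n",
              x$f_score, x$fsub, x$n_detected, x$n_truth))
  if (x$n_detected > 0L)
    cat(sprintf("  exact FDR mean %.3f; est. FDR mean %s\n",
                mean(x$exact_fdr),
                if (all(is.na(x$est_fdr))) "NA" else sprintf("%.3f", mean(x$est_fdr))))
  if (x$zero_detections) cat("  (zero detections)\n")
  invisible(x)
}
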