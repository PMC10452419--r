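#' Build the optimization instance for one seed's local graph
#'
#' Collapses the state-node selection variables of the conductance program to
#' one binary variable per physical gene (the cover constraint makes a gene's
#' state nodes move together, and interlayer edges therefore never cross the
#' cut). For a gene set `P` containing the seed, the cut weight of
#' `S = P x L` is `N(P) = sum_{i<j} c_ij |x_i - x_j| + sum_i b_i x_i` and its
#' volume is `D(P) = sum_i d_i x_i`, so `N/D` is exactly the generalized
#' conductance of `S`:
#' * `c_ij` - summed layer weights of intralayer edges between local genes i
#'   and j,
#' * `b_i` - total intralayer weight from i's state nodes to genes outside
#'   the local graph,
#' * `d_i` - full multiplex weighted degree of i's state nodes (interlayer
#'   coupling included).
#'
#' @param local a [extract_local_graph()] result.
#' @param mx the parent `multiplex`.
#' @param walk the [walk_model()] of `mx`.
#' @param scores lfdr source (see [subnetwork_fdr()]).
#' @param B FDR bound in (0, 1).
#' @return An object of class `search_instance`.
#' @export
build_instance <- function(local, mx, walk, scores, B) {
  stopifnot(inherits(local, "local_graph"), inherits(mx, "multiplex"))
  genes <- local$genes
  n <- length(genes)
  w <- lfdr_lookup(scores)
  lfdr <- w[genes]
  if (anyNA(lfdr)) {
    warning(sum(is.na(lfdr)), " unscored local gene(s) treated as lfdr = 1",
            call. = FALSE)
    lfdr[is.na(lfdr)] <- 1
  }
  names(lfdr) <- genes

  # internal cut coefficients c_ij, accumulated over layers
  cmap <- new.env(parent = emptyenv())
  for (lay in mx$layers) {
    e <- lay$edges
    if (nrow(e) == 0L) next
    i <- match(e[, 1L], genes)
    j <- match(e[, 2L], genes)
    ok <- !is.na(i) & !is.na(j)
    for (k in which(ok)) {
      key <- paste0(i[k], "_", j[k])
      cmap[[key]] <- (if (is.null(cmap[[key]])) 0 else cmap[[key]]) + lay$weight
    }
  }
  keys <- ls(cmap)
  if (length(keys) > 0L) {
    ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    pair_i <- as.integer(ij[, 1L])
    pair_j <- as.integer(ij[, 2L])
    pair_c <- vapply(keys, function(k) cmap[[k]], numeric(1L), USE.NAMES = FALSE)
    ord <- order(pair_i, pair_j)
    pair_i <- pair_i[ord]; pair_j <- pair_j[ord]; pair_c <- pair_c[ord]
  } else {
    pair_i <- integer(0); pair_j <- integer(0); pair_c <- numeric(0)
  }

  gi <- match(genes, mx$genes)
  d <- vapply(seq_len(n), function(k)
    sum(walk$deg[state_index(mx, gi[k], seq_len(mx$n_layers))]), numeric(1L))
  b <- local$boundary[genes]

  structure(
    list(genes = genes, seed = local$seed,
         seed_idx = match(local$seed, genes),
         pair_i = pair_i, pair_j = pair_j, pair_c = pair_c,
         b = unname(b), d = unname(d), lfdr = unname(lfdr), B = B,
         n_multiplex_genes = mx$n_genes),
    class = "search_instance")
}

#' @export
print.search_instance <- function(x, ...) {
  cat(sprintf("<search_instance seed '%s'>  %d genes, %d internal edges, B = %g\n",
              x$seed, length(x$genes), length(x$pair_c), x$B))
  invisible(x)
}

# cut and volume of a gene-index subset under the instance coefficients
instance_cut_volume <- function(inst, sel) {
  inside <- logical(length(inst$genes))
  inside[sel] <- TRUE
  cross <- xor(inside[inst$pair_i], inside[inst$pair_j])
  cut <- sum(inst$pair_c[cross]) + sum(inst$b[sel])
  c(cut = cut, volume = sum(inst$d[sel]))
}

find_python <- function() {
  py <- getOption("mplexfdr.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no 'python' interpreter found on the PATH; the subnetwork search ",
         "needs Python with scipy >= 1.9 (see ?solve_subnetwork)", call. = FALSE)
  unname(py)
}

#' Solve one seed's minimum-conductance subnetwork problem
#'
#' Finds the gene set `P` (containing the seed, connected in the local
#' physical adjacency, with mean lfdr at most `B`) that minimizes the
#' generalized conductance `N(P)/D(P)` of the covered state-node set. The
#' fractional objective is handled by Dinkelbach iteration: each round
#' solves the parametric mixed-integer program `min N(x) - lambda D(x)`
#' (cut terms linearized, connectivity enforced by single-commodity flow
#' from the seed) and updates `lambda` to the achieved ratio, until the
#' parametric optimum is nonnegative (within 1e-9). The MILPs are solved by
#' the HiGHS branch-and-bound backend through a bundled Python helper.
#'
#' On a solver timeout the best feasible incumbent is returned with status
#' `"incumbent"`; if no solution was found at all, the seed alone is
#' returned with status `"singleton-fallback"` (the seed's own lfdr is below
#' `B` for seeds chosen by [select_seeds()]).
#'
#' @param inst a [build_instance()] result.
#' @param time_limit wall-clock budget in seconds for this seed (default 600).
#' @param mip_rel_gap relative MIP gap passed to the solver; default 0 for
#'   instances up to 40 genes, 1e-6 above.
#' @return An object of class `subnetwork`: `seed`, `genes`, `conductance`,
#'   `est_fdr`, `status` (`optimal` / `incumbent` / `singleton-fallback` /
#'   `infeasible`), `iterations`, `lambdas`, `certificate`.
#' @export
solve_subnetwork <- function(inst, time_limit = 600, mip_rel_gap = NULL) {
  stopifnot(inherits(inst, "search_instance"))
  s <- inst$seed_idx
  if (inst$lfdr[s] > inst$B) {
    warning("seed '", inst$seed, "' has lfdr above the bound; problem infeasible",
            call. = FALSE)
    return(new_subnetwork(inst, integer(0), NA_real_, "infeasible", 0L,
                          numeric(0), NA_real_))
  }
  # restrict to the seed's connected component of the local physical graph
  g <- igraph::graph_from_data_frame(
    data.frame(from = inst$pair_i, to = inst$pair_j),
    directed = FALSE,
    vertices = data.frame(name = seq_along(inst$genes)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == comp$membership[s])
  if (length(keep) == 1L) {
    cv <- instance_cut_volume(inst, s)
    return(new_subnetwork(inst, s, unname(cv["cut"] / cv["volume"]),
                          "optimal", 0L, numeric(0), 0))
  }
  sub <- restrict_instance(inst, keep)

  if (is.null(mip_rel_gap))
    mip_rel_gap <- if (length(sub$genes) <= 40L) 0 else 1e-6
  # conductance is undefined for the full state-node space: when the seed's
  # component spans the entire multiplex, the all-genes selection is excluded
  forbid_all <- length(keep) == inst$n_multiplex_genes
  payload <- list(
    n = length(sub$genes), seed = sub$seed_idx,
    pair_i = sub$pair_i, pair_j = sub$pair_j, pair_c = sub$pair_c,
    b = sub$b, d = sub$d, lfdr = sub$lfdr, B = sub$B,
    forbid_all = forbid_all,
    time_limit = time_limit, mip_rel_gap = mip_rel_gap,
    dinkelbach_tol = 1e-9, max_iter = 50L)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  helper <- system.file("python", "milp_dinkelbach.py", package = "mplexfdr")
  rc <- suppressWarnings(system2(find_python(), c(shQuote(helper), shQuote(fin),
                                                  shQuote(fout)),
                                 stdout = NULL, stderr = TRUE))
  status_ok <- file.exists(fout) && is.null(attr(rc, "status"))
  if (!status_ok) {
    warning("MILP backend failed for seed '", inst$seed,
            "'; returning the seed alone", call. = FALSE)
    cv <- instance_cut_volume(inst, s)
    return(new_subnetwork(inst, s, unname(cv["cut"] / cv["volume"]),
                          "singleton-fallback", 0L, numeric(0), NA_real_))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  sel <- keep[as.integer(res$selected)]
  if (res$status == "solver_failed") {
    warning("MILP solver found no solution for seed '", inst$seed,
            "'; returning the seed alone", call. = FALSE)
    sel <- s
    res$status <- "singleton-fallback"
  }
  cv <- instance_cut_volume(inst, sel)
  lam <- unname(cv["cut"] / cv["volume"])
  out <- new_subnetwork(inst, sel, lam,
                        if (res$status == "incumbent") "incumbent"
                        else if (res$status == "singleton-fallback") "singleton-fallback"
                        else "optimal",
                        as.integer(res$iterations),
                        as.numeric(res$lambdas),
                        if (is.null(res$certificate)) NA_real_
                        else as.numeric(res$certificate))
  validate_subnetwork(out, inst)
  out
}

restrict_instance <- function(inst, keep) {
  remap <- match(seq_along(inst$genes), keep)
  ok <- !is.na(remap[inst$pair_i]) & !is.na(remap[inst$pair_j])
  structure(
    list(genes = inst$genes[keep], seed = inst$seed,
         seed_idx = remap[inst$seed_idx],
         pair_i = remap[inst$pair_i[ok]], pair_j = remap[inst$pair_j[ok]],
         pair_c = inst$pair_c[ok],
         b = inst$b[keep], d = inst$d[keep], lfdr = inst$lfdr[keep], B = inst$B,
         n_multiplex_genes = inst$n_multiplex_genes),
    class = "search_instance")
}

new_subnetwork <- function(inst, sel, conductance, status, iterations,
                           lambdas, certificate) {
  genes <- sort(inst$genes[sel])
  structure(
    list(seed = inst$seed, genes = genes, conductance = conductance,
         est_fdr = if (length(sel)) mean(inst$lfdr[sel]) else NA_real_,
         status = status, iterations = iterations, lambdas = lambdas,
         certificate = certificate),
    class = "subnetwork")
}

validate_subnetwork <- function(sn, inst) {
  if (sn$status == "infeasible" || length(sn$genes) == 0L) return(invisible(sn))
  if (sn$est_fdr > inst$B + 1e-12)
    warning("subnetwork for seed '", sn$seed, "' violates the FDR bound (",
            format(sn$est_fdr), " > ", inst$B, ")", call. = FALSE)
  sel <- match(sn$genes, inst$genes)
  if (length(sel) > 1L) {
    ok <- inst$pair_i %in% sel & inst$pair_j %in% sel
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(inst$pair_i[ok], sel),
                 to = match(inst$pair_j[ok], sel)),
      directed = FALSE, vertices = data.frame(name = seq_along(sel)))
    if (igraph::components(g)$no != 1L)
      warning("subnetwork for seed '", sn$seed, "' is not connected", call. = FALSE)
  }
  invisible(sn)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork seed '%s'>  %d genes, conductance %.4g, est. FDR %.4g [%s]\n",
              x$seed, length(x$genes), x$conductance, x$est_fdr, x$status))
  if (length(x$genes)) cat("  ", paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

#' Detect subnetworks for an ordered seed list
#'
#' Iterates the seeds in order; a seed already absorbed into a previously
#' returned subnetwork is skipped. For every remaining seed the pipeline
#' runs [extract_local_graph()] -> [build_instance()] -> [solve_subnetwork()].
#'
#' @param mx a `multiplex`.
#' @param walk its [walk_model()].
#' @param scores lfdr source (see [subnetwork_fdr()]).
#' @param seeds a data frame from [select_seeds()] or a character vector of
#'   seed genes (already ordered).
#' @param B FDR bound (default 0.1).
#' @param K local exploration size in state nodes (default 400).
#' @param teleport PPR continuation parameter (default 0.998).
#' @param time_limit per-seed solver budget in seconds (default 600).
#' @param verbose print one progress line per seed.
#' @return List of `subnetwork` objects, with a per-seed log data frame in
#'   `attr(, "log")`.
#' @export
detect_all <- function(mx, walk, scores, seeds, B = 0.1, K = 400,
                       teleport = 0.998, time_limit = 600, verbose = FALSE) {
  if (is.data.frame(seeds)) seeds <- seeds$seed
  seeds <- as.character(seeds)
  out <- list()
  covered <- character(0)
  log <- list()
  for (s in seeds) {
    if (s %in% covered) {
      log[[length(log) + 1L]] <- data.frame(seed = s, action = "skipped",
                                            n_local = NA_integer_, status = NA_character_,
                                            n_genes = NA_integer_, conductance = NA_real_,
                                            est_fdr = NA_real_, seconds = 0,
                                            stringsAsFactors = FALSE)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    lg <- suppressWarnings(extract_local_graph(walk, mx, s, K = K, teleport = teleport))
    inst <- build_instance(lg, mx, walk, scores, B)
    sn <- solve_subnetwork(inst, time_limit = time_limit)
    el <- proc.time()[["elapsed"]] - t0
    if (sn$status != "infeasible" && length(sn$genes) > 0L) {
      out[[length(out) + 1L]] <- sn
      covered <- union(covered, sn$genes)
    }
    log[[length(log) + 1L]] <- data.frame(seed = s, action = "solved",
                                          n_local = length(lg$genes),
                                          status = sn$status,
                                          n_genes = length(sn$genes),
                                          conductance = sn$conductance,
                                          est_fdr = sn$est_fdr, seconds = el,
                                          stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("seed %-12s local %3d genes -> %2d genes, phi %.4f, FDR %.3f [%s] (%.1fs)",
                      s, length(lg$genes), length(sn$genes), sn$conductance,
                      sn$est_fdr, sn$status, el))
  }
  attr(out, "log") <- do.call(rbind, log)
  out
}
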