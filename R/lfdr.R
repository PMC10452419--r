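#' Estimate per-gene local false discovery rates (two-groups model)
#'
#' Fits Efron's two-groups model to gene-level p-values. Each p-value is
#' transformed to a one-sided z-score `z = qnorm(1 - p)` (large z =
#' significant; p clipped to `[1e-15, 1 - 1e-15]`). The marginal density
#' `f(z)` is estimated by Lindsey's method: counts over `bins` histogram cells
#' spanning `[min(z) - 0.1, max(z) + 0.1]` are modelled by Poisson regression
#' on a polynomial basis of degree `df`. The null density `f0` is the standard
#' normal (`null = "theoretical"`) or a normal with centre/scale estimated
#' from the central half of the z range (`null = "empirical"`). The null
#' proportion `pi0` is the largest value with `pi0 * f0 <= f` over the central
#' window (capped at 1), and the local FDR of gene `i` is
#' `lfdr_i = min(1, pi0 * f0(z_i) / f(z_i))` - the posterior probability that
#' the gene is null given its statistic.
#'
#' If the Poisson fit fails to converge, a kernel-density estimate of `f`
#' with a monotone (isotonic) correction of the lfdr curve in the right tail
#' is used instead, with a warning.
#'
#' @param pvalues named numeric vector of p-values in `[0, 1]`, or a data
#'   frame with columns `gene` and `pvalue`.
#' @param null `"theoretical"` (standard normal null, default) or
#'   `"empirical"`.
#' @param df degree of the polynomial basis in the Poisson regression
#'   (default 7).
#' @param bins number of histogram cells (default 120).
#' @return An object of class `lfdr_fit`: `table` (data frame gene, pvalue,
#'   z, lfdr), `pi0`, `null` parameters, and the density fit, with `print()`
#'   and `plot()` methods.
#' @examples
#' set.seed(1)
#' p <- c(stats::runif(450), stats::rbeta(50, 0.01, 1))
#' names(p) <- sprintf("g%03d", seq_along(p))
#' fit <- estimate_local_fdr(p)
#' fit
#' @export
estimate_local_fdr <- function(pvalues, null = c("theoretical", "empirical"),
                               df = 7, bins = 120) {
  null <- match.arg(null)
  if (is.data.frame(pvalues)) {
    if (!all(c("gene", "pvalue") %in% names(pvalues)))
      stop("data frame input needs columns 'gene' and 'pvalue'", call. = FALSE)
    p <- stats::setNames(as.numeric(pvalues$pvalue), as.character(pvalues$gene))
  } else {
    p <- pvalues
  }
  if (is.null(names(p)) || any(names(p) == ""))
    stop("p-values must be named by gene", call. = FALSE)
  if (anyDuplicated(names(p)))
    stop("duplicate gene in p-value table", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n < 200L)
    warning("fewer than 200 genes; density estimation may be unstable",
            call. = FALSE)
  if (length(unique(p)) == 1L)
    stop("degenerate input: all p-values identical; cannot fit two-groups model",
         call. = FALSE)
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(1 - pc)

  lo <- min(z) - 0.1
  hi <- max(z) + 0.1
  breaks <- seq(lo, hi, length.out = bins + 1L)
  binw <- breaks[2L] - breaks[1L]
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE), nbins = bins)
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2

  basis <- stats::poly(mids, degree = df)
  fit <- tryCatch(
    suppressWarnings(stats::glm(counts ~ basis, family = stats::poisson())),
    error = function(e) NULL)
  fallback <- is.null(fit) || !fit$converged
  if (!fallback) {
    # marginal density on the gene z-values via the fitted Poisson rates
    zb <- stats::predict(basis, z)
    eta <- cbind(1, zb) %*% stats::coef(fit)
    fz <- pmax(exp(as.vector(eta)) / (n * binw), 1e-300)
    grid_f <- pmax(fit$fitted.values / (n * binw), 1e-300)
  } else {
    warning("Poisson density fit did not converge; falling back to a kernel ",
            "estimate with monotone tail correction", call. = FALSE)
    kd <- stats::density(z, from = lo, to = hi, n = 512L)
    fz <- pmax(stats::approx(kd$x, kd$y, xout = z, rule = 2L)$y, 1e-300)
    grid_f <- pmax(stats::approx(kd$x, kd$y, xout = mids, rule = 2L)$y, 1e-300)
  }

  # central 50% of the z range: null estimation / pi0 window
  win <- c(lo + 0.25 * (hi - lo), lo + 0.75 * (hi - lo))
  in_win <- z >= win[1L] & z <= win[2L]
  if (null == "empirical" && sum(in_win) >= 10L) {
    delta <- mean(z[in_win]); sigma <- stats::sd(z[in_win])
    if (!is.finite(sigma) || sigma <= 0) { delta <- 0; sigma <- 1 }
  } else {
    if (null == "empirical")
      warning("too few central z-values for an empirical null; using theoretical",
              call. = FALSE)
    delta <- 0; sigma <- 1
  }
  f0 <- function(x) stats::dnorm(x, mean = delta, sd = sigma)

  gwin <- mids >= win[1L] & mids <= win[2L]
  ratio <- grid_f[gwin] / pmax(f0(mids[gwin]), 1e-300)
  pi0 <- min(1, min(ratio[is.finite(ratio)]))
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1

  lfdr <- pmin(1, pi0 * f0(z) / fz)
  if (fallback) {
    # enforce a non-increasing lfdr right of the null centre
    ord <- order(z)
    zo <- z[ord]; lo_ <- lfdr[ord]
    right <- zo > delta
    if (sum(right) > 2L) {
      iso <- stats::isoreg(zo[right], -lo_[right])
      lfdr[ord][right] <- pmin(1, -iso$yf)
    }
  }

  tab <- data.frame(gene = names(p), pvalue = as.numeric(p), z = z,
                    lfdr = lfdr, stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(table = tab, pi0 = pi0, null = null,
         null_params = c(mean = delta, sd = sigma),
         df = df, bins = bins, breaks = breaks, counts = counts,
         grid = mids, grid_f = grid_f, window = win, fallback = fallback),
    class = "lfdr_fit")
}

#' @export
print.lfdr_fit <- function(x, ...) {
  cat(sprintf("<lfdr_fit>  %d genes, pi0 = %.3f, null = %s%s\n",
              nrow(x$table), x$pi0, x$null,
              if (x$fallback) " (kernel fallback)" else ""))
  cat(sprintf("  lfdr < 0.1: %d genes; lfdr < 0.5: %d genes\n",
              sum(x$table$lfdr < 0.1), sum(x$table$lfdr < 0.5)))
  invisible(x)
}

#' @export
summary.lfdr_fit <- function(object, ...) {
  print(object)
  print(summary(object$table$lfdr))
  invisible(object)
}

#' @export
#' @importFrom graphics hist lines legend
plot.lfdr_fit <- function(x, ...) {
  graphics::hist(x$table$z, breaks = x$breaks, freq = FALSE,
                 main = "two-groups fit", xlab = "z", border = "grey70", ...)
  graphics::lines(x$grid, x$grid_f, col = "steelblue", lwd = 2)
  graphics::lines(x$grid, x$pi0 * stats::dnorm(x$grid, x$null_params[1L],
                                               x$null_params[2L]),
                  col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topright", c("f (marginal)", "pi0 * f0 (null)"),
                   col = c("steelblue", "firebrick"), lwd = 2, lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' @export
as.data.frame.lfdr_fit <- function(x, ...) x$table

# accept an lfdr_fit, a data.frame(gene, lfdr), or a named numeric vector
lfdr_lookup <- function(scores) {
  if (inherits(scores, "lfdr_fit")) scores <- scores$table
  if (is.data.frame(scores)) {
    if (!all(c("gene", "lfdr") %in% names(scores)))
      stop("score table needs columns 'gene' and 'lfdr'", call. = FALSE)
    stats::setNames(as.numeric(scores$lfdr), as.character(scores$gene))
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    scores
  } else {
    stop("scores must be an lfdr_fit, a data.frame(gene, lfdr), or a named vector",
         call. = FALSE)
  }
}

#' Estimated FDR of a subnetwork
#'
#' The mean local FDR of the distinct physical genes in the subnetwork. A
#' gene represented by state nodes in several layers counts once; genes
#' without a score are treated as surely null (`lfdr = 1`) with a warning.
#'
#' @param genes character vector of physical genes (the subnetwork's `P_S`).
#' @param scores an `lfdr_fit`, a `data.frame(gene, lfdr)`, or a named
#'   numeric lfdr vector.
#' @return Mean lfdr in `[0, 1]`.
#' @export
subnetwork_fdr <- function(genes, scores) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  w <- lfdr_lookup(scores)
  v <- w[genes]
  if (anyNA(v)) {
    warning(sum(is.na(v)), " unscored gene(s) treated as lfdr = 1", call. = FALSE)
    v[is.na(v)] <- 1
  }
  mean(v)
}

#' Select and order seed genes
#'
#' Seeds are the walkable genes with local FDR strictly below the bound `B`.
#' They are ordered by the descending count of other seeds among their direct
#' neighbours in the aggregated network (so that seeds in seed-rich
#' neighbourhoods are searched first and later seeds already absorbed into a
#' subnetwork can be skipped); ties are broken lexicographically.
#'
#' @param scores an `lfdr_fit`, `data.frame(gene, lfdr)`, or named lfdr vector.
#' @param B FDR bound in (0, 1).
#' @param mx a `multiplex` (defines walkability and the aggregated network).
#' @param walk optional precomputed [walk_model()] (avoids recomputation).
#' @return Data frame with columns `seed` and `n_seed_neighbors`, ordered;
#'   zero rows (with a message) when no gene passes the bound.
#' @export
select_seeds <- function(scores, B, mx, walk = NULL) {
  if (!is.numeric(B) || B <= 0 || B >= 1)
    stop("B must lie strictly between 0 and 1", call. = FALSE)
  w <- lfdr_lookup(scores)
  if (is.null(walk)) walk <- suppressWarnings(walk_model(mx))
  unwalk_genes <- unique(mx$genes[state_gene(mx, which(walk$unwalkable))])
  cand <- names(w)[w < B]
  cand <- intersect(cand, setdiff(mx$genes, unwalk_genes))
  if (length(cand) == 0L) {
    message("no seed genes: no scored, walkable gene has lfdr < ", B)
    return(data.frame(seed = character(), n_seed_neighbors = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate_network(mx)
  is_seed <- stats::setNames(rep(FALSE, length(mx$genes)), mx$genes)
  is_seed[cand] <- TRUE
  cnt <- stats::setNames(integer(length(cand)), cand)
  if (nrow(agg$edges) > 0L) {
    e <- agg$edges
    for (col in 1:2) {
      other <- e[, 3L - col]
      sel <- e[, col] %in% cand & is_seed[other]
      t0 <- table(e[sel, col])
      cnt[names(t0)] <- cnt[names(t0)] + as.integer(t0)
    }
  }
  ord <- order(-cnt, names(cnt))
  data.frame(seed = names(cnt)[ord], n_seed_neighbors = as.integer(cnt[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine local FDR tables across data types by per-gene minimum
#'
#' Local FDRs are comparable across data types (mutation, amplification,
#' deletion, ...), so a gene significant in any one of them keeps its
#' smallest lfdr. Genes absent from a table contribute nothing to its
#' minimum.
#'
#' @param ... lfdr sources (each an `lfdr_fit`, `data.frame(gene, lfdr)`, or
#'   named numeric vector), or a single list of them.
#' @return Named numeric vector of per-gene minimum lfdrs.
#' @export
combine_lfdr_min <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is.data.frame(args[[1L]]) &&
      !inherits(args[[1L]], "lfdr_fit"))
    args <- args[[1L]]
  if (length(args) == 0L) stop("no lfdr tables given", call. = FALSE)
  maps <- lapply(args, lfdr_lookup)
  genes <- sort(unique(unlist(lapply(maps, names))))
  out <- rep(Inf, length(genes)); names(out) <- genes
  for (m in maps) out[names(m)] <- pmin(out[names(m)], m)
  out
}
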