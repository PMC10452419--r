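#' Read a network layer from a two-column TSV edge list
#'
#' Lines starting with `#` are comments; a header row is detected when its
#' tokens look like column labels (`gene`, `gene1`, `protein_a`, `source`,
#' `from`, ...). Self-loops are dropped with a message; duplicate edges (in
#' either orientation) are stored once.
#'
#' @param path file path.
#' @param name layer label; defaults to the file name without extension.
#' @param weight layer weight, default 1.
#' @return A [layer_network()].
#' @export
read_layer <- function(path, name = NULL, weight = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L)
    stop("malformed line ", lineno[bad[1L]], " in ", path,
         " (expected two tab-separated genes): ", lines[bad[1L]], call. = FALSE)
  e <- t(vapply(parts, function(x) trimws(x[1:2]), character(2L)))
  header_tokens <- c("gene", "gene1", "gene2", "gene_a", "gene_b", "genea",
                     "geneb", "source", "target", "from", "to", "protein1",
                     "protein2", "protein_a", "protein_b", "node1", "node2",
                     "interactor_a", "interactor_b", "symbol_a", "symbol_b")
  if (nrow(e) > 0L && all(tolower(e[1L, ]) %in% header_tokens))
    e <- e[-1L, , drop = FALSE]
  if (nrow(e) == 0L) stop("no edges in ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lay <- layer_network(e, name = name, weight = weight)
  if (lay$n_self_loops_dropped > 0L)
    message(lay$n_self_loops_dropped, " self-loop(s) dropped from ", path)
  lay
}

#' Read a gene score table (p-values or local FDRs)
#'
#' Two-column TSV `gene TAB value`, optional header. Values must lie in
#' `[0, 1]`; duplicated genes are accepted only when their values agree.
#'
#' @param path file path.
#' @param kind `"pvalue"` (default) or `"lfdr"`.
#' @return Named numeric vector (gene -> value).
#' @export
read_scores <- function(path, kind = c("pvalue", "lfdr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty score table: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed score line in ", path, call. = FALSE)
  gene <- trimws(vapply(parts, `[`, character(1L), 1L))
  valtok <- trimws(vapply(parts, `[`, character(1L), 2L))
  val <- suppressWarnings(as.numeric(valtok))
  if (is.na(val[1L]) && length(val) > 1L) {  # header row
    gene <- gene[-1L]; val <- val[-1L]; valtok <- valtok[-1L]
  }
  if (anyNA(val))
    stop("non-numeric ", kind, " for gene ", gene[which(is.na(val))[1L]],
         " in ", path, call. = FALSE)
  if (any(val < 0 | val > 1))
    stop(kind, " outside [0, 1] for gene ",
         gene[which(val < 0 | val > 1)[1L]], " in ", path, call. = FALSE)
  if (anyDuplicated(gene)) {
    agree <- tapply(val, gene, function(v) length(unique(v)) == 1L)
    if (!all(agree))
      stop("duplicate gene(s) with conflicting values: ",
           paste(utils::head(names(agree)[!agree], 5L), collapse = ", "),
           call. = FALSE)
    first <- !duplicated(gene)
    gene <- gene[first]; val <- val[first]
  }
  stats::setNames(val, gene)
}

#' Write an lfdr table to TSV
#'
#' @param fit an `lfdr_fit` (or its table).
#' @param path output path.
#' @export
write_scores <- function(fit, path) {
  tab <- if (inherits(fit, "lfdr_fit")) fit$table else fit
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detection results to JSON (and optionally a flat TSV)
#'
#' The JSON is an array of `{seed, genes, conductance, est_fdr, status}`
#' objects in detection order with genes sorted lexicographically; the TSV
#' holds one row per (subnetwork, gene). [read_results()] reconstructs the
#' gene sets exactly.
#'
#' @param result an `mplexfdr_result` or list of `subnetwork` objects.
#' @param json_path output JSON path.
#' @param tsv_path optional flat TSV path.
#' @param edges_path optional path for per-layer edge lists of each
#'   subnetwork (TSV: subnetwork_id, layer, gene_a, gene_b).
#' @export
write_results <- function(result, json_path, tsv_path = NULL, edges_path = NULL) {
  sns <- if (inherits(result, "mplexfdr_result")) result$subnetworks else result
  recs <- lapply(seq_along(sns), function(k) {
    sn <- sns[[k]]
    list(seed = sn$seed, genes = as.list(sort(sn$genes)),
         conductance = sn$conductance, est_fdr = sn$est_fdr,
         status = sn$status)
  })
  jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(tsv_path)) {
    if (inherits(result, "mplexfdr_result")) {
      flat <- as.data.frame(result)[, c("subnetwork_id", "gene", "lfdr")]
    } else {
      flat <- do.call(rbind, lapply(seq_along(sns), function(k)
        data.frame(subnetwork_id = k, gene = sort(sns[[k]]$genes),
                   lfdr = NA_real_, stringsAsFactors = FALSE)))
      if (is.null(flat))
        flat <- data.frame(subnetwork_id = integer(), gene = character(),
                           lfdr = numeric())
    }
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(edges_path) && inherits(result, "mplexfdr_result")) {
    rows <- list()
    for (k in seq_along(sns)) {
      for (lay in result$multiplex$layers) {
        e <- lay$edges
        inset <- e[, 1L] %in% sns[[k]]$genes & e[, 2L] %in% sns[[k]]$genes
        if (any(inset))
          rows[[length(rows) + 1L]] <-
            data.frame(subnetwork_id = k, layer = lay$name,
                       gene_a = e[inset, 1L], gene_b = e[inset, 2L],
                       stringsAsFactors = FALSE)
      }
    }
    ed <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subnetwork_id = integer(), layer = character(),
                 gene_a = character(), gene_b = character())
    utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}

#' Read detection results back from JSON
#'
#' @param json_path path written by [write_results()].
#' @return List of `subnetwork` objects (status and scores preserved).
#' @export
read_results <- function(json_path) {
  recs <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  lapply(recs, function(r)
    structure(list(seed = r$seed, genes = sort(unlist(r$genes)),
                   conductance = as.numeric(r$conductance),
                   est_fdr = as.numeric(r$est_fdr), status = r$status,
                   iterations = NA_integer_, lambdas = numeric(0),
                   certificate = NA_real_),
              class = "subnetwork"))
}
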