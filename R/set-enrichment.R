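# Module x regulon gene-set overlap, one-sided Fisher enrichment,
# Benjamini-Hochberg adjustment and the per-module significance summary.

#' Overlap counts between two gene-set collections
#'
#' Restricts both collections to the declared universe and counts
#' pairwise intersections.
#'
#' @param modules,regulons named lists of gene-id vectors.
#' @param universe character vector of all gene ids; defaults to the union
#'   of both collections.
#' @param outside how to treat genes outside the universe: `"error"`
#'   (default) or `"drop"` with a warning.
#' @return integer matrix (modules x regulons) of overlap counts, with
#'   attributes `module_sizes`, `regulon_sizes`, `universe_size`
#'   (post-restriction).
#' @export
overlap_counts <- function(modules, regulons, universe = NULL,
                           outside = c("error", "drop")) {
  outside <- match.arg(outside)
  stopifnot(length(modules) >= 1L, length(regulons) >= 1L)
  if (anyDuplicated(names(modules)) || anyDuplicated(names(regulons)))
    stop_input("set names must be unique")
  if (is.null(universe)) universe <- unique(unlist(c(modules, regulons)))
  strays <- setdiff(unique(unlist(c(modules, regulons))), universe)
  if (length(strays)) {
    if (outside == "error")
      stop_input("gene(s) outside the declared universe: %s",
                 paste(utils::head(strays, 10L), collapse = ", "))
    warning(sprintf("%d gene(s) outside the universe dropped", length(strays)))
  }
  modules <- lapply(modules, function(s) unique(intersect(s, universe)))
  regulons <- lapply(regulons, function(s) unique(intersect(s, universe)))
  counts <- vapply(regulons, function(r)
    vapply(modules, function(m) length(intersect(m, r)), integer(1)),
    integer(length(modules)))
  counts <- matrix(counts, length(modules), length(regulons),
                   dimnames = list(names(modules), names(regulons)))
  structure(counts,
            module_sizes = lengths(modules),
            regulon_sizes = lengths(regulons),
            universe_size = length(universe))
}

#' One-sided Fisher (hypergeometric) enrichment p-values
#'
#' For each (module, regulon) cell, the probability of observing an
#' intersection at least as large as the one counted, under hypergeometric
#' sampling of the regulon from a universe of size N containing the module:
#' `p = P(X >= overlap)`, `X ~ Hypergeometric(N, K = |module|,
#' n = |regulon|)`. An overlap of 0 gives p = 1 exactly.
#'
#' @param counts overlap-count matrix from [overlap_counts()] (or a plain
#'   matrix plus explicit sizes).
#' @param module_sizes,regulon_sizes,universe_size taken from the `counts`
#'   attributes when omitted.
#' @return numeric matrix of one-sided p-values in (0, 1\].
#' @export
fisher_enrichment <- function(counts, module_sizes = NULL,
                              regulon_sizes = NULL, universe_size = NULL) {
  if (is.null(module_sizes)) module_sizes <- attr(counts, "module_sizes")
  if (is.null(regulon_sizes)) regulon_sizes <- attr(counts, "regulon_sizes")
  if (is.null(universe_size)) universe_size <- attr(counts, "universe_size")
  stopifnot(!is.null(module_sizes), !is.null(regulon_sizes),
            !is.null(universe_size))
  K <- rep(module_sizes, times = ncol(counts))
  n <- rep(regulon_sizes, each = nrow(counts))
  x <- as.vector(counts)
  if (any(K > universe_size) || any(n > universe_size))
    stop_input("set size exceeds the universe size")
  if (any(x > pmin(K, n)) || any(x < 0))
    stop_input("inconsistent table: overlap outside [0, min(sizes)]")
  p <- stats::phyper(x - 1L, K, universe_size - K, n, lower.tail = FALSE)
  matrix(p, nrow(counts), ncol(counts), dimnames = dimnames(counts))
}

#' BH adjustment and per-module significance summary of an overlap grid
#'
#' Benjamini-Hochberg step-up adjustment applied jointly across all
#' module x regulon cells, plus the per-module flag of having at least one
#' significant overlap (modules without one correspond to grayed rows in
#' the overlap heatmap).
#'
#' @param p p-value matrix from [fisher_enrichment()].
#' @param counts optional overlap-count matrix for the long-format grid.
#' @param method adjustment method for [stats::p.adjust()].
#' @param alpha significance level on the adjusted p.
#' @return list with `adjusted` (matrix), `log10_adjusted`, `grid`
#'   (long-format `data.frame`), `module_summary` (`module`,
#'   `n_significant`, `any_significant`).
#' @export
adjust_and_summarize <- function(p, counts = NULL, method = "BH",
                                 alpha = 0.05) {
  stopifnot(is.matrix(p), all(p > 0 & p <= 1))
  adj <- matrix(stats::p.adjust(as.vector(p), method = method),
                nrow(p), ncol(p), dimnames = dimnames(p))
  grid <- data.frame(
    module = rep(rownames(p), times = ncol(p)),
    regulon = rep(colnames(p), each = nrow(p)),
    overlap = if (is.null(counts)) NA_integer_ else as.vector(counts),
    p = as.vector(p), p_adj = as.vector(adj),
    log10_p_adj = log10(as.vector(adj)))
  sig <- adj <= alpha
  module_summary <- data.frame(
    module = rownames(p),
    n_significant = rowSums(sig),
    any_significant = rowSums(sig) > 0, row.names = NULL)
  list(adjusted = adj, log10_adjusted = log10(adj), grid = grid,
       module_summary = module_summary)
}
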