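# Cross-dataset consensus labeling: nomenclature harmonization, all-source
# agreement filtering with exempt families, marker ranking, a pluggable
# probabilistic classifier with a score cutoff, and the probabilistic
# cross-similarity matrix between cell types.

#' Harmonize source-specific labels to a shared nomenclature
#'
#' Replaces every label in a multi-source label matrix by its harmonized
#' name using a per-source homology map. `"unassigned"` is preserved.
#'
#' @param label_matrix `data.frame` with a `cell_id` column and one label
#'   column per source.
#' @param homology_map named list (one element per source) of named
#'   character vectors `source_label -> harmonized_label`. Sources absent
#'   from the map are treated as already harmonized only if an identity
#'   entry exists for every label present.
#' @return harmonized label matrix, same shape.
#' @export
harmonize <- function(label_matrix, homology_map) {
  stopifnot("cell_id" %in% names(label_matrix))
  sources <- setdiff(names(label_matrix), "cell_id")
  out <- label_matrix
  for (s in sources) {
    map <- homology_map[[s]]
    if (is.null(map)) stop_input("no homology map for source '%s'", s)
    lab <- label_matrix[[s]]
    need <- setdiff(unique(lab), c("unassigned", names(map)))
    if (length(need))
      stop_input("unmapped label(s) in source '%s': %s", s,
                 paste(need, collapse = ", "))
    out[[s]] <- ifelse(lab == "unassigned", "unassigned",
                       unname(map[lab]))
  }
  out
}

#' Consensus filter: keep cells on which all sources agree
#'
#' A cell is kept when every source assigns it the same harmonized label,
#' or when all its source labels fall inside a single exempt family
#' (families of labels whose cross-assignment is known to be unreliable
#' are treated as one group). `"unassigned"` from any source counts as
#' disagreement.
#'
#' @param label_matrix harmonized label matrix (from [harmonize()] or
#'   already harmonized).
#' @param exempt_families named list of harmonized-label vectors.
#' @return list with `kept` (cell ids) and `report` (`data.frame` with
#'   `cell_id`, `kept`, `reason` in
#'   `{"agree", "exempt_family", "unassigned", "disagree"}`).
#' @export
consensus_filter <- function(label_matrix, exempt_families = list()) {
  stopifnot("cell_id" %in% names(label_matrix))
  sources <- setdiff(names(label_matrix), "cell_id")
  if (length(sources) < 1L) stop_input("label matrix has no source columns")
  mat <- as.matrix(label_matrix[, sources, drop = FALSE])
  reason <- apply(mat, 1L, function(lab) {
    if (any(lab == "unassigned")) return("unassigned")
    if (length(unique(lab)) == 1L) return("agree")
    for (fam in names(exempt_families))
      if (all(lab %in% exempt_families[[fam]])) return("exempt_family")
    "disagree"
  })
  kept <- reason %in% c("agree", "exempt_family")
  report <- data.frame(cell_id = label_matrix$cell_id, kept = kept,
                       reason = reason, row.names = NULL)
  list(kept = label_matrix$cell_id[kept], report = report)
}

#' Rank marker genes per cell type by two specificity heuristics
#'
#' For each gene and type: the log2 fold change of pseudocounted means
#' (`log2((mean_in + 1) / (mean_out + 1))`) and the expressing-fraction
#' difference (fraction of in-type cells with expression > 0 minus the
#' same fraction outside). Each heuristic yields a descending rank; the
#' final rank of a gene is its best (minimum) rank across the two.
#'
#' @param expr genes x cells matrix with gene rownames.
#' @param labels per-cell type labels.
#' @param top_k markers returned per type.
#' @param n_hvg number of globally most-variable genes unioned into the
#'   feature set.
#' @return list with `markers` (named list per type of top-k gene ids),
#'   `table` (long `data.frame` of both heuristics and ranks) and
#'   `features` (union of all top-k markers and the HVGs).
#' @export
rank_markers <- function(expr, labels, top_k = 20L, n_hvg = 50L) {
  stopifnot(is.matrix(expr), ncol(expr) == length(labels))
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (length(types) < 2L) stop_input("need >= 2 cell types")
  rows <- list()
  markers <- list()
  for (tp in types) {
    inn <- labels == tp
    if (sum(inn) < 2L) {
      warning(sprintf("type '%s' has < 2 cells: skipped", tp))
      next
    }
    m_in <- rowMeans(expr[, inn, drop = FALSE])
    m_out <- rowMeans(expr[, !inn, drop = FALSE])
    lfc <- log2((m_in + 1) / (m_out + 1))
    frac <- rowMeans(expr[, inn, drop = FALSE] > 0) -
            rowMeans(expr[, !inn, drop = FALSE] > 0)
    r1 <- rank(-lfc, ties.method = "min")
    r2 <- rank(-frac, ties.method = "min")
    final <- pmin(r1, r2)
    ord <- order(final, -lfc, rownames(expr))
    markers[[tp]] <- rownames(expr)[ord][seq_len(min(top_k, nrow(expr)))]
    rows[[tp]] <- data.frame(cell_type = tp, gene = rownames(expr),
                             log2fc = unname(lfc), frac_diff = unname(frac),
                             rank_fc = unname(r1), rank_frac = unname(r2),
                             rank = unname(final))
  }
  hvg <- rownames(expr)[order(-apply(expr, 1L, stats::var))]
  hvg <- hvg[seq_len(min(n_hvg, length(hvg)))]
  list(markers = markers,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       features = union(unlist(markers), hvg))
}

#' Train a probabilistic classifier and score query cells
#'
#' Features shared between reference and query are min-max scaled per gene
#' (fit on the reference), a probabilistic classifier produces per-class
#' scores summing to 1 per cell, and cells whose top score falls below
#' `cutoff` are left `"unassigned"`. The default classifier is a
#' regularized multinomial linear model with normalized-exponential
#' (softmax) outputs; any function
#' `function(train_x, train_y, test_x) -> probability matrix` can be
#' plugged in.
#'
#' @param ref_expr,ref_labels reference genes x cells matrix and labels.
#' @param query_expr query genes x cells matrix (gene rownames shared with
#'   the reference, at least partly).
#' @param features optional feature gene set; defaults to
#'   [rank_markers()] features computed on the reference.
#' @param cutoff assignment-score cutoff below which a cell stays
#'   unassigned.
#' @param exclude genes to drop before training (e.g. cell-cycle genes).
#' @param classifier optional classifier function (see Details).
#' @param decay ridge penalty of the default multinomial model.
#' @return list with `scores` (query cells x classes, rows sum to 1) and
#'   `labels` (hard assignments with `"unassigned"`).
#' @export
train_and_score <- function(ref_expr, ref_labels, query_expr,
                            features = NULL, cutoff = 0.55,
                            exclude = character(0), classifier = NULL,
                            decay = 1e-3) {
  stopifnot(is.matrix(ref_expr), is.matrix(query_expr))
  if (is.null(features))
    features <- rank_markers(ref_expr, ref_labels)$features
  features <- setdiff(features, exclude)
  shared <- intersect(intersect(features, rownames(ref_expr)),
                      rownames(query_expr))
  if (!length(shared)) stop_input("no shared feature genes")
  tr <- t(ref_expr[shared, , drop = FALSE])
  te <- t(query_expr[shared, , drop = FALSE])
  # per-gene min-max scaling fit on the reference
  lo <- apply(tr, 2L, min); hi <- apply(tr, 2L, max)
  keep <- hi > lo
  if (!any(keep)) stop_input("all shared features are constant in the reference")
  tr <- sweep(sweep(tr[, keep, drop = FALSE], 2L, lo[keep]), 2L,
              (hi - lo)[keep], "/")
  te <- sweep(sweep(te[, keep, drop = FALSE], 2L, lo[keep]), 2L,
              (hi - lo)[keep], "/")
  if (is.null(classifier)) classifier <- multinom_classifier(decay)
  scores <- classifier(tr, factor(ref_labels), te)
  stopifnot(is.matrix(scores), nrow(scores) == nrow(te))
  scores <- scores / rowSums(scores)
  rownames(scores) <- colnames(query_expr)
  top <- max.col(scores, ties.method = "first")
  hard <- colnames(scores)[top]
  hard[scores[cbind(seq_len(nrow(scores)), top)] < cutoff] <- "unassigned"
  list(scores = scores, labels = stats::setNames(hard, rownames(scores)))
}

multinom_classifier <- function(decay = 1e-3) {
  function(train_x, train_y, test_x) {
    df <- data.frame(.y = train_y, train_x, check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = df, decay = decay,
                          maxit = 200, trace = FALSE, MaxNWts = 1e5)
    p <- stats::predict(fit, newdata = data.frame(test_x, check.names = FALSE),
                        type = "probs")
    if (is.null(dim(p))) {  # two-class case returns a vector
      p <- cbind(1 - p, p)
      colnames(p) <- levels(train_y)
    }
    p
  }
}

#' Cross-dataset cell-type similarity from probabilistic score profiles
#'
#' Concatenated per-cell score profiles are reduced to their top principal
#' components; each cell's k nearest neighbors in that latent space are
#' found; the similarity of a type pair (one type per dataset) is the
#' Pearson correlation of the two types' mean PC profiles, computed only
#' for pairs connected by at least one cross-dataset neighbor edge (others
#' are floored to the minimum computed correlation). The matrix is then
#' passed through a sign-preserving power transform
#' (`sign(s) * |s|^power`) and column z-scored.
#'
#' @param scores cells x reference-classes score matrix (rows over all
#'   datasets combined).
#' @param dataset,type per-cell dataset and type labels.
#' @param n_pcs number of principal components (capped at what the data
#'   support, with a warning).
#' @param k neighbors per cell; must be < number of cells.
#' @param power exponent of the sign-preserving power transform.
#' @return list with `similarity` (query types x reference types: rows are
#'   the first dataset's types, columns the second's; the full
#'   group x group matrix for > 2 datasets), `raw` (pre-transform
#'   correlations) and `gated` (logical matrix of kNN-connected pairs).
#' @export
cross_similarity <- function(scores, dataset, type, n_pcs = 15L, k = 100L,
                             power = 1.25) {
  stopifnot(is.matrix(scores), nrow(scores) == length(dataset),
            nrow(scores) == length(type))
  dataset <- as.character(dataset); type <- as.character(type)
  datasets <- unique(dataset)
  if (length(datasets) < 2L) stop_input("need >= 2 datasets")
  n <- nrow(scores)
  if (k >= n) stop_input("k (%d) must be < number of cells (%d)", k, n)
  pc <- stats::prcomp(scores, center = TRUE, scale. = FALSE)$x
  if (n_pcs > ncol(pc)) {
    warning(sprintf("n_pcs reduced from %d to %d (available components)",
                    n_pcs, ncol(pc)))
    n_pcs <- ncol(pc)
  }
  pc <- pc[, seq_len(n_pcs), drop = FALSE]
  group <- paste(dataset, type, sep = "\r")
  groups <- unique(group)
  gmean <- t(vapply(groups, function(g)
    colMeans(pc[group == g, , drop = FALSE]), numeric(n_pcs)))
  # kNN edges in the latent space gate which type pairs get a correlation
  d2 <- as.matrix(stats::dist(pc))
  diag(d2) <- Inf
  gated <- matrix(FALSE, length(groups), length(groups),
                  dimnames = list(groups, groups))
  gi <- match(group, groups)
  for (i in seq_len(n)) {
    nn <- order(d2[i, ])[seq_len(k)]
    cross <- nn[dataset[nn] != dataset[i]]
    if (length(cross)) {
      gated[gi[i], gi[cross]] <- TRUE
      gated[gi[cross], gi[i]] <- TRUE
    }
  }
  raw <- stats::cor(t(gmean))
  dimnames(raw) <- list(groups, groups)
  floorv <- min(raw, na.rm = TRUE)
  sim <- ifelse(gated, raw, floorv)
  diag(sim) <- ifelse(diag(gated), diag(raw), floorv)
  if (length(datasets) == 2L) {
    rows <- groups[startsWith(groups, paste0(datasets[1], "\r"))]
    cols <- groups[startsWith(groups, paste0(datasets[2], "\r"))]
    sim <- sim[rows, cols, drop = FALSE]
    raw <- raw[rows, cols, drop = FALSE]
    gated <- gated[rows, cols, drop = FALSE]
    rownames(sim) <- rownames(raw) <- rownames(gated) <-
      sub("^.*\r", "", rows)
    colnames(sim) <- colnames(raw) <- colnames(gated) <-
      sub("^.*\r", "", cols)
  } else {
    nice <- sub("\r", ".", groups, fixed = TRUE)
    dimnames(sim) <- dimnames(raw) <- dimnames(gated) <- list(nice, nice)
  }
  sim <- sign(sim) * abs(sim) ^ power
  sim <- scale(sim)  # column z-score
  attr(sim, "scaled:center") <- attr(sim, "scaled:scale") <- NULL
  list(similarity = sim, raw = raw, gated = gated)
}
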