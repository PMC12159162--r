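# Pairwise cell-cell distances, volume normalization, cell-type distance
# matrix, neighbor scores and hierarchical ordering of the type matrix.

#' Pairwise Euclidean distances between cell centroids
#'
#' Computes the full symmetric matrix of centroid-to-centroid Euclidean
#' distances within one tissue section,
#' \eqn{d_{ij} = \sqrt{(x_i - x_j)^2 + (y_i - y_j)^2}}.
#'
#' @param cells a cell table (`data.frame`) with numeric columns `x_um` and
#'   `y_um` (centroid coordinates in micrometres) and a `cell_id` column.
#' @return numeric matrix (cells x cells), symmetric with zero diagonal,
#'   dimnames set to `cell_id`.
#' @export
pairwise_euclidean <- function(cells) {
  check_cell_table(cells, need_volume = FALSE)
  if (nrow(cells) < 2L) stop_input("need at least 2 cells, got %d", nrow(cells))
  bad <- !is.finite(cells$x_um) | !is.finite(cells$y_um)
  if (any(bad))
    stop_input("non-finite coordinates for cell_id: %s",
               paste(cells$cell_id[bad], collapse = ", "))
  d <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  dimnames(d) <- list(cells$cell_id, cells$cell_id)
  diag(d) <- 0
  d
}

#' Volume-normalize a pairwise distance matrix
#'
#' Divides each pairwise distance by the average volume of the two cells:
#' \eqn{d_{ij,\mathrm{norm}} = d_{ij} / ((v_i + v_j)/2)}. Cell size varies
#' systematically between types (large proprioceptors vs small nociceptors),
#' so raw centroid distances conflate packing with soma size; this removes
#' the size component. The result is unit-bearing (distance per unit volume).
#'
#' @param d raw distance matrix from [pairwise_euclidean()].
#' @param volumes numeric vector of per-cell volumes (> 0), aligned with the
#'   rows of `d`.
#' @return normalized distance matrix, symmetric, zero diagonal.
#' @export
volume_normalize <- function(d, volumes) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (length(volumes) != nrow(d))
    stop_input("volumes length (%d) != matrix dimension (%d)",
               length(volumes), nrow(d))
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop_input("all volumes must be finite and > 0")
  avg <- outer(volumes, volumes, function(a, b) (a + b) / 2)
  out <- d / avg
  diag(out) <- 0
  dimnames(out) <- dimnames(d)
  out
}

#' Aggregate normalized distances into a cell-type distance matrix
#'
#' Entry (A, B) is the mean normalized distance over all cross pairs of a
#' type-A cell and a type-B cell; the diagonal (A, A) averages over distinct
#' within-type pairs only (self-pairs are excluded, since their zero
#' distances would deflate the mean). A type with a single cell has no
#' within-type pair and gets an `NA` diagonal.
#'
#' @param dnorm normalized pairwise distance matrix.
#' @param labels character/factor vector of cell-type labels aligned with
#'   the rows of `dnorm`.
#' @return symmetric types x types matrix of mean normalized distances.
#' @export
aggregate_type_distance <- function(dnorm, labels) {
  stopifnot(is.matrix(dnorm), nrow(dnorm) == ncol(dnorm))
  if (length(labels) != nrow(dnorm))
    stop_input("labels length (%d) != matrix dimension (%d)",
               length(labels), nrow(dnorm))
  if (anyNA(labels)) stop_input("missing cell-type labels")
  labels <- as.character(labels)
  types <- sort(unique(labels))
  k <- length(types)
  out <- matrix(NA_real_, k, k, dimnames = list(types, types))
  idx <- split(seq_along(labels), labels)
  for (a in seq_len(k)) {
    ia <- idx[[types[a]]]
    for (b in a:k) {
      ib <- idx[[types[b]]]
      if (a == b) {
        if (length(ia) >= 2L) {
          block <- dnorm[ia, ia, drop = FALSE]
          out[a, a] <- mean(block[upper.tri(block)])
        } # single-cell type: diagonal stays NA (flagged missing)
      } else {
        out[a, b] <- out[b, a] <- mean(dnorm[ia, ib])
      }
    }
  }
  out
}

#' Neighbor score from a type-distance matrix
#'
#' Min-max inverts the mean normalized type distances so that 1 marks the
#' most co-localized pair of types and 0 the most spatially separated pair.
#' Alternatively (`method = "knn"`), scores are the symmetrized fraction of
#' each type's k nearest neighbors belonging to the other type, computed
#' from per-cell data.
#'
#' @param tdm type-distance matrix from [aggregate_type_distance()].
#' @param method `"minmax"` (default, distance-derived) or `"knn"`
#'   (neighborhood-composition; requires `cells`).
#' @param cells,k cell table and neighbor count for `method = "knn"`.
#' @return types x types matrix of scores in \[0, 1\].
#' @export
neighbor_score <- function(tdm, method = c("minmax", "knn"),
                           cells = NULL, k = 10L) {
  method <- match.arg(method)
  if (method == "knn") return(neighbor_score_knn(cells, k))
  stopifnot(is.matrix(tdm))
  fin <- tdm[is.finite(tdm)]
  if (length(unique(fin)) < 2L)
    stop_input("degenerate type-distance matrix: all finite entries equal (%s); neighbor score undefined",
               format(fin[1]))
  rng <- range(fin)
  out <- 1 - (tdm - rng[1]) / (rng[2] - rng[1])
  dimnames(out) <- dimnames(tdm)
  out
}

neighbor_score_knn <- function(cells, k = 10L) {
  check_cell_table(cells, need_volume = FALSE)
  stopifnot(k >= 1L, k < nrow(cells))
  d <- pairwise_euclidean(cells)
  diag(d) <- Inf
  labels <- as.character(cells$cell_type)
  types <- sort(unique(labels))
  comp <- matrix(0, length(types), length(types),
                 dimnames = list(types, types))
  for (i in seq_len(nrow(d))) {
    nn <- order(d[i, ])[seq_len(k)]
    tab <- table(factor(labels[nn], levels = types)) / k
    comp[labels[i], ] <- comp[labels[i], ] + tab
  }
  comp <- comp / as.vector(table(factor(labels, levels = types)))
  (comp + t(comp)) / 2
}

#' Hierarchically cluster the cell-type distance matrix
#'
#' Agglomerative clustering of types using the type-distance matrix as the
#' dissimilarity, average linkage by default. Types are ordered
#' lexicographically before clustering so equal-height merges resolve
#' deterministically.
#'
#' @param tdm symmetric, finite type-distance matrix.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an object of class `hclust`.
#' @seealso [write_type_tree()] to export the dendrogram as Newick.
#' @export
cluster_type_matrix <- function(tdm, linkage = "average") {
  stopifnot(is.matrix(tdm), nrow(tdm) == ncol(tdm))
  if (anyNA(tdm) || any(!is.finite(tdm)))
    stop_input("type-distance matrix contains NA/non-finite entries")
  ord <- order(rownames(tdm))
  tdm <- tdm[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(tdm), method = linkage)
}

check_cell_table <- function(cells, need_volume = TRUE) {
  need <- c("cell_id", "x_um", "y_um", "cell_type")
  if (need_volume) need <- c(need, "volume")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop_input("cell table missing column(s): %s", paste(miss, collapse = ", "))
  invisible(cells)
}
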