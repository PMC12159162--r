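# Post-processing of co-expression module eigengenes: redundant kME-based
# gene assignment, relative magnitude, module selection, digitization,
# signal width and uniqueness, identity bar decomposition, bin-matched
# per-cell gene-set scores and regulon dot scores.

#' Redundant assignment of genes to co-expression modules
#'
#' Each gene is assigned first to the module with its highest kME
#' (module-eigengene correlation), `R_max`, then additionally to every
#' module whose kME is at least `frac * R_max`. Genes whose `R_max` falls
#' below the floor `r_min` stay unassigned. Both thresholds are closed
#' (>=), so the argmax module always satisfies its own rule and exact
#' boundary ties are included.
#'
#' @param kme genes x modules matrix of kME values in \[-1, 1\].
#' @param r_min floor on `R_max` for assigning a gene to any module.
#' @param frac fraction of `R_max` a module must reach to share the gene.
#' @return `data.frame` with columns `gene`, `r_max`, `modules` (list
#'   column of assigned module names; empty character for unassigned) and
#'   `n_modules`.
#' @export
assign_genes <- function(kme, r_min = 0.3, frac = 0.95) {
  if (!is.matrix(kme) || nrow(kme) == 0L || ncol(kme) == 0L)
    stop_input("kME table must be a non-empty genes x modules matrix")
  if (any(!is.finite(kme))) stop_input("kME table contains non-finite values")
  if (any(kme < -1 | kme > 1)) stop_input("kME values must lie in [-1, 1]")
  mods <- colnames(kme)
  if (is.null(mods)) mods <- colnames(kme) <- paste0("M", seq_len(ncol(kme)))
  r_max <- apply(kme, 1L, max)
  assigned <- lapply(seq_len(nrow(kme)), function(i) {
    if (r_max[i] < r_min) return(character(0))
    mods[kme[i, ] >= frac * r_max[i] & kme[i, ] >= r_min]
  })
  genes <- rownames(kme)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(kme)))
  out <- data.frame(gene = genes, r_max = unname(r_max))
  out$modules <- assigned
  out$n_modules <- lengths(assigned)
  out
}

#' Module eigengene of a gene set
#'
#' First principal component of the per-gene standardized expression of the
#' module genes, scaled to unit variance and sign-fixed so that its
#' correlation with the module's mean standardized expression is
#' non-negative (the WGCNA convention).
#'
#' @param expr genes x cells expression matrix with gene rownames.
#' @param module_genes character vector of module gene ids (those absent
#'   from `expr` are dropped).
#' @return numeric per-cell eigengene vector, unit variance.
#' @export
compute_eigengene <- function(expr, module_genes) {
  stopifnot(is.matrix(expr))
  present <- intersect(module_genes, rownames(expr))
  if (!length(present))
    stop_input("no module gene present in the expression matrix")
  x <- expr[present, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop_input("zero-variance module gene(s): %s",
               paste(present[sds == 0], collapse = ", "))
  z <- t(scale(t(x)))  # standardize each gene across cells
  if (length(present) == 1L) {
    e <- drop(z)
  } else {
    e <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1]
  }
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  unname(e)
}

#' Per-group eigengene summary, magnitude and relative magnitude
#'
#' For one module eigengene, computes per-cluster and per-dataset means and
#' SDs; the magnitude (difference between the highest and lowest group
#' mean) and the relative magnitude (magnitude divided by the mean of the
#' group SDs), across clusters and across datasets separately. Relative
#' magnitude measures whether a module separates clusters (biology) or
#' datasets (batch).
#'
#' @param eigengene per-cell eigengene values.
#' @param cluster,dataset per-cell group labels aligned with `eigengene`.
#' @return an `eigengene_summary` list with elements `cluster` and
#'   `dataset`, each holding `means`, `sds`, `magnitude`,
#'   `relative_magnitude` (NA-flagged when the mean SD is 0 or undefined).
#' @export
summarize_and_magnitude <- function(eigengene, cluster, dataset) {
  stopifnot(length(eigengene) == length(cluster),
            length(eigengene) == length(dataset))
  if (anyNA(cluster) || anyNA(dataset))
    stop_input("every cell must carry both a cluster and a dataset label")
  out <- list(cluster = group_magnitude(eigengene, cluster),
              dataset = group_magnitude(eigengene, dataset))
  class(out) <- "eigengene_summary"
  out
}

group_magnitude <- function(x, g) {
  g <- as.character(g)
  means <- tapply(x, g, mean)
  sds <- tapply(x, g, stats::sd)  # NA for singleton groups
  if (anyNA(sds))
    warning(sprintf("group(s) with a single cell: SD excluded (%s)",
                    paste(names(sds)[is.na(sds)], collapse = ", ")))
  magnitude <- max(means) - min(means)
  mean_sd <- mean(sds, na.rm = TRUE)
  rel <- if (!is.finite(mean_sd) || mean_sd == 0) NA_real_
         else magnitude / mean_sd
  list(means = means, sds = sds, magnitude = unname(magnitude),
       relative_magnitude = unname(rel))
}

#' Select modules that separate clusters rather than datasets
#'
#' Keeps a module when its relative magnitude across clusters reaches
#' `cluster_rm_min` and exceeds its relative magnitude across datasets
#' (dataset-dominated modules are batch artifacts and are excluded). Both
#' criteria are reported per module so users can re-filter.
#'
#' @param summaries named list of [summarize_and_magnitude()] results, one
#'   per module.
#' @param cluster_rm_min minimum relative magnitude across clusters.
#' @return `data.frame` with `module`, `cluster_rm`, `dataset_rm`,
#'   `passes_rm`, `cluster_dominant`, `kept`.
#' @export
select_modules <- function(summaries, cluster_rm_min = 3.7) {
  stopifnot(length(summaries) >= 1L)
  rows <- lapply(names(summaries), function(m) {
    s <- summaries[[m]]
    crm <- s$cluster$relative_magnitude
    drm <- s$dataset$relative_magnitude
    passes <- !is.na(crm) && crm >= cluster_rm_min
    dom <- !is.na(crm) && (is.na(drm) || crm > drm)
    data.frame(module = m, cluster_rm = crm, dataset_rm = drm,
               passes_rm = passes, cluster_dominant = dom,
               kept = passes && dom)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Digitize a module's per-cluster eigengene profile to {0, 0.5, 1}
#'
#' Each cluster mean is positioned on the min-max range of the module's
#' cluster means: level 0 below 33% of the magnitude, 0.5 within the closed
#' 33-67% band, 1 above 67%. A module whose magnitude is below `tol` is
#' degenerate and gets all-zero levels with a flag.
#'
#' @param summary an `eigengene_summary` (or its `$cluster` element).
#' @param tol magnitude below which the profile is flagged degenerate.
#' @return list with `levels` (named per-cluster vector in {0, 0.5, 1})
#'   and `degenerate` (logical).
#' @export
digitize <- function(summary, tol = 1e-9) {
  s <- if (inherits(summary, "eigengene_summary")) summary$cluster else summary
  means <- s$means
  magnitude <- max(means) - min(means)
  if (magnitude < tol) {
    return(list(levels = stats::setNames(rep(0, length(means)), names(means)),
                degenerate = TRUE))
  }
  p <- (means - min(means)) / magnitude
  lev <- ifelse(p < 1 / 3, 0, ifelse(p <= 2 / 3, 0.5, 1))
  list(levels = stats::setNames(as.numeric(lev), names(means)),
       degenerate = FALSE)
}

#' Signal width and uniqueness of digitized module profiles
#'
#' Signal width is the sum of a module's digitized levels across clusters
#' (a proxy for the number of clusters the module is active in);
#' uniqueness is `w_max - width`. By default `w_max` is the maximum
#' observed width; setting `w_max = 10` reproduces the convention of a
#' fixed 10-wide scale.
#'
#' @param profiles named list of [digitize()] results (or plain level
#'   vectors), one per module.
#' @param w_max subtrahend for uniqueness; `NULL` (default) uses the
#'   observed maximum width.
#' @return `data.frame` with `module`, `width`, `uniqueness`.
#' @export
width_uniqueness <- function(profiles, w_max = NULL) {
  lv <- lapply(profiles, function(p) if (is.list(p)) p$levels else p)
  width <- vapply(lv, sum, numeric(1))
  if (is.null(w_max)) w_max <- max(width)
  data.frame(module = names(lv), width = unname(width),
             uniqueness = unname(w_max - width), row.names = NULL)
}

#' Identity bar decomposition of cluster transcriptional identity
#'
#' For each (cluster, module) pair, the segment value is the number of
#' genes assigned to the module times the module's digitized level in that
#' cluster (0.5 or 1; level-0 modules contribute nothing). The per-cluster
#' total counts "efficient genes" building that cluster's identity.
#'
#' @param assignment result of [assign_genes()].
#' @param profiles named list of digitized profiles over the same modules.
#' @return `data.frame` with `cluster`, `module`, `n_genes`, `level`,
#'   `segment`, plus attribute `totals` (per-cluster sums).
#' @export
bar_decomposition <- function(assignment, profiles) {
  counts <- table(unlist(assignment$modules))
  mods <- names(profiles)
  miss <- setdiff(unique(names(counts)), mods)
  if (length(miss))
    stop_input("module(s) present in assignment but not in profiles: %s",
               paste(miss, collapse = ", "))
  lv <- lapply(profiles, function(p) if (is.list(p)) p$levels else p)
  clusters <- names(lv[[1]])
  out <- do.call(rbind, lapply(mods, function(m) {
    n <- if (m %in% names(counts)) as.integer(counts[[m]]) else 0L
    data.frame(cluster = clusters, module = m, n_genes = n,
               level = unname(lv[[m]][clusters]),
               segment = n * unname(lv[[m]][clusters]))
  }))
  rownames(out) <- NULL
  totals <- tapply(out$segment, out$cluster, sum)
  attr(out, "totals") <- totals
  out
}

#' Per-cell gene-set score with bin-matched controls
#'
#' The score of a cell is the mean expression of the set genes minus the
#' mean expression of control genes drawn from the same average-expression
#' bins: genes are cut into `n_bins` equal-frequency bins of their mean
#' expression across cells, and `n_ctrl` controls per set gene are sampled
#' with replacement from the corresponding bin. Deterministic given `seed`.
#'
#' @param expr genes x cells expression matrix with gene rownames.
#' @param gene_set character vector of set gene ids.
#' @param n_bins number of average-expression bins.
#' @param n_ctrl controls sampled per set gene.
#' @param seed integer seed for the control draw.
#' @return numeric per-cell score vector.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  stopifnot(is.matrix(expr))
  present <- intersect(gene_set, rownames(expr))
  if (!length(present))
    stop_input("no gene of the set is present in the expression matrix")
  n_bins <- min(n_bins, nrow(expr))
  avg <- rowMeans(expr)
  # equal-frequency bins; rank tie-break keeps the cut deterministic
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(expr) / n_bins))
  ctrl <- with_substream(seed, "module_score", {
    unlist(lapply(present, function(g) {
      pool <- which(bin == bin[match(g, rownames(expr))])
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  unname(set_mean - ctrl_mean)
}

#' Regulon dot-heatmap scores
#'
#' For each regulon (TF) across cell types: the dot size is the product of
#' the TF expression statistic and the region-set accessibility score, each
#' min-max scaled to \[0, 1\] across types; the dot color is the min-max
#' scaled target-gene-set score. Constant inputs scale to all zeros with a
#' warning.
#'
#' @param tf_stat,region_score,gene_score numeric vectors over the same
#'   cell types (named identically).
#' @return `data.frame` with `cell_type`, `size`, `color`.
#' @export
eregulon_dot <- function(tf_stat, region_score, gene_score) {
  n <- length(tf_stat)
  if (n < 2L) stop_input("need >= 2 cell types")
  if (length(region_score) != n || length(gene_score) != n)
    stop_input("all three vectors must cover the same cell types")
  types <- names(tf_stat)
  if (!is.null(types) &&
      (!identical(types, names(region_score)) ||
       !identical(types, names(gene_score))))
    stop_input("cell-type names disagree between inputs")
  if (is.null(types)) types <- paste0("t", seq_len(n))
  s_tf <- minmax_scale(tf_stat)
  s_rg <- minmax_scale(region_score)
  s_gn <- minmax_scale(gene_score)
  data.frame(cell_type = types, size = unname(s_tf * s_rg),
             color = unname(s_gn))
}
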