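# Synthetic data with planted ground truth: zonated clustered tissue point
# patterns, expression with planted co-expression modules, gene sets with
# controlled overlap, and multi-source label matrices with controlled
# concordance. Every downstream stage of the package is testable on these
# generators without any external download.

#' Configuration for a simulated ganglion section
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector (recycled) of cells per type.
#' @param boundary either a list `list(ngon = k, radius = r)` describing a
#'   regular k-gon of circumradius `r` micrometres centred at the origin,
#'   or an explicit vertex matrix of a convex polygon.
#' @param depth_quantile per-type target normalized edge depth in \[0, 1\]
#'   (0 = at the edge, 1 = centre).
#' @param depth_concentration concentration of the Beta distribution the
#'   per-cell depth is drawn from (larger = tighter zonation).
#' @param n_parents per-type number of cluster parents of the Thomas-type
#'   parent-offspring process.
#' @param dispersion_sd per-type offspring dispersion (micrometres, >= 0).
#' @param volume_meanlog,volume_sdlog per-type lognormal volume parameters.
#' @param section_id section identifier written into the cell table.
#' @return a `ganglion_config` list, validated.
#' @export
ganglion_config <- function(n_types = 3L,
                            cells_per_type = 500L,
                            boundary = list(ngon = 64L, radius = 500),
                            depth_quantile = seq(0.15, 0.85,
                                                 length.out = n_types),
                            depth_concentration = 20,
                            n_parents = 15L,
                            dispersion_sd = 25,
                            volume_meanlog = log(1000),
                            volume_sdlog = 0.25,
                            section_id = "S1") {
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = rep_len(as.integer(cells_per_type), n_types),
              boundary = boundary,
              depth_quantile = rep_len(depth_quantile, n_types),
              depth_concentration = depth_concentration,
              n_parents = rep_len(as.integer(n_parents), n_types),
              dispersion_sd = rep_len(dispersion_sd, n_types),
              volume_meanlog = rep_len(volume_meanlog, n_types),
              volume_sdlog = rep_len(volume_sdlog, n_types),
              section_id = section_id)
  if (cfg$n_types < 1L) stop_input("n_types must be >= 1")
  if (any(cfg$cells_per_type < 1L)) stop_input("cells_per_type must be >= 1")
  if (any(cfg$depth_quantile < 0 | cfg$depth_quantile > 1))
    stop_input("depth_quantile must lie in [0, 1]")
  if (any(cfg$dispersion_sd < 0)) stop_input("dispersion_sd must be >= 0")
  if (any(cfg$n_parents < 1L)) stop_input("n_parents must be >= 1")
  class(cfg) <- "ganglion_config"
  cfg
}

boundary_from_spec <- function(boundary) {
  if (is.list(boundary) && !is.null(boundary$ngon)) {
    k <- as.integer(boundary$ngon)
    if (k < 3L) stop_input("regular polygon needs >= 3 vertices, got %d", k)
    ang <- 2 * pi * (seq_len(k) - 1) / k
    as_boundary_polygon(cbind(boundary$radius * cos(ang),
                              boundary$radius * sin(ang)))
  } else {
    as_boundary_polygon(boundary)  # validates convexity, >= 3 vertices
  }
}

#' Simulate a zonated, clustered ganglion section
#'
#' Cells of each type are placed by a Thomas-type parent-offspring process
#' inside a convex tissue outline. Parent points sit at a radial position
#' whose normalized edge depth is Beta-distributed around the type's
#' `depth_quantile`; offspring scatter isotropically around their parent
#' with the configured dispersion and are resampled until inside the
#' boundary. Per-cell volumes are lognormal per type.
#'
#' @param cfg a [ganglion_config()].
#' @param seed integer seed; identical config + seed gives identical output.
#' @return list with `cells` (a cell-table `data.frame`), `boundary`
#'   (a `boundary_polygon`) and `truth` (planted depth quantiles and the
#'   implied peripheral-to-central type ordering).
#' @export
simulate_ganglion <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ganglion_config"))
  boundary <- boundary_from_spec(cfg$boundary)
  centre <- colMeans(boundary)
  cells <- with_substream(seed, "ganglion", {
    do.call(rbind, lapply(seq_len(cfg$n_types), function(tp) {
      n <- cfg$cells_per_type[tp]
      parents <- sample_zonated_points(cfg$n_parents[tp], boundary, centre,
                                       cfg$depth_quantile[tp],
                                       cfg$depth_concentration)
      assign_to <- sample(nrow(parents), n, replace = TRUE)
      pts <- matrix(NA_real_, n, 2)
      sd <- cfg$dispersion_sd[tp]
      todo <- seq_len(n)
      iter <- 0L
      while (length(todo)) {
        prop <- parents[assign_to[todo], , drop = FALSE] +
          matrix(stats::rnorm(2 * length(todo), 0, sd), ncol = 2)
        ok <- point_in_polygon(prop, boundary)
        pts[todo[ok], ] <- prop[ok, , drop = FALSE]
        todo <- todo[!ok]
        iter <- iter + 1L
        if (sd == 0 || iter > 1000L) {
          # degenerate dispersion (or pathological config): fall back to
          # the parent location, which is inside by construction
          pts[todo, ] <- parents[assign_to[todo], , drop = FALSE]
          break
        }
      }
      vol <- stats::rlnorm(n, cfg$volume_meanlog[tp], cfg$volume_sdlog[tp])
      data.frame(x_um = pts[, 1], y_um = pts[, 2], volume = vol,
                 cell_type = sprintf("type%02d", tp))
    }))
  })
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(nrow(cells))),
                      section_id = cfg$section_id, cells,
                      stringsAsFactors = FALSE)
  truth <- list(
    depth_quantile = stats::setNames(cfg$depth_quantile,
                                     sprintf("type%02d", seq_len(cfg$n_types))),
    depth_order = sprintf("type%02d", order(cfg$depth_quantile)))
  list(cells = cells, boundary = boundary, truth = truth)
}

# Place points at Beta(q * c, (1 - q) * c)-distributed normalized depth
# along uniformly random rays from the polygon centre to the boundary.
sample_zonated_points <- function(n, boundary, centre, q, concentration) {
  a <- max(q * concentration, 1e-6)
  b <- max((1 - q) * concentration, 1e-6)
  depth <- stats::rbeta(n, a, b)
  theta <- stats::runif(n, 0, 2 * pi)
  ray <- ray_length(theta, boundary, centre)
  cbind(centre[1] + (1 - depth) * ray * cos(theta),
        centre[2] + (1 - depth) * ray * sin(theta))
}

# Distance from the centre to the boundary along direction theta.
ray_length <- function(theta, boundary, centre) {
  n <- nrow(boundary)
  j <- c(2:n, 1)
  ax <- boundary[, 1] - centre[1]; ay <- boundary[, 2] - centre[2]
  bx <- boundary[j, 1] - centre[1]; by <- boundary[j, 2] - centre[2]
  vapply(theta, function(th) {
    dx <- cos(th); dy <- sin(th)
    ex <- bx - ax; ey <- by - ay
    den <- dx * ey - dy * ex
    t <- (ax * ey - ay * ex) / den
    u <- (ay * dx - ax * dy) / (-den)
    t[!(is.finite(t) & t > 0 & u >= -1e-12 & u <= 1 + 1e-12)] <- Inf
    out <- min(t)
    if (!is.finite(out)) stop_input("ray-boundary intersection failed")
    out
  }, numeric(1))
}

#' Configuration for simulated expression with planted modules
#'
#' @param n_genes,n_cells,n_clusters,n_datasets dimensions of the matrix and
#'   its annotations.
#' @param modules list of module specs, each
#'   `list(n_genes =, levels =, loading = 1)` where `levels` is a
#'   per-cluster activity vector with values in {0, 0.5, 1}.
#' @param noise_sd i.i.d. Gaussian noise SD (expression units).
#' @param batch_shift_sd SD of per-(gene, dataset) additive batch shifts.
#' @return an `expression_config` list, validated.
#' @export
expression_config <- function(n_genes = 200L, n_cells = 400L,
                              n_clusters = 4L, n_datasets = 2L,
                              modules = list(), noise_sd = 0.2,
                              batch_shift_sd = 0) {
  for (m in modules) {
    stopifnot(!is.null(m$n_genes), !is.null(m$levels))
    if (!all(m$levels %in% c(0, 0.5, 1)))
      stop_input("planted module levels must be in {0, 0.5, 1}")
    if (length(m$levels) != n_clusters)
      stop_input("module levels must have one entry per cluster")
  }
  if (sum(vapply(modules, function(m) m$n_genes, numeric(1))) > n_genes)
    stop_input("module gene counts exceed n_genes")
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_clusters = as.integer(n_clusters),
              n_datasets = as.integer(n_datasets),
              modules = modules, noise_sd = noise_sd,
              batch_shift_sd = batch_shift_sd)
  class(cfg) <- "expression_config"
  cfg
}

#' Simulate expression with planted co-expression modules
#'
#' Genes of each planted module take value
#' `loading x level(cluster of the cell)` plus a per-(gene, dataset) batch
#' shift and i.i.d. Gaussian noise; background genes are pure noise. The
#' returned kME table is the Pearson correlation of every gene with each
#' module's eigengene (computed from the planted memberships by
#' [compute_eigengene()]), emulating the module-connectivity table a
#' co-expression pipeline would hand downstream.
#'
#' @param cfg an [expression_config()].
#' @param seed integer seed.
#' @return list with `expr` (genes x cells matrix), `cells` (annotation
#'   `data.frame` with `cell_id`, `cluster`, `dataset`), `kme` (genes x
#'   modules matrix) and `truth` (planted memberships and level profiles).
#' @export
simulate_expression <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "expression_config"))
  with_substream(seed, "expression", {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    cells <- sprintf("c%05d", seq_len(cfg$n_cells))
    cluster <- sprintf("cl%02d",
                       rep_len(seq_len(cfg$n_clusters), cfg$n_cells))
    dataset <- sprintf("ds%d",
                       rep_len(rep(seq_len(cfg$n_datasets),
                                   each = cfg$n_clusters), cfg$n_cells))
    expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cells, 0, cfg$noise_sd),
                   cfg$n_genes, cfg$n_cells, dimnames = list(genes, cells))
    membership <- list()
    level_truth <- list()
    next_gene <- 1L
    for (mi in seq_along(cfg$modules)) {
      m <- cfg$modules[[mi]]
      idx <- next_gene:(next_gene + m$n_genes - 1L)
      next_gene <- next_gene + m$n_genes
      loading <- if (is.null(m$loading)) 1 else m$loading
      lev <- m$levels[match(cluster, sprintf("cl%02d", seq_len(cfg$n_clusters)))]
      expr[idx, ] <- expr[idx, ] + loading * rep(lev, each = length(idx))
      name <- sprintf("M%d", mi)
      membership[[name]] <- genes[idx]
      level_truth[[name]] <- stats::setNames(
        m$levels, sprintf("cl%02d", seq_len(cfg$n_clusters)))
    }
    if (cfg$batch_shift_sd > 0) {
      for (d in unique(dataset)) {
        shift <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
        expr[, dataset == d] <- expr[, dataset == d] + shift
      }
    }
    cells_df <- data.frame(cell_id = cells, cluster = cluster,
                           dataset = dataset, stringsAsFactors = FALSE)
    kme <- kme_table(expr, membership)
    list(expr = expr, cells = cells_df, kme = kme,
         truth = list(membership = membership, levels = level_truth))
  })
}

#' kME table: correlation of each gene with each module eigengene
#'
#' @param expr genes x cells expression matrix.
#' @param membership named list of module gene-id vectors.
#' @return genes x modules matrix of Pearson correlations.
#' @export
kme_table <- function(expr, membership) {
  stopifnot(is.matrix(expr), length(membership) >= 1L)
  eig <- vapply(membership, function(g) compute_eigengene(expr, g),
                numeric(ncol(expr)))
  ok <- apply(expr, 1L, stats::sd) > 0
  kme <- matrix(0, nrow(expr), length(membership),
                dimnames = list(rownames(expr), names(membership)))
  kme[ok, ] <- stats::cor(t(expr[ok, , drop = FALSE]), eig)
  kme
}

#' Simulate gene-set collections with controlled overlap to planted modules
#'
#' Builds "regulon" gene sets whose intersection with specified planted
#' modules is exact: the specified number of member genes is sampled from
#' the module, and the remainder from the universe excluding every module
#' mentioned in the spec for that regulon (so realized overlaps with
#' specified modules equal the specification exactly; unspecified pairs
#' overlap only by chance).
#'
#' @param module_truth named list of module gene-id vectors (as in the
#'   `truth$membership` of [simulate_expression()]).
#' @param universe character vector of all gene ids.
#' @param regulon_sizes named integer vector: size of each regulon.
#' @param overlap_spec `data.frame` with columns `module`, `regulon`,
#'   `overlap` (may be empty for a fully null collection).
#' @param seed integer seed.
#' @return list with `regulons` (named list of gene-id vectors) and `truth`
#'   (the realized overlap specification).
#' @export
simulate_regulons <- function(module_truth, universe, regulon_sizes,
                              overlap_spec = NULL, seed = 1L) {
  if (is.null(overlap_spec))
    overlap_spec <- data.frame(module = character(), regulon = character(),
                               overlap = integer())
  stopifnot(all(c("module", "regulon", "overlap") %in% names(overlap_spec)))
  if (any(!overlap_spec$module %in% names(module_truth)))
    stop_input("overlap_spec names unknown module(s)")
  with_substream(seed, "regulons", {
    regulons <- lapply(names(regulon_sizes), function(r) {
      size <- regulon_sizes[[r]]
      spec <- overlap_spec[overlap_spec$regulon == r, , drop = FALSE]
      picked <- character(0)
      for (i in seq_len(nrow(spec))) {
        mg <- module_truth[[spec$module[i]]]
        k <- spec$overlap[i]
        if (k > min(length(mg), size))
          stop_input("requested overlap %d exceeds min(set sizes) for %s/%s",
                     k, spec$module[i], r)
        picked <- c(picked, sample(mg, k))
      }
      if (length(picked) > size)
        stop_input("overlap_spec for regulon %s exceeds its size", r)
      excl <- unique(unlist(module_truth[spec$module]))
      pool <- setdiff(universe, union(excl, picked))
      c(picked, sample(pool, size - length(picked)))
    })
    names(regulons) <- names(regulon_sizes)
    list(regulons = regulons,
         truth = list(overlap_spec = overlap_spec))
  })
}

#' Simulate a multi-source label matrix with controlled concordance
#'
#' Each cell has one true label; every source independently reports the
#' true label with probability `concordance` and otherwise a uniformly
#' random other label. The ground truth records which cells are fully
#' concordant across sources, counting agreement within a declared exempt
#' family (labels treated as one group) as concordance.
#'
#' @param n_cells number of cells.
#' @param sources character vector of source names (>= 2).
#' @param labels label vocabulary.
#' @param concordance per-source probability of reporting the true label.
#' @param exempt_families named list of label vectors; all-source assignment
#'   inside one family counts as concordant.
#' @param seed integer seed.
#' @return list with `label_matrix` (`data.frame`: `cell_id` plus one
#'   column per source), `truth` (`true_label`, `concordant` cell ids).
#' @export
simulate_label_matrix <- function(n_cells, sources, labels,
                                  concordance = 0.9,
                                  exempt_families = list(), seed = 1L) {
  if (length(sources) < 2L) stop_input("need >= 2 sources")
  if (concordance < 0 || concordance > 1)
    stop_input("concordance must lie in [0, 1]")
  with_substream(seed, "labels", {
    ids <- sprintf("cell%05d", seq_len(n_cells))
    true_label <- sample(labels, n_cells, replace = TRUE)
    mat <- vapply(sources, function(s) {
      hit <- stats::runif(n_cells) < concordance
      out <- true_label
      miss <- which(!hit)
      for (i in miss) out[i] <- sample(setdiff(labels, true_label[i]), 1L)
      out
    }, character(n_cells))
    lm <- data.frame(cell_id = ids, mat, stringsAsFactors = FALSE,
                     check.names = FALSE)
    concordant <- ids[apply(mat, 1L, function(r)
      all_concordant(r, exempt_families))]
    list(label_matrix = lm,
         truth = list(true_label = stats::setNames(true_label, ids),
                      concordant = concordant))
  })
}

all_concordant <- function(lab, exempt_families) {
  if (any(lab == "unassigned")) return(FALSE)
  if (length(unique(lab)) == 1L) return(TRUE)
  for (fam in exempt_families) if (all(lab %in% fam)) return(TRUE)
  FALSE
}
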