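# Readers and writers for the external formats the pipeline consumes and
# produces: cell-table CSV, expression MTX (+ genes.tsv/cells.tsv) or dense
# CSV, GMT gene sets, GeoJSON boundary polygons, label CSV, homology-map
# JSON, Newick dendrograms, and run manifests.

#' Read a cell table from CSV
#'
#' Expects columns `cell_id`, `section_id`, `x_um`, `y_um`, `volume`,
#' `cell_type`. Coordinates are parsed as micrometre floats. Tolerates
#' Windows line endings and quoted labels.
#'
#' @param path CSV file path.
#' @return cell-table `data.frame`.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "section_id", "x_um", "y_um", "volume", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("cell CSV missing column(s): %s", paste(miss, collapse = ", "))
  for (col in c("x_um", "y_um", "volume")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]]))
      stop_input("non-numeric values in column '%s'", col)
    df[[col]] <- v
  }
  dup <- stats::aggregate(seq_len(nrow(df)),
                          by = list(df$section_id, df$cell_id), length)
  if (any(dup$x > 1L))
    stop_input("duplicate cell_id within a section: %s",
               paste(utils::head(dup[dup$x > 1L, 2L], 5L), collapse = ", "))
  df[need]
}

#' Write a cell table to CSV
#' @param cells cell-table `data.frame`.
#' @param path output path.
#' @export
write_cells <- function(cells, path) {
  check_cell_table(cells)
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix (Matrix Market or dense CSV)
#'
#' For `format = "mtx"`, `path` is the `.mtx` file and `genes`/`cells` are
#' the accompanying TSVs; the cells TSV must carry `cell_id` and may carry
#' `cluster` and `dataset` columns. One-based MTX indices are handled by
#' the Matrix package. For `format = "csv"`, a dense genes x cells CSV
#' with gene rownames in the first column.
#'
#' @param path matrix file path.
#' @param genes,cells annotation TSV paths (MTX only).
#' @param format `"mtx"` or `"csv"` (guessed from the extension).
#' @return list with `expr` (dense genes x cells matrix) and `cells`
#'   (annotation `data.frame`, NULL for CSV input).
#' @export
read_expression <- function(path, genes = NULL, cells = NULL,
                            format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    return(list(expr = as.matrix(df), cells = NULL))
  }
  m <- as.matrix(Matrix::readMM(path))
  gtab <- utils::read.delim(genes, stringsAsFactors = FALSE)
  ctab <- utils::read.delim(cells, stringsAsFactors = FALSE)
  if (nrow(gtab) != nrow(m))
    stop_input("MTX header says %d genes but genes TSV has %d rows",
               nrow(m), nrow(gtab))
  if (nrow(ctab) != ncol(m))
    stop_input("MTX header says %d cells but cells TSV has %d rows",
               ncol(m), nrow(ctab))
  rownames(m) <- gtab[[1L]]
  colnames(m) <- ctab[[1L]]
  list(expr = m, cells = ctab)
}

#' Write an expression matrix as Matrix Market plus annotation TSVs
#'
#' @param expr genes x cells matrix.
#' @param cells annotation `data.frame` (first column `cell_id`).
#' @param prefix output path prefix: writes `<prefix>.mtx`,
#'   `<prefix>.genes.tsv`, `<prefix>.cells.tsv`.
#' @export
write_expression <- function(expr, cells, prefix) {
  stopifnot(is.matrix(expr), nrow(cells) == ncol(expr))
  Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  utils::write.table(data.frame(gene = rownames(expr)),
                     paste0(prefix, ".genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cells, paste0(prefix, ".cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate members within a set are collapsed with a
#' warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop_input("duplicate gene-set name(s): %s",
               paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members collapsed in set '%s'", p[1L]))
      members <- unique(members)
    }
    members
  })
  names(sets) <- names_
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a boundary polygon as GeoJSON
#' @param polygon a `boundary_polygon`.
#' @param path file path.
#' @return `write_boundary_geojson`: the path, invisibly;
#'   `read_boundary_geojson`: a `boundary_polygon`.
#' @export
write_boundary_geojson <- function(polygon, path) {
  ring <- rbind(unclass(polygon), unclass(polygon)[1, ])  # closed ring
  gj <- list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)), function(i)
               c(ring[i, 1], ring[i, 2]))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundary_geojson
#' @export
read_boundary_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "Polygon"))
    stop_input("GeoJSON geometry must be a Polygon, got '%s'", gj$type)
  ring <- do.call(rbind, lapply(gj$coordinates[[1]], unlist))
  as_boundary_polygon(ring)
}

#' Read a homology map from JSON
#'
#' JSON object with one key per source, each an object mapping source
#' labels to harmonized labels; an optional `"_exempt_families"` key maps
#' family names to label arrays.
#'
#' @param path JSON file path.
#' @return list with `map` (per-source named vectors) and
#'   `exempt_families`.
#' @export
read_homology_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fam <- j[["_exempt_families"]]
  j[["_exempt_families"]] <- NULL
  list(map = lapply(j, unlist), exempt_families = lapply(fam, unlist))
}

#' Write a type dendrogram as Newick
#' @param hc an `hclust` from [cluster_type_matrix()].
#' @param path output path.
#' @export
write_type_tree <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Run manifest for reproducibility bookkeeping
#'
#' Records the package version, seed, a stable hash of the configuration,
#' input file checksums and per-stage row counts; attach or write next to
#' any pipeline output so a run can be reproduced exactly.
#'
#' @param seed the seed in effect.
#' @param config a (nested) list of stage parameters.
#' @param inputs named character vector of input file paths (checksummed).
#' @param counts named integer vector of per-stage row counts.
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(seed, config = list(), inputs = character(0),
                         counts = integer(0)) {
  csum <- vapply(inputs, function(p)
    as.character(tools::md5sum(p)), character(1))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (ch in utf8ToInt(as.character(cfg_json)))
    h <- (h * 31 + ch) %% 2147483647
  structure(list(package = "gangliostat",
                 version = as.character(utils::packageVersion("gangliostat")),
                 seed = seed, config_hash = h, config = config,
                 input_md5 = csum, counts = counts),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
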