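# Independent oracles the tests check the implementation against. These are
# deliberately naive (nested loops, dense sampling, exhaustive enumeration)
# and share no code with the package internals.

# Nested-loop volume-normalized type-distance oracle.
oracle_type_distance <- function(cells) {
  n <- nrow(cells)
  types <- sort(unique(cells$cell_type))
  k <- length(types)
  dn <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
              (cells$y_um[i] - cells$y_um[j])^2)
    dn[i, j] <- d / ((cells$volume[i] + cells$volume[j]) / 2)
  }
  out <- matrix(NA_real_, k, k, dimnames = list(types, types))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ia <- which(cells$cell_type == types[a])
    ib <- which(cells$cell_type == types[b])
    vals <- c()
    for (i in ia) for (j in ib) if (i != j) vals <- c(vals, dn[i, j])
    if (length(vals)) out[a, b] <- mean(vals)
  }
  out
}

# Dense boundary-sampling oracle for point-to-polygon-edge distance.
oracle_edge_distance <- function(point, verts, n_samples = 1e6) {
  v <- rbind(verts, verts[1, ])
  seg_len <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], length.out = n_samples)
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[seg]) / seg_len[seg]
  bx <- v[seg, 1] + t * (v[seg + 1, 1] - v[seg, 1])
  by <- v[seg, 2] + t * (v[seg + 1, 2] - v[seg, 2])
  min(sqrt((bx - point[1])^2 + (by - point[2])^2))
}

# Step-by-step average-linkage agglomeration oracle.
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  heights <- numeric(0)
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(NA, NA); besth <- Inf
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      h <- mean(d[active[[a]], active[[b]]])
      if (h < besth) { besth <- h; best <- c(a, b) }
    }
    heights <- c(heights, besth)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  heights
}

# Independent two-pass redundant gene-to-module assignment.
oracle_assign <- function(kme, r_min = 0.3, frac = 0.95) {
  lapply(seq_len(nrow(kme)), function(i) {
    row <- kme[i, ]
    rmax <- max(row)
    if (rmax < r_min) return(character(0))
    first <- colnames(kme)[which.max(row)]
    extra <- colnames(kme)[row >= frac * rmax & row >= r_min]
    union(first, extra)
  })
}

# Exhaustive hypergeometric upper-tail p via choose().
oracle_hyper_tail <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# A small deterministic random cell table.
random_cells <- function(n, n_types = 3, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)), section_id = "S1",
             x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
             volume = runif(n, 0.5, 5),
             cell_type = sample(LETTERS[seq_len(n_types)], n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# A random convex polygon (hull of random points).
random_convex_polygon <- function(n_pts = 20, seed = 1) {
  set.seed(seed)
  build_boundary(cbind(runif(n_pts, 0, 100), runif(n_pts, 0, 100)))
}
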