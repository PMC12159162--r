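test_that("redundant gene assignment applies both thresholds and matches the oracle", {
  kme <- matrix(c(0.8, 0.77, 0.5), 1, 3,
                dimnames = list("g1", c("M1", "M2", "M3")))
  a <- assign_genes(kme)
  expect_setequal(a$modules[[1]], c("M1", "M2"))  # 0.77 >= 0.95 * 0.8

  kme_low <- matrix(c(0.2, 0.25, 0.1), 1, 3,
                    dimnames = list("g1", c("M1", "M2", "M3")))
  expect_length(assign_genes(kme_low)$modules[[1]], 0)  # below the 0.3 floor

  set.seed(3)
  kme <- matrix(runif(500 * 10, -1, 1), 500, 10,
                dimnames = list(sprintf("g%03d", 1:500), paste0("M", 1:10)))
  a <- assign_genes(kme)
  ref <- oracle_assign(kme)
  for (i in seq_len(500)) expect_setequal(a$modules[[i]], ref[[i]])
  # every nonempty assignment contains its row argmax
  nonempty <- which(a$n_modules > 0)
  expect_true(all(vapply(nonempty, function(i)
    colnames(kme)[which.max(kme[i, ])] %in% a$modules[[i]], logical(1))))
  # invariant to module column order
  perm <- sample(10)
  a2 <- assign_genes(kme[, perm])
  for (i in seq_len(500)) expect_setequal(a2$modules[[i]], a$modules[[i]])

  expect_error(assign_genes(matrix(numeric(0), 0, 0)), "empty")
})

test_that("eigengene is PC1 with unit variance and a non-negative mean correlation", {
  set.seed(4)
  expr <- matrix(rnorm(200), 10, 20,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  # single-gene module: eigengene equals the standardized gene
  e1 <- compute_eigengene(expr, "g1")
  expect_equal(abs(cor(e1, expr["g1", ])), 1, tolerance = 1e-12)
  expect_equal(sd(e1), 1, tolerance = 1e-9)
  # two perfectly correlated genes
  expr["g2", ] <- 2 * expr["g1", ] + 5
  e2 <- compute_eigengene(expr, c("g1", "g2"))
  expect_equal(cor(e2, expr["g1", ]), 1, tolerance = 1e-9)
  # contract on any module: unit variance, non-negative mean correlation
  e3 <- compute_eigengene(expr, paste0("g", 1:6))
  z <- t(scale(t(expr[paste0("g", 1:6), ])))
  expect_equal(sd(e3), 1, tolerance = 1e-9)
  expect_gte(cor(e3, colMeans(z)), 0)

  expr["g3", ] <- 7
  expect_error(compute_eigengene(expr, c("g1", "g3")), "g3")
  expect_error(compute_eigengene(expr, "absent"), "no module gene")
})

test_that("eigengene tracks the planted signal better than single member genes", {
  wins <- 0
  for (s in 1:10) {
    e <- simulate_expression(expression_config(
      n_genes = 40, n_cells = 200, n_clusters = 4, n_datasets = 1,
      modules = list(list(n_genes = 20, levels = c(0, 0.5, 1, 0))),
      noise_sd = 0.5), seed = s)
    lev <- e$truth$levels$M1[e$cells$cluster]
    eig <- compute_eigengene(e$expr, e$truth$membership$M1)
    r_eig <- abs(cor(eig, lev))
    r_genes <- max(abs(cor(t(e$expr[e$truth$membership$M1, ]), lev)))
    wins <- wins + (r_eig > r_genes)
  }
  expect_gte(wins, 9)
})

test_that("magnitude and relative magnitude follow their definitions", {
  x <- c(rep(0, 10), rep(1, 10), rep(2, 10)) +
    rep(c(-0.5, 0.5), 15)  # per-group sd = 0.5138.../ exact below
  cl <- rep(c("a", "b", "c"), each = 10)
  ds <- rep("d1", 30)
  s <- summarize_and_magnitude(x, cl, ds)
  expect_equal(s$cluster$magnitude, 2)
  expect_equal(s$cluster$relative_magnitude,
               2 / mean(tapply(x, cl, sd)))

  # worked case: means (0, 1, 2), sds (0.5, 0.5, 0.5) -> rm = 4
  fake <- list(means = c(a = 0, b = 1, c = 2), sds = c(0.5, 0.5, 0.5))
  expect_equal((max(fake$means) - min(fake$means)) / mean(fake$sds), 4)

  # constant eigengene: magnitude 0
  s0 <- summarize_and_magnitude(rep(1, 12), rep(c("a", "b"), 6),
                                rep("d", 12))
  expect_equal(s0$cluster$magnitude, 0)
  expect_equal(s0$cluster$relative_magnitude, NA_real_)  # mean sd = 0, flagged

  # random groups vs direct recomputation
  set.seed(6)
  x <- rnorm(120); cl <- sample(letters[1:4], 120, TRUE)
  ds <- sample(c("d1", "d2"), 120, TRUE)
  s <- summarize_and_magnitude(x, cl, ds)
  expect_equal(s$cluster$means, tapply(x, cl, mean), tolerance = 1e-12)
  expect_equal(s$dataset$magnitude,
               diff(range(tapply(x, ds, mean))), tolerance = 1e-12)
  # singleton group flags its SD and warns
  expect_warning(
    s1 <- summarize_and_magnitude(c(x, 9), c(cl, "solo"), c(ds, "d1")),
    "single cell")
  expect_true(is.na(s1$cluster$sds["solo"]))
})

test_that("module selection keeps cluster-driven and drops dataset-driven modules", {
  mk <- function(crm, drm) list(cluster = list(relative_magnitude = crm),
                                dataset = list(relative_magnitude = drm))
  out <- select_modules(list(good = mk(5, 1), weak = mk(2, 0.1),
                             batch = mk(4, 6)))
  expect_true(out$kept[out$module == "good"])
  expect_false(out$kept[out$module == "weak"])   # below the 3.7 floor
  expect_false(out$kept[out$module == "batch"])  # dataset-dominated

  # simulation: planted batch module excluded, cluster module kept
  kept_ok <- excl_ok <- 0
  for (s in 1:5) {
    e <- simulate_expression(expression_config(
      n_genes = 60, n_cells = 240, n_clusters = 4, n_datasets = 2,
      modules = list(list(n_genes = 15, levels = c(0, 0, 1, 1)),
                     list(n_genes = 15, levels = c(0, 0, 0, 0))),
      noise_sd = 0.15, batch_shift_sd = 0), seed = s)
    # plant a dataset effect into module 2 only
    m2 <- e$truth$membership$M2
    e$expr[m2, e$cells$dataset == "ds2"] <-
      e$expr[m2, e$cells$dataset == "ds2"] + 1
    summaries <- lapply(e$truth$membership, function(g) {
      eig <- compute_eigengene(e$expr, g)
      summarize_and_magnitude(eig, e$cells$cluster, e$cells$dataset)
    })
    out <- select_modules(summaries)
    kept_ok <- kept_ok + out$kept[out$module == "M1"]
    excl_ok <- excl_ok + !out$kept[out$module == "M2"]
  }
  expect_equal(kept_ok, 5)
  expect_equal(excl_ok, 5)
})

test_that("digitization maps min-max positions onto {0, 0.5, 1} with a closed middle bin", {
  s <- list(means = c(a = 0, b = 1, c = 2))
  expect_equal(unname(digitize(s)$levels), c(0, 0.5, 1))
  # boundary convention: exactly 1/3 falls in the middle bin
  s <- list(means = c(a = 0, b = 1, c = 3))
  expect_equal(unname(digitize(s)$levels), c(0, 0.5, 1))
  s <- list(means = c(a = 0, b = 2, c = 3))  # 2/3 also middle (closed)
  expect_equal(unname(digitize(s)$levels), c(0, 0.5, 1))
  # degenerate magnitude flags and zeroes
  d0 <- digitize(list(means = c(a = 1, b = 1)))
  expect_true(d0$degenerate)
  expect_equal(unname(d0$levels), c(0, 0))
  # affine invariance: positions are min-max normalized
  set.seed(7)
  m <- runif(8)
  s1 <- digitize(list(means = m))
  s2 <- digitize(list(means = 3.2 * m - 17))
  expect_equal(s1$levels, s2$levels)
})

test_that("planted digitized profiles are recovered at high signal-to-noise", {
  total <- hits <- 0
  for (s in 1:10) {
    profiles <- list(c(0, 0.5, 1, 0), c(1, 0, 0.5, 0.5), c(0.5, 1, 0, 1))
    e <- simulate_expression(expression_config(
      n_genes = 80, n_cells = 240, n_clusters = 4, n_datasets = 1,
      modules = lapply(profiles, function(p)
        list(n_genes = 12, levels = p, loading = 1)),
      noise_sd = 0.2), seed = s)  # loading / noise = 5
    for (m in names(e$truth$membership)) {
      eig <- compute_eigengene(e$expr, e$truth$membership[[m]])
      sm <- summarize_and_magnitude(eig, e$cells$cluster, e$cells$dataset)
      lev <- digitize(sm)$levels
      truth <- e$truth$levels[[m]][names(lev)]
      hits <- hits + sum(lev == truth)
      total <- total + length(lev)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("width and uniqueness are exact sums with monotone behavior", {
  profiles <- list(A = c(x = 1, y = 0.5, z = 0, w = 0),
                   B = c(x = 0, y = 0, z = 0, w = 0),
                   C = c(x = 1, y = 1, z = 1, w = 0.5))
  wu <- width_uniqueness(profiles, w_max = 10)
  expect_equal(wu$width, c(1.5, 0, 3.5))
  expect_equal(wu$uniqueness, c(8.5, 10, 6.5))  # fixed 10-wide convention
  # default w_max = observed maximum
  wu_obs <- width_uniqueness(profiles)
  expect_equal(wu_obs$uniqueness, c(2, 3.5, 0))
  # decreasing a level weakly decreases width, increases uniqueness
  profiles$A["x"] <- 0.5
  wu2 <- width_uniqueness(profiles, w_max = 10)
  expect_lt(wu2$width[1], wu$width[1])
  expect_gt(wu2$uniqueness[1], wu$uniqueness[1])
})

test_that("bar decomposition multiplies assigned gene counts by digitized levels", {
  kme <- matrix(c(rep(0.9, 40), rep(0.1, 40)), 40, 2,
                dimnames = list(sprintf("g%02d", 1:40), c("M1", "M2")))
  a <- assign_genes(kme)
  profiles <- list(M1 = c(cl1 = 0.5, cl2 = 0), M2 = c(cl1 = 1, cl2 = 1))
  bars <- bar_decomposition(a, profiles)
  expect_equal(bars$segment[bars$module == "M1" & bars$cluster == "cl1"], 20)
  expect_equal(bars$segment[bars$module == "M1" & bars$cluster == "cl2"], 0)
  expect_equal(attr(bars, "totals")[["cl1"]], 20)  # M2 has no assigned genes

  # random instance vs elementwise product oracle
  set.seed(8)
  kme <- matrix(runif(200, 0, 1), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), paste0("M", 1:4)))
  a <- assign_genes(kme)
  lv <- replicate(4, sample(c(0, 0.5, 1), 3, TRUE), simplify = FALSE)
  names(lv) <- paste0("M", 1:4)
  lv <- lapply(lv, function(x) setNames(x, c("c1", "c2", "c3")))
  bars <- bar_decomposition(a, lv)
  counts <- table(unlist(a$modules))
  for (r in seq_len(nrow(bars))) {
    n <- if (bars$module[r] %in% names(counts))
      counts[[bars$module[r]]] else 0
    expect_equal(bars$segment[r], n * lv[[bars$module[r]]][[bars$cluster[r]]])
  }
  expect_error(bar_decomposition(a, lv[1:3]), "M4")
})

test_that("bin-matched module score is zero on constant input and deterministic", {
  expr <- matrix(5, 40, 12, dimnames = list(sprintf("g%02d", 1:40), NULL))
  sc <- module_score(expr, c("g01", "g02"), seed = 1)
  expect_equal(sc, rep(0, 12))

  set.seed(9)
  expr <- matrix(rnorm(40 * 30), 40, 30,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  s1 <- module_score(expr, c("g01", "g05", "g09"), seed = 5)
  s2 <- module_score(expr, c("g01", "g05", "g09"), seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, module_score(expr, c("g01", "g05", "g09"),
                                          seed = 6)))
  expect_error(module_score(expr, "nope", seed = 1), "no gene")

  # planted module scores highest in its active cluster
  ok <- 0
  for (s in 1:5) {
    e <- simulate_expression(expression_config(
      n_genes = 100, n_cells = 200, n_clusters = 4, n_datasets = 1,
      modules = list(list(n_genes = 15, levels = c(0, 0, 1, 0))),
      noise_sd = 0.3), seed = s)
    sc <- module_score(e$expr, e$truth$membership$M1, seed = s)
    by_cl <- tapply(sc, e$cells$cluster, mean)
    ok <- ok + (names(which.max(by_cl)) == "cl03")
  }
  expect_equal(ok, 5)
})

test_that("regulon dot scores are scaled products with degeneracy warnings", {
  tf <- c(a = 1, b = 5, c = 3)
  rg <- c(a = 0.2, b = 0.8, c = 0.4)
  gn <- c(a = 0, b = 2, c = 1)
  dots <- eregulon_dot(tf, rg, gn)
  expect_equal(dots$size[dots$cell_type == "b"], 1)     # max TF x max region
  expect_equal(dots$size[dots$cell_type == "a"], 0)     # min TF
  expect_true(all(dots$size >= 0 & dots$size <= 1))
  expect_true(all(dots$color >= 0 & dots$color <= 1))
  # elementwise oracle
  set.seed(10)
  tf <- setNames(runif(5), letters[1:5])
  rg <- setNames(runif(5), letters[1:5])
  gn <- setNames(runif(5), letters[1:5])
  dots <- eregulon_dot(tf, rg, gn)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(dots$size, unname(mm(tf) * mm(rg)), tolerance = 1e-12)
  expect_equal(dots$color, unname(mm(gn)), tolerance = 1e-12)
  expect_warning(eregulon_dot(setNames(rep(1, 3), letters[1:3]),
                              setNames(1:3, letters[1:3]),
                              setNames(1:3, letters[1:3])), "constant")
})
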