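# A grid small enough to run in seconds, used by several blocks below.
small_grid <- function(replicates = 2L, backends = "kmeans", seed = 5L) {
  grid_spec(proportion_sets = list(c(0.2, 0.3, 0.5)),
            n_cells_levels = 120L,
            fold_changes = 8,
            n_genes = 600L, n_markers_per_type = 20L,
            backends = backends, replicates = replicates, master_seed = seed)
}

test_that("grid enumeration is factorial, ordered, and seed-stable", {
  gs <- grid_spec(replicates = 1L)           # default 3 x 3 x 3 design
  cells <- enumerate_grid(gs)
  expect_length(cells, 27L)
  # ordering: proportions outer, n_cells middle, fold change inner
  expect_equal(cells[[1]]$meta$fold_change, 2)
  expect_equal(cells[[2]]$meta$fold_change, 4)
  expect_equal(cells[[4]]$meta$n_cells, 2000L)
  expect_equal(cells[[10]]$meta$rarity, 0.05)
  # replicates multiply the count and get distinct seeds
  gs5 <- grid_spec(replicates = 5L)
  cells5 <- enumerate_grid(gs5)
  expect_length(cells5, 135L)
  seeds <- vapply(cells5, function(x) x$params$seed, integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_identical(seeds,
                   vapply(enumerate_grid(gs5), function(x) x$params$seed,
                          integer(1)))
  expect_length(enumerate_grid(small_grid(replicates = 1L)), 1L)
  expect_error(grid_spec(fold_changes = numeric(0)), "non-empty")
})

test_that("run_grid yields one row per dataset x backend and is resumable", {
  pt <- run_grid(small_grid(replicates = 2L))
  expect_identical(nrow(pt), 2L)
  expect_true(all(pt$status == "ok"))
  expect_true(all(pt$rare_type_f1 >= 0 & pt$rare_type_f1 <= 1))
  # unresolvable backend fails before simulating anything
  expect_error(run_grid(small_grid(backends = "missing")), "unknown backend")
  # ledger resume: first run writes it, second run does no new work
  led <- tempfile(fileext = ".tsv")
  on.exit(unlink(led), add = TRUE)
  pt1 <- run_grid(small_grid(replicates = 2L), ledger_path = led)
  n_lines <- length(readLines(led))
  pt2 <- run_grid(small_grid(replicates = 2L), ledger_path = led)
  expect_identical(length(readLines(led)), n_lines)
  expect_equal(pt2$rare_type_f1, pt1$rare_type_f1)
})

test_that("run_grid records backend failures without aborting", {
  register_backend("bomb", function(embedding, m_target, seed, ...)
    stop("boom"))
  on.exit(rm("bomb", envir = rarecell:::.backends))
  pt <- run_grid(small_grid(replicates = 1L, backends = c("kmeans", "bomb")))
  expect_identical(nrow(pt), 2L)
  expect_identical(pt$status[pt$backend == "bomb"], "error")
  expect_match(pt$note[pt$backend == "bomb"], "boom")
  expect_identical(pt$status[pt$backend == "kmeans"], "ok")
})

test_that("grid reruns reproduce the power table exactly", {
  gs <- small_grid(replicates = 2L, backends = c("kmeans", "mk_spectral"))
  expect_identical(run_grid(gs), run_grid(gs))
})

test_that("minimum-cells estimation scans levels and is monotone in threshold", {
  pt <- data.frame(backend = "b", rarity = 0.05, fold_change = 2,
                   n_cells = rep(c(1000L, 2000L, 3000L), each = 2),
                   replicate = rep(1:2, 3), seed = 1L,
                   rare_type_f1 = c(0.5, 0.5, 0.95, 0.95, 0.97, 0.97),
                   macro_f1 = 0.9, n_clusters = 5L, status = "ok", note = "")
  res <- min_cells_for_threshold(pt, 0.9)
  expect_identical(res$min_cells, 2000L)
  expect_true(res$achieved)
  res_low <- min_cells_for_threshold(pt, 0.4)
  expect_identical(res_low$min_cells, 1000L)
  res_high <- min_cells_for_threshold(pt, 0.99)
  expect_false(res_high$achieved)
  expect_true(is.na(res_high$min_cells))
  # monotone: raising the threshold never returns a smaller level
  ths <- c(0.3, 0.6, 0.9, 0.96)
  mins <- vapply(ths, function(t) {
    r <- min_cells_for_threshold(pt, t)
    if (r$achieved) r$min_cells else .Machine$integer.max
  }, numeric(1))
  expect_true(all(diff(mins) >= 0))
  expect_error(min_cells_for_threshold(pt, 0), "threshold")
  expect_error(min_cells_for_threshold(pt, 1.5), "threshold")
})

test_that("pipeline ranking orders backends by rare-type then macro F1", {
  pt <- data.frame(backend = rep(c("a", "b", "c"), each = 2),
                   rarity = 0.1, fold_change = 2, n_cells = 1000L,
                   replicate = rep(1:2, 3), seed = 1L,
                   rare_type_f1 = c(0.9, 0.9, 0.5, 0.5, 0.9, 0.9),
                   macro_f1 = c(0.8, 0.8, 0.9, 0.9, 0.95, 0.95),
                   n_clusters = 5L, status = "ok", note = "")
  rk <- select_best_pipeline(pt, rarity = 0.1, fold_change = 2,
                             n_cells = 1000L)
  expect_identical(rk$backend, c("c", "a", "b"))   # macro breaks the tie
  expect_identical(rk$rank, 1:3)
  one <- select_best_pipeline(pt[pt$backend == "b", ], 0.1, 2, 1000L)
  expect_identical(one$backend, "b")
  expect_error(select_best_pipeline(pt, 0.9, 2, 1000L), "no rows")
})
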