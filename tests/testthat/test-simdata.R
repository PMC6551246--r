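test_that("cell allocation is exact largest-remainder apportionment", {
  expect_identical(allocate_cells(c(0.1, 0.2, 0.2, 0.2, 0.3), 1000),
                   c(100L, 200L, 200L, 200L, 300L))
  # hand-computed: quotas 19.98, 199.8 x3, 379.62; remainders .98,.8,.8,.8,.62
  expect_identical(allocate_cells(c(0.02, 0.2, 0.2, 0.2, 0.38), 999),
                   c(20L, 200L, 200L, 200L, 379L))
  expect_error(allocate_cells(1.0, 10), "two cell types")
  expect_error(allocate_cells(c(0.001, 0.999), 100), "too small for rarest")
  expect_error(allocate_cells(c(0.5, 0.6), 100), "sum to 1")
  # conservation over random proportion vectors
  set.seed(7)
  for (i in 1:25) {
    m <- sample(2:8, 1)
    p <- stats::runif(m); p <- p / sum(p)
    n <- sample(m:500, 1)
    a <- tryCatch(allocate_cells(p, n), error = function(e) NULL)
    if (!is.null(a)) {
      expect_identical(sum(a), n)
      expect_true(all(a >= 1L))
    }
  }
})

test_that("baseline gene means follow the requested gamma distribution", {
  set.seed(1)
  x <- simulate_gene_means(100000, mean_shape = 0.6, mean_rate = 0.3)
  expect_true(all(x > 0))
  se_mean <- sqrt(0.6 / 0.09 / 1e5)
  expect_lt(abs(mean(x) - 2), 3 * se_mean)
  # var = shape/rate^2 = 6.667; allow generous Monte-Carlo slack
  expect_lt(abs(stats::var(x) - 0.6 / 0.09), 0.4)
  expect_error(simulate_gene_means(10, mean_shape = 0, mean_rate = 1))
})

test_that("fold-change factors have gamma(fC, 1) moments; truncation bounds them", {
  set.seed(2)
  x4 <- sample_fold_change(100000, 4, truncate_below_one = FALSE)
  expect_lt(abs(mean(x4) - 4), 3 * sqrt(4 / 1e5))
  x2 <- sample_fold_change(100000, 2, truncate_below_one = FALSE)
  expect_lt(abs(stats::var(x2) - 2), 0.1)
  xt <- sample_fold_change(10000, 2, truncate_below_one = TRUE)
  expect_true(all(xt >= 1))
  expect_error(sample_fold_change(10, 0.5), "fold_change >= 1")
})

test_that("marker injection multiplies only marker means of the right type", {
  base <- c(1, 2, 3, 4, 5, 6)
  mm <- list(`1` = c(1L, 2L), `2` = c(4L, 5L))
  # fold_change = 1 with truncation forces every factor to exactly 1:
  # gamma(1,1) truncated below 1 has support [1, inf) -- not degenerate --
  # so instead check the structural contract: non-marker rows untouched.
  set.seed(3)
  adj <- inject_marker_means(base, mm, 4, truncate_below_one = FALSE)
  expect_equal(dim(adj), c(6L, 2L))
  expect_equal(adj[3, ], c(3, 3))      # non-marker rows = baseline broadcast
  expect_equal(adj[6, ], c(6, 6))
  expect_equal(adj[4, 1], 4)           # type-2 markers untouched in type 1
  expect_equal(adj[1, 2], 1)
  expect_error(inject_marker_means(base, list(`1` = 99L), 2), "out of range")
  expect_error(inject_marker_means(base, list(`1` = 1L, `2` = 1L), 2),
               "disjoint")
  # plug-in expectation: mean over many (marker, type) factors is fC
  set.seed(4)
  big <- inject_marker_means(rep(1, 5000), list(`1` = 1:2500), 4,
                             truncate_below_one = FALSE)
  expect_lt(abs(mean(big[1:2500, 1]) - 4), 0.15)
})

test_that("library sizes are log-normal with median exp(location)", {
  set.seed(5)
  L <- simulate_library_sizes(100000, libsize_location = log(20000),
                              libsize_scale = 0.2)
  expect_true(all(L > 0))
  expect_lt(abs(stats::median(L) / 20000 - 1), 0.01)
})

test_that("counts are Poisson at zero dispersion and overdispersed otherwise", {
  set.seed(6)
  tm <- matrix(stats::rgamma(400, 2, 0.5), ncol = 2)
  type_of_cell <- rep(1:2, each = 150)
  L <- rep(2000, 300)
  x0 <- as.matrix(simulate_counts(tm, L, type_of_cell, bcv_dispersion = 0))
  expect_true(all(x0 >= 0) && all(x0 == round(x0)))
  # index of dispersion within one type ~ 1 for Poisson marginals
  ok <- rowMeans(x0[, 1:150]) > 0.5
  iod <- apply(x0[ok, 1:150], 1, stats::var) / rowMeans(x0[ok, 1:150])
  expect_lt(abs(mean(iod) - 1), 0.05)
  # expected column sum equals the library size
  expect_lt(abs(mean(colSums(x0) / L) - 1), 0.02)
  # overdispersion pushes the index of dispersion above 1
  set.seed(7)
  x1 <- as.matrix(simulate_counts(tm, L, type_of_cell, bcv_dispersion = 0.3))
  iod1 <- apply(x1[ok, 1:150], 1, stats::var) / rowMeans(x1[ok, 1:150])
  expect_gt(mean(iod1), mean(iod) + 0.2)
})

test_that("generate_dataset honors the design shape and is bit-reproducible", {
  p <- simulation_params(n_cells = 1000,
                         proportions = c(0.1, 0.2, 0.2, 0.2, 0.3),
                         n_genes = 2000, n_markers_per_type = 50,
                         fold_change = 2, seed = 11)
  d <- generate_dataset(p)
  expect_identical(dim(d$counts), c(2000L, 1000L))
  expect_identical(tabulate(d$true_labels), c(100L, 200L, 200L, 200L, 300L))
  expect_identical(unname(lengths(d$marker_map)), rep(50L, 5))
  expect_identical(anyDuplicated(unlist(d$marker_map)), 0L)
  d2 <- generate_dataset(p)
  expect_identical(as.matrix(d$counts), as.matrix(d2$counts))
  expect_identical(d$marker_map, d2$marker_map)
  # a different seed changes the data
  d3 <- generate_dataset(simulation_params(
    n_cells = 1000, proportions = c(0.1, 0.2, 0.2, 0.2, 0.3),
    n_genes = 2000, n_markers_per_type = 50, fold_change = 2, seed = 12))
  expect_false(identical(as.matrix(d$counts), as.matrix(d3$counts)))
})

test_that("untruncated unit fold change is indistinguishable from no injection", {
  pvals <- vapply(1:5, function(s) {
    p <- simulation_params(n_cells = 500,
                           proportions = c(0.2, 0.2, 0.2, 0.2, 0.2),
                           n_genes = 2000, n_markers_per_type = 30,
                           fold_change = 1, truncate_fc_below_one = FALSE,
                           seed = 100 + s)
    d <- generate_dataset(p)
    marker_r <- unlist(lapply(1:5, function(k)
      group_rest_ratio(d, d$marker_map[[k]], k)))
    nonmark <- setdiff(seq_len(2000), unlist(d$marker_map))
    set.seed(s)
    null_r <- group_rest_ratio(d, sample(nonmark, 150), 1)
    stats::t.test(marker_r, null_r)$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 4)
})

test_that("realized marker fold change tracks the target", {
  p <- tiny_params(seed = 21, n_cells = 600, fold_change = 4,
                   truncate_fc_below_one = FALSE)
  r <- realized_fold_change(generate_dataset(p))
  expect_gt(r$n_used, 50)
  expect_lt(abs(r$overall / 4 - 1), 0.25)  # small-n single-seed tolerance
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(simulation_params(100, c(0.5, 0.4)), "sum to 1")
  expect_error(simulation_params(100, c(1)), "at least two")
  expect_error(simulation_params(100, c(0.5, 0.5), n_genes = 10,
                                 n_markers_per_type = 6), "exceeds n_genes")
  expect_error(simulation_params(100, c(0.5, 0.5), fold_change = 0.5),
               "fold_change")
  expect_error(simulation_params(100, c(0.5, 0.5), dropout_midpoint = 1),
               "together")
})
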