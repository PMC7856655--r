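test_that("partial correlation matches plain Pearson with no covariates", {
  expect_equal(partial_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1,
               tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_correlation(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("a covariate that generates y absorbs the correlation", {
  set.seed(2)
  z <- rnorm(40); x <- rnorm(40)
  expect_equal(partial_correlation(x, 3 * z, Z = z), 0, tolerance = 1e-10)
})

test_that("partial correlation equals the precision-matrix identity", {
  # independent oracle: r_xy.Z = -P[1,2] / sqrt(P[1,1] P[2,2]) with
  # P = inverse covariance of (x, y, Z)
  oracle <- function(x, y, Z) {
    P <- solve(cov(cbind(x, y, Z)))
    -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  set.seed(3)
  for (i in 1:50) {
    n <- 50; k <- 5
    Z <- matrix(rnorm(n * k), n, k)
    x <- rnorm(n) + Z %*% rnorm(k, 0, 0.5)
    y <- rnorm(n) + Z %*% rnorm(k, 0, 0.5)
    expect_equal(partial_correlation(drop(x), drop(y), Z),
                 oracle(drop(x), drop(y), Z), tolerance = 1e-8)
  }
})

test_that("partial correlation rejects degenerate designs", {
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_error(partial_correlation(x, y, Z = cbind(z, 2 * z)),
               "rank-deficient")
  expect_error(partial_correlation(rep(1, 20), y), "degenerate")
  expect_error(partial_correlation(x[1:4], y[1:4], Z = matrix(rnorm(12), 4)),
               "n > k")
})

test_that("seeded maps separate in- from out-of-territory voxels", {
  sim <- shared_sim(seed = 3, n = 20)
  ds <- sim$dataset
  rows <- group_rows(ds, "HC")
  tt <- true_territory(sim, "cerebellum")
  for (l in c(1, 4)) {
    r <- seed_structure_map(ds, l, "cerebellum", rows)
    expect_gt(mean(r[tt == l]), mean(r[tt != l]))
  }
})

test_that("seeded maps are invariant to subject order, replication and
           covariate rescaling", {
  sim <- shared_sim(seed = 3, n = 20)
  ds <- sim$dataset
  rows <- group_rows(ds, "GE_GTCS")
  r0 <- seed_structure_map(ds, 2, "striatum", rows)
  expect_equal(seed_structure_map(ds, 2, "striatum", sample(rows)), r0,
               tolerance = 1e-12)
  expect_equal(seed_structure_map(ds, 2, "striatum", c(rows, rows)), r0,
               tolerance = 1e-10)
  # affine rescaling of a covariate (TIV in litres instead of ml)
  ds2 <- ds
  ds2$cohort$tiv <- ds$cohort$tiv / 1000 + 7
  expect_equal(seed_structure_map(ds2, 2, "striatum", rows), r0,
               tolerance = 1e-8)
})

test_that("winner-take-all picks the signed maximum with lowest-id ties", {
  r <- rbind(c(0.1, 0.5, 0.2, -0.3, 0.0),
             c(0.4, 0.4, 0.1, 0.0, -0.2),
             c(-0.6, -0.2, -0.4, -0.5, -0.3))
  m <- wta_label(r)
  expect_equal(m$winner_label, c(2L, 1L, 2L))
  expect_equal(m$winner_r, c(0.5, 0.4, -0.2))
  expect_equal(m$n_ties, 1L)
  # all-negative rows stay labeled (full partition)
  expect_true(all(m$winner_label %in% 1:5))
  # absolute mode flips the all-negative row to the largest magnitude
  ma <- wta_label(r, absolute = TRUE)
  expect_equal(ma$winner_label[3], 1L)
  expect_error(wta_label(rbind(rep(NA_real_, 5))), "finite")
})

test_that("label counts conserve the structure voxel count", {
  sim <- shared_sim(seed = 3, n = 20)
  ds <- sim$dataset
  for (s in names(structure_ids())) {
    m <- wta_structure_map(ds, s, group = "HC")
    cnt <- count_labels(m)
    expect_equal(sum(cnt), length(region_columns(ds, structure_ids()[[s]])))
    expect_true(all(cnt >= 0))
  }
  expect_equal(unname(count_labels(wta_label(cbind(1, matrix(0, 100, 4))))),
               c(100L, 0L, 0L, 0L, 0L))
})

test_that("high-SNR winner-take-all recovers the planted territories", {
  sim <- shared_sim(seed = 3, n = 40)
  ds <- sim$dataset
  agree <- vapply(names(structure_ids()), function(s) {
    m <- wta_structure_map(ds, s, group = "HC")
    mean(m$winner_label == true_territory(sim, s))
  }, numeric(1))
  expect_true(all(agree >= 0.9))
})

test_that("radar normalisation is the published count ratio", {
  # printed counts 2006 (patients) vs 965 (controls) standardise to ~2.079
  expect_equal(radar_normalize(c(2006, rep(1, 4)), c(965, rep(1, 4)))[1],
               2006 / 965, tolerance = 1e-12)
  expect_equal(round(2006 / 965, 3), 2.079)
})

test_that("identical groups give zero observed difference and p = 1", {
  sim <- shared_sim(seed = 3, n = 10)
  ds <- sim$dataset
  # duplicate the HC block under two different labels: A and B are the same
  # subjects subject-for-subject
  hc <- group_rows(ds, "HC")
  mat <- rbind(ds$matrix[hc, ], ds$matrix[hc, ])
  co <- rbind(ds$cohort[hc, ], ds$cohort[hc, ])
  co$group <- rep(c("GE_GTCS", "FE_FBTS"), each = length(hc))
  co$duration_months <- 50
  co$subject_id <- sprintf("d%03d", seq_len(nrow(co)))
  ds2 <- scnwta:::.gmv_dataset_from_matrix(mat, ds$voxel_index,
                                           cohort_table(co), ds$atlas,
                                           ds$dims)
  cmp <- suppressWarnings(
    permutation_map_test(ds2, "GE_GTCS", "FE_FBTS", "striatum",
                         n_perm = 99, seed = 1))
  expect_true(all(cmp$table$observed_diff == 0))
  expect_true(all(cmp$table$p_perm == 1))
})

test_that("permutation p-values respect their attainable range", {
  sim <- shared_sim(seed = 3, n = 10)
  cmp <- suppressWarnings(
    permutation_map_test(sim$dataset, "GE_GTCS", "HC", "thalamus",
                         n_perm = 99, seed = 2))
  expect_true(all(cmp$table$p_perm >= 1 / 100))
  expect_true(all(cmp$table$p_perm <= 1))
  expect_warning(
    permutation_map_test(sim$dataset, "GE_GTCS", "HC", "thalamus",
                         n_perm = 50, seed = 2), "n_perm")
})

test_that("fast permutation counts agree with the reference WTA path", {
  sim <- shared_sim(seed = 3, n = 20)
  ds <- sim$dataset
  cmp <- suppressWarnings(
    permutation_map_test(ds, "GE_GTCS", "HC", "cerebellum",
                         n_perm = 1, seed = 1))
  ma <- wta_structure_map(ds, "cerebellum", group = "GE_GTCS")
  mb <- wta_structure_map(ds, "cerebellum", group = "HC")
  expect_equal(cmp$table$count_a, unname(as.integer(count_labels(ma))))
  expect_equal(cmp$table$count_b, unname(as.integer(count_labels(mb))))
})
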