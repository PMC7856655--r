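# per-voxel loop oracle fitting lm() voxel by voxel
loop_anova_f <- function(ds, cols) {
  co <- ds$cohort
  vapply(cols, function(v) {
    full <- lm(ds$matrix[, v] ~ group + tiv + age + sex, data = co)
    red <- lm(ds$matrix[, v] ~ tiv + age + sex, data = co)
    unname(anova(red, full)$F[2])
  }, numeric(1))
}

test_that("voxelwise group ANOVA matches the nested-model loop oracle", {
  sim <- shared_sim(seed = 3, n = 12)
  ds <- sim$dataset
  fmap <- voxelwise_group_anova(ds)
  cols <- seq(1, ncol(ds$matrix), length.out = 50)
  cols <- unique(as.integer(cols))
  expect_equal(fmap$values[cols], loop_anova_f(ds, cols), tolerance = 1e-8)
  expect_equal(fmap$df[1], 2)
})

test_that("null F-map quantiles follow the F distribution", {
  # identical group-generating config with independent voxels: the group
  # factor is pure noise, so per-voxel F values are iid F(2, df2)
  sim <- generate_cohort(indep_config(seed = 77))
  ds <- sim$dataset
  fmap <- voxelwise_group_anova(ds)
  ks <- suppressWarnings(
    ks.test(pf(fmap$values, fmap$df[1], fmap$df[2]), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted atrophy localises the strongest group effect", {
  atr <- array(0, c(3, 8))
  atr[1, 7] <- 8e-4   # thalamic loss in GE_GTCS only
  hits <- vapply(1:10, function(i) {
    sim <- generate_cohort(generator_config(grid = 16, n_per_group = 25,
                                            atrophy_slope = atr,
                                            seed = 500 + i))
    ds <- sim$dataset
    fmap <- voxelwise_group_anova(ds)
    ds$voxel_index$label[which.max(fmap$values)] == structure_ids()["thalamus"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duration correlation equals partial_correlation voxelwise", {
  sim <- shared_sim(seed = 3, n = 12)
  ds <- sim$dataset
  rmap <- voxelwise_duration_corr(ds, "GE_GTCS")
  rows <- group_rows(ds, "GE_GTCS")
  co <- ds$cohort[rows, ]
  Z <- cbind(co$tiv, co$age, as.integer(co$sex == "M"))
  for (v in c(1, 101, 501)) {
    expect_equal(rmap$values[v],
                 partial_correlation(ds$matrix[rows, v], co$duration_months,
                                     Z),
                 tolerance = 1e-8)
  }
})

test_that("planted atrophy shows as negative duration correlation", {
  atr <- array(0, c(3, 8))
  atr[1:2, 8] <- 6e-4   # cerebellar loss per month in both patient groups
  sim <- generate_cohort(generator_config(grid = 16, n_per_group = 30,
                                          atrophy_slope = atr, seed = 61))
  ds <- sim$dataset
  rmap <- voxelwise_duration_corr(ds, "GE_GTCS")
  cer <- region_columns(ds, structure_ids()["cerebellum"])
  expect_lt(mean(rmap$values[cer]), mean(rmap$values[-cer]))
  expect_lt(mean(rmap$values[cer]), 0)
})

test_that("slope interaction map matches lm() and is recode-invariant", {
  sim <- shared_sim(seed = 3, n = 12)
  ds <- sim$dataset
  tmap <- slope_interaction_map(ds)
  rows <- c(group_rows(ds, "GE_GTCS"), group_rows(ds, "FE_FBTS"))
  co <- ds$cohort[rows, ]
  gi <- as.integer(co$group == "GE_GTCS")
  for (v in c(2, 202)) {
    lmfit <- summary(lm(ds$matrix[rows, v] ~ gi * co$duration_months +
                          co$tiv + co$age + I(co$sex == "M")))
    expect_equal(tmap$values[v],
                 lmfit$coefficients["gi:co$duration_months", "t value"],
                 tolerance = 1e-8)
    # ±1 recoding leaves |t| unchanged
    gpm <- 2 * gi - 1
    lmpm <- summary(lm(ds$matrix[rows, v] ~ gpm * co$duration_months +
                         co$tiv + co$age + I(co$sex == "M")))
    expect_equal(abs(tmap$values[v]),
                 abs(lmpm$coefficients["gpm:co$duration_months", "t value"]),
                 tolerance = 1e-8)
  }
})

test_that("connected components are order-invariant and 26-connected", {
  coords <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),   # one diagonal chain
                  c(9, 9, 9),                            # isolated voxel
                  c(5, 0, 0), c(5, 1, 0))                # one face pair
  m1 <- scnwta:::.components26(coords)
  expect_equal(max(m1), 3)
  expect_equal(m1[1], m1[2])
  expect_equal(m1[2], m1[3])
  expect_equal(m1[5], m1[6])
  expect_false(m1[4] == m1[1])
  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- scnwta:::.components26(coords[perm, ])
  # same partition under any traversal order
  expect_equal(outer(m1, m1, "=="), outer(m2[order(perm)], m2[order(perm)],
                                          "=="))
})

test_that("an extreme voxel threshold yields an empty cluster list", {
  sim <- shared_sim(seed = 3, n = 12)
  ds <- sim$dataset
  fmap <- voxelwise_group_anova(ds)
  res <- cluster_correct(fmap, ds, list(type = "group_anova"),
                         voxel_p = 1e-9, n_perm = 19, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$membership == 0))
})

test_that("a large planted effect survives cluster correction", {
  # localized effect: strong cerebellar atrophy in GE_GTCS against a
  # background of independent voxels (no lobe-factor coherence, which would
  # dominate the max-cluster null with whole-lobe pseudo-clusters)
  atr <- array(0, c(3, 8))
  atr[1, 8] <- 1e-3
  sim <- generate_cohort(indep_config(seed = 71, n = 30,
                                      atrophy_slope = atr))
  ds <- sim$dataset
  fmap <- voxelwise_group_anova(ds)
  res <- cluster_correct(fmap, ds, list(type = "group_anova"),
                         voxel_p = 0.01, n_perm = 199, seed = 2)
  expect_gt(nrow(res$clusters), 0)
  sig <- res$clusters[res$clusters$p_corrected < 0.05, ]
  expect_gt(nrow(sig), 0)
  # the winning cluster covers at least half of the planted region
  cer <- region_columns(ds, structure_ids()["cerebellum"])
  best <- sig$id[which.max(sig$size)]
  covered <- sum(res$membership[cer] == best) / length(cer)
  expect_gte(covered, 0.5)
})
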