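test_that("default atlas has 28 tracts with mirror-symmetric homolog pairs", {
  atlas <- generate_atlas(synthetic_atlas_spec(), seed = 2)
  expect_equal(length(atlas$tract_names), 28L)
  expect_equal(sum(atlas$hemisphere == "L"), 13L)
  expect_equal(sum(atlas$hemisphere == "R"), 13L)
  expect_equal(sum(atlas$hemisphere == "bilateral"), 2L)
  for (p in seq_len(nrow(atlas$pairs))) {
    lv <- atlas$maps[[atlas$pairs$left[p]]]$voxels
    rv <- atlas$maps[[atlas$pairs$right[p]]]$voxels
    expect_setequal(mirror_voxels(lv, atlas$grid_shape), rv)
  }
})

test_that("left tracts occupy only the left half-grid (and right the right)", {
  atlas <- generate_atlas(synthetic_atlas_spec(), seed = 9)
  half <- atlas$grid_shape[1] / 2
  xcoord <- function(idx) arrayInd(idx, atlas$grid_shape)[, 1]
  for (t in seq_along(atlas$maps)) {
    x <- xcoord(atlas$maps[[t]]$voxels)
    if (atlas$hemisphere[t] == "L") expect_true(all(x <= half))
    if (atlas$hemisphere[t] == "R") expect_true(all(x > half))
  }
})

test_that("synthetic tracts are pairwise disjoint", {
  atlas <- generate_atlas(synthetic_atlas_spec(), seed = 4)
  all_vox <- unlist(lapply(atlas$maps, function(m) m$voxels))
  expect_equal(anyDuplicated(all_vox), 0L)
})

test_that("oversized tract requests raise a capacity error", {
  spec <- synthetic_atlas_spec(grid_shape = c(8, 8, 4), n_tract_pairs = 2,
                               n_bilateral_tracts = 0, tract_size = 100)
  expect_error(generate_atlas(spec, seed = 1), "capacity")
})

test_that("a single pair with no bilateral tract is mirror symmetric", {
  spec <- synthetic_atlas_spec(grid_shape = c(10, 10, 6), n_tract_pairs = 1,
                               n_bilateral_tracts = 0, tract_size = 20)
  atlas <- generate_atlas(spec, seed = 3)
  expect_equal(length(atlas$tract_names), 2L)
  expect_setequal(mirror_voxels(atlas$maps[[1]]$voxels, atlas$grid_shape),
                  atlas$maps[[2]]$voxels)
})

test_that("planted lateralization is exact, including the extremes", {
  atlas <- generate_atlas(small_atlas_spec(), seed = 10)
  li_values <- c(1, 0, -0.5)
  gt <- generate_ground_truth(atlas, k = 3, lateralization_profile = li_values,
                              effects = effect_config(k = 3), seed = 11)
  hemi <- atlas$hemisphere
  # LI = 1: zero weight on every right tract
  expect_true(all(gt$W_true[hemi == "R", 1] == 0))
  # LI = 0: equal left and right sums
  expect_equal(sum(gt$W_true[hemi == "L", 2]), sum(gt$W_true[hemi == "R", 2]))
  for (a in 1:3) {
    expect_equal(lateralization_index(gt$W_true[, a], hemi), li_values[a])
  }
  expect_error(
    generate_ground_truth(atlas, k = 2, lateralization_profile = c(0, 1.5),
                          effects = effect_config(k = 2)),
    "\\[-1, 1\\]")
})

test_that("default ground truth covers every tract and stays non-negative", {
  atlas <- generate_atlas(synthetic_atlas_spec(), seed = 2)
  gt <- generate_ground_truth(atlas, k = 10, seed = 3)
  expect_true(all(gt$W_true >= 0))
  expect_true(all(rowSums(gt$W_true) > 0))
  li_re <- vapply(seq_len(10), function(a) {
    lateralization_index(gt$W_true[, a], atlas$hemisphere)
  }, numeric(1))
  expect_equal(li_re, gt$planted_li, tolerance = 1e-12)
})

test_that("expressions are non-negative, right-skewed, with the stated mean", {
  st <- small_study()
  H1 <- generate_expressions(st$gt, 1, seed = 1)
  expect_equal(ncol(H1), 1L)
  H <- generate_expressions(st$gt, 2000, seed = 2)
  expect_true(all(H >= 0))
  expect_gt(mean(H > stats::median(H) + 2 * mad(H)), 0.01) # heavy right tail
  se <- stats::sd(H) / sqrt(length(H))
  expect_lt(abs(mean(H) - attr(H, "entry_mean")), 3 * se)
})

test_that("masks hit integer target loads exactly on the disjoint atlas", {
  st <- small_study(n_patients = 25)
  masks <- generate_lesion_masks(st$gt, st$atlas, st$H, seed = 3)
  targets <- attr(masks, "target_loads")
  V <- lesion_load_matrix(masks, st$atlas)
  expect_equal(unname(V$values), unname(targets))
  # zero-target patient gives an empty mask
  H0 <- st$H
  H0[, 1] <- 0
  masks0 <- generate_lesion_masks(st$gt, st$atlas, H0, seed = 4)
  expect_length(masks0[[1]], 0)
})

test_that("saturating target loads raise a scaling error", {
  st <- small_study(n_patients = 3)
  Hbig <- st$H * 1e4
  expect_error(generate_lesion_masks(st$gt, st$atlas, Hbig, seed = 1),
               "exceeds tract")
})

test_that("cohort moments match the emulated registry at large n", {
  st <- small_study(n_patients = 5000)
  cohort <- generate_covariates_and_outcomes(st$gt, st$H, seed = 6)
  n <- nrow(cohort)
  p_f <- mean(cohort$sex == "female")
  expect_lt(abs(p_f - 0.42), 3 * sqrt(0.42 * 0.58 / n))
  expect_lt(abs(mean(cohort$age) - 67.58), 3 * stats::sd(cohort$age) / sqrt(n))
  age_f <- cohort$age[cohort$sex == "female"]
  expect_lt(abs(mean(age_f) - 70.73), 3 * stats::sd(age_f) / sqrt(length(age_f)))
  expect_true(all(cohort$age >= 18 & cohort$age <= 100))
})

test_that("zero noise and zero effects give an exactly zero latent outcome", {
  st <- small_study(n_patients = 200)
  ef <- effect_config(k = 3,
                      beta_atoms_female = rep(0, 3),
                      beta_atoms_male = rep(0, 3),
                      beta_lesion_volume = 0, beta_age = 0, beta_age_sq = 0,
                      beta_education = 0, beta_iqcode = 0,
                      beta_male = 0, beta_female = 0, alpha = 0, noise_sd = 0)
  gt <- generate_ground_truth(st$atlas, k = 3, effects = ef, seed = 12)
  cohort <- generate_covariates_and_outcomes(gt, st$H, seed = 13)
  # outcomes collapse to the raw-scale anchor constant
  expect_equal(cohort$boston_naming, rep(9.92, 200))
})

test_that("with zero noise a single atom effect gives perfect within-sex correlation", {
  st <- small_study(n_patients = 300)
  ef <- effect_config(k = 3,
                      beta_atoms_female = c(0.5, 0, 0),
                      beta_atoms_male = c(0.5, 0, 0),
                      beta_lesion_volume = 0, beta_age = 0, beta_age_sq = 0,
                      beta_education = 0, beta_iqcode = 0,
                      beta_male = 0, beta_female = 0, alpha = 0, noise_sd = 0)
  gt <- generate_ground_truth(st$atlas, k = 3, effects = ef, seed = 14)
  cohort <- generate_covariates_and_outcomes(gt, st$H, seed = 15)
  for (s in c("female", "male")) {
    i <- cohort$sex == s
    expect_equal(cor(cohort$boston_naming[i], st$H[1, i]), 1, tolerance = 1e-10)
  }
})

test_that("default generator targets a theoretical R^2 of one half", {
  st <- small_study(n_patients = 1500)
  cohort <- generate_covariates_and_outcomes(st$gt, st$H, seed = 16)
  truth <- attr(cohort, "outcome_truth")
  for (oc in names(truth)) {
    expect_equal(truth[[oc]]$r2_theoretical, 0.5, tolerance = 1e-12)
  }
})
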