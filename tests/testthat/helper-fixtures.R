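# Shared fixtures: a small synthetic study that most tests reuse.

small_atlas_spec <- function() {
  synthetic_atlas_spec(grid_shape = c(16, 16, 8), n_tract_pairs = 4,
                       n_bilateral_tracts = 1, tract_size = 100)
}

small_study <- function(n_patients = 60, k = 3, seed = 101) {
  atlas <- generate_atlas(small_atlas_spec(), seed = seed)
  gt <- generate_ground_truth(atlas, k = k, seed = seed + 1,
                              effects = effect_config(k = k))
  H <- generate_expressions(gt, n_patients, seed = seed + 2)
  list(atlas = atlas, gt = gt, H = H)
}

make_cohort_df <- function(n = 5, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age = round(runif(n, 40, 90), 1),
    education_years = round(runif(n, 0, 18)),
    iqcode = round(runif(n, 3, 4), 2),
    lesion_volume = round(runif(n, 0, 60), 2),
    boston_naming = round(runif(n, 0, 15)),
    semantic_fluency = round(runif(n, 0, 25)),
    phonemic_fluency = round(runif(n, 0, 40))
  )
}

# greedy one-to-one alignment of fitted atoms to true atoms by cosine
cosine_alignment <- function(W_true, W_fit) {
  cn <- function(A) sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-300), "/")
  cm <- crossprod(cn(W_true), cn(W_fit))
  k <- ncol(W_true)
  out <- numeric(k)
  taken <- rep(FALSE, ncol(W_fit))
  for (rep_i in seq_len(k)) {
    cm_masked <- cm
    cm_masked[, taken] <- -Inf
    idx <- which(cm_masked == max(cm_masked), arr.ind = TRUE)[1, ]
    out[idx[1]] <- cm[idx[1], idx[2]]
    taken[idx[2]] <- TRUE
    cm[idx[1], ] <- -Inf
  }
  out
}

# brute-force per-voxel quantification oracle: plain triple loop semantics
brute_force_loads <- function(mask_array, atlas) {
  loads <- numeric(length(atlas$tract_names))
  for (t in seq_along(atlas$maps)) {
    total <- 0
    vox <- atlas$maps[[t]]$voxels
    wts <- atlas$maps[[t]]$weights
    for (i in seq_along(vox)) {
      total <- total + wts[i] * mask_array[vox[i]]
    }
    loads[t] <- total
  }
  names(loads) <- atlas$tract_names
  loads
}

# exhaustive sorted-window HDI oracle
hdi_oracle <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}
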