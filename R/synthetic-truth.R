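#' Effect configuration for the synthetic outcome generator
#'
#' Holds the generative counterparts of every coefficient of the outcome
#' model: the intercept, sex-indexed atom slopes, the covariate slopes, the
#' sex-indicator offsets, and the likelihood noise scale. All values are on
#' the standardized-predictor scale. Default atom effects are a mix of signs
#' and magnitudes comparable to published posterior means (roughly -0.35 to
#' +0.15 standardized units).
#'
#' @param k Number of atoms.
#' @param beta_atoms_female,beta_atoms_male Length-k atom slopes per sex.
#' @param beta_lesion_volume,beta_age,beta_age_sq,beta_education,beta_iqcode
#'   Covariate slopes.
#' @param beta_male,beta_female Sex-indicator offsets.
#' @param alpha Intercept.
#' @param noise_sd Gaussian noise sd on the latent outcome scale. `NULL`
#'   (default) sets it to the empirical sd of the linear predictor, which
#'   makes the generating model's theoretical R^2 equal 0.5, the scale of the
#'   best published fit.
#' @return An `effect_config` list.
#' @export
effect_config <- function(k = 10,
                          beta_atoms_female = NULL,
                          beta_atoms_male = NULL,
                          beta_lesion_volume = -0.10,
                          beta_age = -0.10,
                          beta_age_sq = 0.05,
                          beta_education = 0.20,
                          beta_iqcode = -0.15,
                          beta_male = 0.05,
                          beta_female = -0.05,
                          alpha = 0,
                          noise_sd = NULL) {
  base_f <- c(-0.25, -0.05, 0.00, 0.15, -0.35, 0.10, -0.10, 0.14, -0.15, -0.08)
  base_m <- c(-0.16, -0.03, -0.22, 0.05, -0.19, 0.00, 0.08, 0.02, -0.15, -0.08)
  recycle <- function(x, k) x[((seq_len(k) - 1) %% length(x)) + 1]
  cfg <- list(
    k = as.integer(k),
    beta_atoms_female = beta_atoms_female %||% recycle(base_f, k),
    beta_atoms_male = beta_atoms_male %||% recycle(base_m, k),
    beta_lesion_volume = beta_lesion_volume,
    beta_age = beta_age,
    beta_age_sq = beta_age_sq,
    beta_education = beta_education,
    beta_iqcode = beta_iqcode,
    beta_male = beta_male,
    beta_female = beta_female,
    alpha = alpha,
    noise_sd = noise_sd
  )
  stopifnot(length(cfg$beta_atoms_female) == k,
            length(cfg$beta_atoms_male) == k)
  class(cfg) <- "effect_config"
  cfg
}

default_lateralization_profile <- function(k) {
  # mostly lateralized left/right homolog pairs, one bilateral atom,
  # echoing the typical pattern of paired lesion constellations
  base <- c(0.70, -0.70, -0.60, 0.55, 0.65, -0.55, -0.75, 0.90, 0.60, 0.00)
  base[((seq_len(k) - 1) %% length(base)) + 1]
}

#' Generate ground-truth atom structure and effects
#'
#' Builds a sparse non-negative basis `W_true` (tracts x k): each atom is
#' anchored on its own dominant homolog tract pair (making the planted
#' factorization separable and hence recoverable), carries a couple of minor
#' pairs, and has an exactly planted lateralization index. A pair with base
#' weight b and planted LI `li` receives left weight `b * (1 + li)` and right
#' weight `b * (1 - li)`, so the recomputed LI equals `li` to machine
#' precision. Bilateral tracts (excluded from LI) are spread over the last
#' atoms so every tract is covered.
#'
#' @param atlas A `tract_atlas` with homolog pairs.
#' @param k Number of atoms (default 10); must not exceed the tract count.
#' @param lateralization_profile Length-k planted LI values in \[-1, 1\].
#' @param effects An [effect_config()]; defaults to `effect_config(k)`.
#' @param seed Integer seed (jitters tract weights).
#' @return A `lesion_ground_truth` with `W_true`, `planted_li`, `effects`
#'   and the atlas hemisphere labels.
#' @export
generate_ground_truth <- function(atlas, k = 10,
                                  lateralization_profile = NULL,
                                  effects = NULL,
                                  seed = 1) {
  if (k > n_tracts(atlas)) abort("k must not exceed the number of tracts")
  li <- lateralization_profile %||% default_lateralization_profile(k)
  if (length(li) != k) abort("lateralization profile must have length k")
  if (any(li < -1 | li > 1)) {
    abort("planted lateralization indices must lie in [-1, 1]")
  }
  effects <- effects %||% effect_config(k)
  stopifnot(inherits(effects, "effect_config"), effects$k == k)
  np <- nrow(atlas$pairs)
  if (np < 1) abort("atlas has no homolog pairs; cannot plant lateralized atoms")
  set.seed(seed)
  m <- n_tracts(atlas)
  W <- matrix(0, m, k, dimnames = list(atlas$tract_names,
                                       sprintf("atom_%02d", seq_len(k))))
  add_pair <- function(W, atom, pair, base) {
    W[atlas$pairs$left[pair], atom] <- W[atlas$pairs$left[pair], atom] +
      base * (1 + li[atom])
    W[atlas$pairs$right[pair], atom] <- W[atlas$pairs$right[pair], atom] +
      base * (1 - li[atom])
    W
  }
  for (a in seq_len(k)) {
    anchor <- ((a - 1) %% np) + 1
    minor1 <- (a %% np) + 1
    minor2 <- ((a + 4) %% np) + 1
    W <- add_pair(W, a, anchor, 3.0 * runif(1, 0.9, 1.1))
    W <- add_pair(W, a, minor1, 0.8 * runif(1, 0.8, 1.2))
    if (minor2 != anchor && minor2 != minor1) {
      W <- add_pair(W, a, minor2, 0.5 * runif(1, 0.8, 1.2))
    }
  }
  # cover any tract pair no atom touched (preserves each planted LI exactly)
  covered <- rowSums(W) > 0
  for (p in seq_len(np)) {
    if (!covered[atlas$pairs$left[p]] || !covered[atlas$pairs$right[p]]) {
      a <- ((p - 1) %% k) + 1
      W <- add_pair(W, a, p, 0.4)
    }
  }
  # bilateral tracts ride on the later atoms; they do not enter the LI
  bilat <- which(atlas$hemisphere == "bilateral")
  for (i in seq_along(bilat)) {
    a <- k - ((i - 1) %% k)
    W[bilat[i], a] <- W[bilat[i], a] + 1.0
  }
  structure(list(
    W_true = W,
    planted_li = li,
    effects = effects,
    hemisphere = atlas$hemisphere,
    tract_names = atlas$tract_names
  ), class = "lesion_ground_truth")
}

#' @export
print.lesion_ground_truth <- function(x, ...) {
  cat(sprintf("<lesion_ground_truth> %d tracts, %d atoms; planted LI: %s\n",
              nrow(x$W_true), ncol(x$W_true),
              paste(sprintf("%.2f", x$planted_li), collapse = " ")))
  invisible(x)
}

#' Generate patient-level atom expressions H
#'
#' Entries are non-negative and right-skewed: every patient gets a small
#' exponential background expression on each atom plus a large exponential
#' boost on one uniformly chosen dominant atom, so most patients express few
#' atoms strongly. The marginal mean of an entry is
#' `mu_background + mu_dominant / k`.
#'
#' @param ground_truth A `lesion_ground_truth`.
#' @param n_patients Number of patients (columns).
#' @param seed Integer seed.
#' @param mu_background Mean of the background exponential (default 0.3).
#' @param mu_dominant Mean of the dominant-atom exponential boost (default 3).
#' @return k x n non-negative matrix with an attribute `"entry_mean"` giving
#'   the configured marginal mean.
#' @export
generate_expressions <- function(ground_truth, n_patients, seed = 1,
                                 mu_background = 0.3, mu_dominant = 3) {
  stopifnot(n_patients >= 1, mu_background >= 0, mu_dominant >= 0)
  k <- ncol(ground_truth$W_true)
  set.seed(seed)
  H <- matrix(rexp(k * n_patients, rate = 1 / max(mu_background, 1e-12)),
              k, n_patients)
  if (mu_background == 0) H[] <- 0
  dom <- sample.int(k, n_patients, replace = TRUE)
  boost <- rexp(n_patients, rate = 1 / max(mu_dominant, 1e-12))
  if (mu_dominant == 0) boost[] <- 0
  H[cbind(dom, seq_len(n_patients))] <-
    H[cbind(dom, seq_len(n_patients))] + boost
  dimnames(H) <- list(colnames(ground_truth$W_true),
                      sprintf("P%04d", seq_len(n_patients)))
  attr(H, "entry_mean") <- mu_background + mu_dominant / k
  H
}

#' Generate per-patient binary lesion masks matching target tract loads
#'
#' Target loads are `round(W_true %*% H)` (half-up rounding). For each
#' patient, exactly that many voxels are sampled without replacement inside
#' each tract. Because the synthetic atlas tracts are disjoint, quantifying a
#' generated mask reproduces the integer targets exactly.
#'
#' @param ground_truth A `lesion_ground_truth`.
#' @param atlas The `tract_atlas` used to build the ground truth.
#' @param H k x n expression matrix from [generate_expressions()].
#' @param seed Integer seed.
#' @return List of n integer voxel-index vectors (one mask per patient) with
#'   attributes `grid_shape` and `target_loads` (m x n integer matrix).
#' @export
generate_lesion_masks <- function(ground_truth, atlas, H, seed = 1) {
  targets <- round(ground_truth$W_true %*% H)
  caps <- tract_voxel_counts(atlas)
  over <- which(targets > caps, arr.ind = TRUE)
  if (nrow(over) > 0) {
    abort(sprintf(
      "target load %d exceeds tract '%s' voxel count %d (mis-scaled config?)",
      targets[over[1, 1], over[1, 2]],
      atlas$tract_names[over[1, 1]], caps[over[1, 1]]))
  }
  set.seed(seed)
  n <- ncol(targets)
  masks <- vector("list", n)
  for (j in seq_len(n)) {
    vox <- integer(0)
    for (t in which(targets[, j] > 0)) {
      vox <- c(vox, sample(atlas$maps[[t]]$voxels, targets[t, j]))
    }
    masks[[j]] <- sort(vox)
  }
  names(masks) <- colnames(H)
  attr(masks, "grid_shape") <- atlas$grid_shape
  attr(masks, "target_loads") <- targets
  masks
}

#' Expand a sparse voxel-index mask into a binary 3-D array
#'
#' @param mask Integer vector of lesioned voxel indices.
#' @param grid_shape Grid dimensions.
#' @return Binary 3-D array.
#' @export
mask_to_array <- function(mask, grid_shape) {
  arr <- array(0, grid_shape)
  arr[mask] <- 1
  arr
}
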