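cohort_anchor_defaults <- function() {
  # sex-specific distributional anchors of the emulated registry cohort:
  # 42% women; age (y), education (y) and IQCODE drawn per sex so the pooled
  # moments reproduce the published cohort table
  list(
    p_female = 0.42,
    age = list(female = c(mean = 70.73, sd = 11.15),
               male = c(mean = 65.29, sd = 11.38), range = c(18, 100)),
    education = list(female = c(mean = 6.68, sd = 4.98),
                     male = c(mean = 11.16, sd = 4.51), range = c(0, 25)),
    iqcode = list(female = c(mean = 3.42, sd = 0.49),
                  male = c(mean = 3.32, sd = 0.44), range = c(1, 5)),
    ml_per_voxel = 0.12,
    outcome_scales = tibble::tibble(
      outcome = c("boston_naming", "semantic_fluency", "phonemic_fluency"),
      mean = c(9.92, 11.51, 17.37),
      sd = c(3.59, 5.11, 10.78))
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate covariates and model-consistent outcomes for a synthetic cohort
#'
#' Sex is Bernoulli(0.42) for female; age, education years and IQCODE are
#' truncated normals with sex-specific anchors whose pooled moments match the
#' emulated cohort (overall age 67.58, sd 11.59, 42% women). Lesion volume is
#' the planted tract burden `colSums(W %*% H)` plus an independent
#' exponential out-of-atlas component, so it is right-skewed and correlated
#' with — but not collinear with — the atom expressions, as in real data.
#'
#' Each outcome is generated from the model's own linear predictor: the
#' standardized design matrix (identical code path to [build_design()]) times
#' the configured coefficients, plus Gaussian noise. Outcomes are stored on a
#' raw test-score scale; z-scoring them recovers the generating scale. The
#' attribute `"outcome_truth"` records, per outcome, the coefficients on the
#' z-scored-outcome scale actually estimated by the model
#' (`beta / sd(latent outcome)`), the noise sd, and the theoretical R^2.
#'
#' @param ground_truth A `lesion_ground_truth` (supplies effects and W).
#' @param H k x n expression matrix.
#' @param seed Integer seed.
#' @param outcome_names Outcome columns to generate.
#' @param anchors Distributional anchors; see `cohort_anchor_defaults()`.
#' @return Cohort tibble with attribute `"outcome_truth"`.
#' @export
generate_covariates_and_outcomes <- function(ground_truth, H, seed = 1,
                                             outcome_names = c("boston_naming",
                                                               "semantic_fluency",
                                                               "phonemic_fluency"),
                                             anchors = cohort_anchor_defaults()) {
  n <- ncol(H)
  ef <- ground_truth$effects
  k <- ef$k
  set.seed(seed)
  female <- rbinom(n, 1, anchors$p_female)
  sex <- factor(ifelse(female == 1, "female", "male"),
                levels = c("female", "male"))
  draw_by_sex <- function(a) {
    x <- numeric(n)
    for (s in c("female", "male")) {
      i <- which(sex == s)
      x[i] <- rnorm_trunc(length(i), a[[s]]["mean"], a[[s]]["sd"],
                          a$range[1], a$range[2])
    }
    x
  }
  age <- draw_by_sex(anchors$age)
  education <- draw_by_sex(anchors$education)
  iqcode <- draw_by_sex(anchors$iqcode)
  # total lesion volume = tract burden + damage outside the atlas tracts;
  # the out-of-atlas exponential component keeps the volume correlated with,
  # but not a linear combination of, the atom expressions
  tract_burden <- colSums(ground_truth$W_true %*% H)
  out_of_atlas <- rexp(n, rate = 1 / max(mean(tract_burden), 1e-12))
  lesion_volume <- (tract_burden + out_of_atlas) * anchors$ml_per_voxel

  zs <- function(x) standardize_vector(x)$values
  atoms_std <- apply(t(H), 2, zs)
  X <- design_matrix_core(atoms_std, sex, zs(lesion_volume), zs(age),
                          zs(education), zs(iqcode))
  beta <- c(ef$alpha, ef$beta_atoms_female, ef$beta_atoms_male,
            ef$beta_lesion_volume, ef$beta_age, ef$beta_age_sq,
            ef$beta_education, ef$beta_iqcode, ef$beta_male, ef$beta_female)
  names(beta) <- design_term_table(k)$term
  eta <- drop(X %*% beta)
  s_signal <- stats::sd(eta)
  noise_sd <- ef$noise_sd %||% s_signal

  cohort <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    sex = sex, age = age, education_years = education,
    iqcode = iqcode, lesion_volume = lesion_volume
  )
  truth <- list()
  for (oc in outcome_names) {
    y_latent <- eta + rnorm(n, 0, noise_sd)
    sc <- anchors$outcome_scales[anchors$outcome_scales$outcome == oc, ]
    if (nrow(sc) == 0) sc <- tibble::tibble(outcome = oc, mean = 0, sd = 1)
    cohort[[oc]] <- sc$mean + sc$sd * y_latent
    s_y <- stats::sd(y_latent)
    truth[[oc]] <- list(
      beta = beta,
      beta_std = beta / s_y,
      s_y = s_y,
      noise_sd = noise_sd,
      signal_sd = s_signal,
      r2_theoretical = s_signal^2 / (s_signal^2 + noise_sd^2)
    )
  }
  cohort$complete_case <- TRUE
  attr(cohort, "outcome_truth") <- truth
  cohort
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining atlas, ground truth, expressions, optional
#' voxel masks, and the covariate/outcome table, with per-stage seeds fanned
#' out from the config seed.
#'
#' @param config A [lesion_config()].
#' @param n_patients Cohort size (default 1401, the emulated registry size).
#' @param atlas_spec Optional [synthetic_atlas_spec()].
#' @param effects Optional [effect_config()].
#' @param masks Generate voxel-level lesion masks too (default TRUE)?
#' @return List with `atlas`, `ground_truth`, `H`, `cohort`, and (optionally)
#'   `masks`.
#' @export
simulate_cohort <- function(config = lesion_config(), n_patients = 1401,
                            atlas_spec = NULL, effects = NULL, masks = TRUE) {
  spec <- atlas_spec %||% synthetic_atlas_spec(
    n_tract_pairs = (config$n_tracts - 2) %/% 2,
    n_bilateral_tracts = config$n_tracts - 2 * ((config$n_tracts - 2) %/% 2))
  atlas <- generate_atlas(spec, seed = stage_seed(config$seed, "atlas"))
  gt <- generate_ground_truth(atlas, k = config$n_atoms, effects = effects,
                              seed = stage_seed(config$seed, "truth"))
  H <- generate_expressions(gt, n_patients,
                            seed = stage_seed(config$seed, "expressions"))
  cohort <- generate_covariates_and_outcomes(
    gt, H, seed = stage_seed(config$seed, "cohort"),
    outcome_names = config$outcome_names)
  out <- list(atlas = atlas, ground_truth = gt, H = H, cohort = cohort)
  if (masks) {
    out$masks <- generate_lesion_masks(gt, atlas, H,
                                       seed = stage_seed(config$seed, "masks"))
  }
  out
}
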