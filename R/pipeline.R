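fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

write_table_csv <- function(df, path) {
  df <- dplyr::mutate(tibble::as_tibble(df),
                      dplyr::across(dplyr::where(is.numeric), fmt6))
  # list-columns (e.g. top-tract lists) are flattened for the CSV surface
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = "|")))
  readr::write_csv(df, path, progress = FALSE)
  basename(path)
}

write_matrix_csv <- function(mat, path, rowname_col) {
  df <- tibble::as_tibble(signif(mat, 6), rownames = rowname_col)
  readr::write_csv(df, path, progress = FALSE)
  basename(path)
}

#' Run the full lesion-atom pipeline
#'
#' Stages: quantify tract loads from masks, log2-stabilize, factorize into
#' atoms, normalize/order and characterize them (LI, names), correlate atom
#' expressions with outcomes and rank atoms, then fit the sex-stratified
#' Bayesian model per outcome and summarize posteriors and
#' posterior-predictive R^2. All tabular outputs are written as CSV (6
#' significant digits) plus a machine-readable JSON manifest; a fixed seed
#' and fixed inputs give byte-identical outputs.
#'
#' In synthetic mode (no `inputs`), a full synthetic study of `n_patients`
#' is generated first and its ground truth is written alongside.
#'
#' @param config A [lesion_config()].
#' @param outdir Output directory (created if needed).
#' @param inputs Optional list with `atlas_dir`, `mask_paths` and
#'   `cohort_path` for real data; `NULL` runs synthetic mode.
#' @param n_patients Cohort size for synthetic mode (default 1401).
#' @return The manifest (list), invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config, outdir, inputs = NULL, n_patients = 1401) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  outputs["config"] <- basename(write_config(config,
                                             file.path(outdir, "config.json")))

  if (is.null(inputs)) {
    sim <- simulate_cohort(config, n_patients = n_patients, masks = TRUE)
    atlas <- sim$atlas
    masks <- sim$masks
    cohort <- sim$cohort
    outputs["cohort"] <- basename(write_cohort_table(
      cohort, file.path(outdir, "cohort.csv")))
    outputs["ground_truth_W"] <- write_matrix_csv(
      sim$ground_truth$W_true, file.path(outdir, "ground_truth_W.csv"),
      "tract")
  } else {
    atlas <- read_atlas(inputs$atlas_dir)
    cohort <- read_cohort_table(inputs$cohort_path, config$outcome_names)
    masks <- lapply(inputs$mask_paths, function(p) {
      v <- read_volume(p)
      if (!identical(v$shape, atlas$grid_shape)) {
        abort(sprintf("mask grid %s does not match atlas grid: %s",
                      paste(v$shape, collapse = "x"), p))
      }
      v$data
    })
  }

  V <- lesion_load_matrix(masks, atlas, patient_ids = cohort$id)
  outputs["loads"] <- write_matrix_csv(V$values,
                                       file.path(outdir, "loads.csv"), "tract")
  Vlog <- log_stabilize(V, config$log_pseudocount)
  outputs["loads_log2"] <- write_matrix_csv(
    Vlog$values, file.path(outdir, "loads_log2.csv"), "tract")

  dec <- fit_nnmf(Vlog, k = config$n_atoms,
                  seed = stage_seed(config$seed, "nnmf"))
  dec <- normalize_and_order_atoms(dec)
  outputs["W"] <- write_matrix_csv(dec$W, file.path(outdir, "W.csv"), "tract")
  outputs["H"] <- write_matrix_csv(dec$H, file.path(outdir, "H.csv"), "atom")
  atoms <- atom_summary(dec, atlas)
  outputs["atoms"] <- write_table_csv(atoms, file.path(outdir, "atoms.csv"))

  cors <- atom_outcome_correlations(dec$H, cohort[config$outcome_names])
  outputs["correlations"] <- write_table_csv(
    cors, file.path(outdir, "correlations.csv"))
  ranking <- rank_atoms(cors)
  outputs["ranking"] <- write_table_csv(ranking,
                                        file.path(outdir, "ranking.csv"))

  r2 <- list(); convergence <- list()
  for (oc in config$outcome_names) {
    design <- build_design(cohort, dec$H, outcome = oc,
                           standardize = config$standardize)
    fit <- fit_outcome_model(design, draws = config$draws,
                             chains = config$chains, warmup = config$warmup,
                             hdi_prob = config$hdi_prob,
                             seed = stage_seed(config$seed, paste0("fit_", oc)))
    summ <- summarize_posterior(fit)
    outputs[paste0("posterior_", oc)] <- write_table_csv(
      summ, file.path(outdir, paste0("posterior_", oc, ".csv")))
    r2[[oc]] <- as.numeric(posterior_predictive_r2(
      fit, seed = stage_seed(config$seed, paste0("ppc_", oc))))
    convergence[[oc]] <- list(max_rhat = max(fit$rhat, na.rm = TRUE),
                              converged = fit$converged)
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    n_patients = ncol(V$values),
    n_tracts = nrow(V$values),
    mode = if (is.null(inputs)) "synthetic" else "real",
    nnmf = list(rel_error = fmt6(dec$rel_error),
                restart = dec$restart, iterations = dec$iterations),
    ppc_r2 = lapply(r2, fmt6),
    convergence = convergence,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
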