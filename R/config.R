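#' Run configuration for the lesion-atom pipeline
#'
#' Holds every tunable the pipeline consumes. Defaults mirror the published
#' analysis settings: 28 tracts, k = 10 atoms, 5000 posterior draws, and 80%
#' highest-density intervals.
#'
#' @param n_atoms Number of latent lesion atoms k (default 10).
#' @param n_tracts Number of atlas tracts m (default 28).
#' @param draws Post-warm-up posterior draws per chain (default 5000).
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Warm-up iterations per chain, discarded (default 1000).
#' @param hdi_prob HDI mass, strictly inside (0, 1) (default 0.80).
#' @param seed Non-negative integer global seed.
#' @param outcome_names Character vector of outcome columns to model.
#' @param log_pseudocount Pseudocount added before the log2 transform
#'   (default 1; must be positive when zero loads occur).
#' @param standardize Should continuous variables be z-scored (default TRUE)?
#' @return A `lesion_config` list.
#' @examples
#' cfg <- lesion_config(seed = 7)
#' cfg$n_atoms
#' @export
lesion_config <- function(n_atoms = 10,
                          n_tracts = 28,
                          draws = 5000,
                          chains = 4,
                          warmup = 1000,
                          hdi_prob = 0.80,
                          seed = 1,
                          outcome_names = c("boston_naming", "semantic_fluency",
                                            "phonemic_fluency"),
                          log_pseudocount = 1,
                          standardize = TRUE) {
  cfg <- list(
    n_atoms = as.integer(n_atoms),
    n_tracts = as.integer(n_tracts),
    draws = as.integer(draws),
    chains = as.integer(chains),
    warmup = as.integer(warmup),
    hdi_prob = as.numeric(hdi_prob),
    seed = as.integer(seed),
    outcome_names = as.character(outcome_names),
    log_pseudocount = as.numeric(log_pseudocount),
    standardize = isTRUE(standardize)
  )
  class(cfg) <- "lesion_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param config A `lesion_config` object.
#' @return The config, invisibly unchanged, or an error.
#' @export
validate_config <- function(config) {
  assert_scalar_number(config$n_atoms, "n_atoms", min = 1, integer = TRUE)
  assert_scalar_number(config$n_tracts, "n_tracts", min = 1, integer = TRUE)
  if (config$n_atoms > config$n_tracts) {
    abort("`n_atoms` must not exceed `n_tracts`.")
  }
  assert_scalar_number(config$draws, "draws", min = 100, integer = TRUE)
  assert_scalar_number(config$chains, "chains", min = 1, integer = TRUE)
  assert_scalar_number(config$warmup, "warmup", min = 0, integer = TRUE)
  if (config$hdi_prob <= 0 || config$hdi_prob >= 1) {
    abort("`hdi_prob` must be strictly between 0 and 1.")
  }
  assert_scalar_number(config$seed, "seed", min = 0, integer = TRUE)
  assert_scalar_number(config$log_pseudocount, "log_pseudocount", min = 0)
  if (length(config$outcome_names) < 1) abort("need at least one outcome name")
  config
}

#' Write a configuration to JSON
#'
#' @param config A `lesion_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a configuration from JSON
#'
#' Parsing a written config reproduces it field-for-field.
#'
#' @param path JSON file written by [write_config()].
#' @return A `lesion_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(lesion_config, raw)
}

#' @export
print.lesion_config <- function(x, ...) {
  cat("<lesion_config>\n")
  cat(sprintf("  tracts: %d, atoms: %d\n", x$n_tracts, x$n_atoms))
  cat(sprintf("  sampler: %d chains x %d draws (+%d warmup), %.0f%% HDI\n",
              x$chains, x$draws, x$warmup, 100 * x$hdi_prob))
  cat(sprintf("  outcomes: %s\n", paste(x$outcome_names, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
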