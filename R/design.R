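design_term_table <- function(k) {
  tibble::tibble(
    term = c("alpha",
             sprintf("atom_%02d_female", seq_len(k)),
             sprintf("atom_%02d_male", seq_len(k)),
             "lesion_volume", "age", "age_sq", "education_years", "iqcode",
             "male", "female"),
    stratum = c("shared", rep("female", k), rep("male", k),
                rep("shared", 7)),
    atom = c(NA_integer_, seq_len(k), seq_len(k), rep(NA_integer_, 7)),
    prior_scale = c(1, rep(1, 2 * k), 1, 10, 10, 5, 1, 1, 1)
  )
}

# Assemble the model design matrix from already z-scored inputs.
# Atom expressions are standardized over the whole sample, then gated by the
# sex indicators so each atom carries one female and one male slope. age^2 is
# built from standardized age and itself re-standardized so its prior scale
# stays meaningful.
design_matrix_core <- function(atoms_std, sex, lesion_volume_std, age_std,
                               education_std, iqcode_std) {
  n <- length(sex)
  k <- ncol(atoms_std)
  female <- as.numeric(sex == "female")
  male <- 1 - female
  age_sq <- standardize_vector(age_std^2)$values
  X <- cbind(
    alpha = rep(1, n),
    atoms_std * female,
    atoms_std * male,
    lesion_volume = lesion_volume_std,
    age = age_std,
    age_sq = age_sq,
    education_years = education_std,
    iqcode = iqcode_std,
    male = male,
    female = female
  )
  dimnames(X) <- list(NULL, design_term_table(k)$term)
  X
}

#' Build the standardized design matrix and outcome for the Bayesian model
#'
#' Drops incomplete rows (with a message), z-scores every continuous
#' predictor and the outcome over the retained sample, forms the sex-gated
#' atom columns, the squared-age term, and the male/female indicator columns
#' of the model.
#'
#' @param cohort Cohort tibble (see [read_cohort_table()]).
#' @param H k x n atom-expression matrix, columns aligned to cohort rows.
#' @param outcome Name of the outcome column to model.
#' @param standardize Z-score continuous variables (default TRUE, as in the
#'   published analysis).
#' @return An `outcome_design`: list with `X` (n x p), `y`, `terms` (term
#'   table with prior scales), `sex`, `y_center`/`y_scale` for inverse
#'   transform, `n_dropped`, and `kept` row indices.
#' @export
build_design <- function(cohort, H, outcome = "boston_naming",
                         standardize = TRUE) {
  if (ncol(H) != nrow(cohort)) {
    abort("H must have one column per cohort row")
  }
  if (!outcome %in% names(cohort)) {
    abort(sprintf("outcome column '%s' not found in cohort", outcome))
  }
  k <- nrow(H)
  need <- c("sex", "age", "education_years", "iqcode", "lesion_volume",
            outcome)
  keep <- stats::complete.cases(cohort[, need])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("build_design: dropped %d incomplete row(s)", n_dropped))
  }
  cc <- cohort[keep, ]
  n <- nrow(cc)
  p <- 2 * k + 8
  if (n < 2 * p) {
    abort(sprintf("insufficient complete cases: %d rows for %d parameters",
                  n, p))
  }
  zs <- function(x) if (standardize) standardize_vector(x)$values else x
  atoms_std <- apply(t(H[, keep, drop = FALSE]), 2, zs)
  X <- design_matrix_core(atoms_std, cc$sex,
                          zs(cc$lesion_volume), zs(cc$age),
                          zs(cc$education_years), zs(cc$iqcode))
  y_raw <- cc[[outcome]]
  if (standardize) {
    ys <- standardize_vector(y_raw)
    y <- ys$values; y_center <- ys$center; y_scale <- ys$scale
  } else {
    y <- y_raw; y_center <- 0; y_scale <- 1
  }
  structure(list(
    X = X, y = y, terms = design_term_table(k), sex = cc$sex,
    outcome = outcome, y_center = y_center, y_scale = y_scale,
    n_dropped = n_dropped, kept = which(keep)
  ), class = "outcome_design")
}

#' @export
print.outcome_design <- function(x, ...) {
  cat(sprintf("<outcome_design> %d patients x %d terms, outcome '%s'\n",
              nrow(x$X), ncol(x$X), x$outcome))
  invisible(x)
}
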