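cohort_required_cols <- function(outcome_names) {
  c("id", "sex", "age", "education_years", "iqcode", "lesion_volume",
    outcome_names)
}

#' Read a per-patient cohort table
#'
#' Expects headered delimited text with one row per patient: `id`, `sex`
#' (female/male), `age`, `education_years`, `iqcode`, `lesion_volume`, and one
#' column per named outcome. Rows with any missing required field are kept but
#' flagged in `complete_case`; the outcome model later drops them with a
#' logged count.
#'
#' @param path CSV file path.
#' @param outcome_names Character vector of outcome columns that must exist.
#' @return A tibble with `sex` parsed to a two-level factor
#'   (`female`, `male`) and a logical `complete_case` column.
#' @export
read_cohort_table <- function(path,
                              outcome_names = c("boston_naming",
                                                "semantic_fluency",
                                                "phonemic_fluency")) {
  if (!file.exists(path)) abort(sprintf("cohort table not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tbl, outcome_names)
}

#' Validate (and type) an in-memory cohort table
#'
#' @param tbl A data frame of patients.
#' @param outcome_names Outcome columns that must be present and numeric.
#' @return A typed tibble with `complete_case` flag.
#' @export
validate_cohort <- function(tbl, outcome_names) {
  req <- cohort_required_cols(outcome_names)
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  sex_chr <- tolower(as.character(tbl$sex))
  bad_sex <- which(!is.na(sex_chr) & !sex_chr %in% c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(sprintf("sex column has unrecognized label(s) at row(s) %s (expected female/male)",
                  paste(utils::head(bad_sex, 5), collapse = ", ")))
  }
  num_cols <- setdiff(req, c("id", "sex"))
  for (cl in num_cols) {
    v <- tbl[[cl]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value in column '%s' at row %d", cl, bad[1]))
      }
      v <- parsed
    }
    if (!is.numeric(v)) abort(sprintf("column '%s' must be numeric", cl))
    tbl[[cl]] <- as.numeric(v)
  }
  out <- tibble::as_tibble(tbl)
  out$sex <- factor(sex_chr, levels = c("female", "male"))
  out$complete_case <- stats::complete.cases(out[, req])
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- cohort
  out$complete_case <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
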