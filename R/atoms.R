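#' Lateralization index of an atom's tract loadings
#'
#' `LI = (L - R) / (L + R)` where `L` and `R` are the summed loadings over
#' left- and right-hemisphere tracts. Bilateral tracts are excluded from
#' both sums. Positive values indicate left dominance; the index lies in
#' \[-1, 1\].
#'
#' @param w Non-negative loading vector (one `W` column).
#' @param hemisphere Per-tract labels in `L`/`R`/`bilateral`.
#' @return A single LI value.
#' @export
lateralization_index <- function(w, hemisphere) {
  stopifnot(length(w) == length(hemisphere))
  if (any(w < 0)) abort("atom loadings must be non-negative")
  L <- sum(w[hemisphere == "L"])
  R <- sum(w[hemisphere == "R"])
  if (L + R == 0) {
    abort("lateralization index undefined: no weight on lateralized tracts")
  }
  (L - R) / (L + R)
}

#' Name an atom by its highest-weighted tracts
#'
#' @param w Loading vector (one `W` column).
#' @param tract_names Tract identifiers aligned with `w`.
#' @param top_n How many tracts to report (default 3). Ties are broken by
#'   tract index (lower index first).
#' @return Character vector of the `top_n` tract names, descending weight.
#' @export
name_atom <- function(w, tract_names, top_n = 3) {
  stopifnot(top_n >= 1, length(w) == length(tract_names))
  ord <- order(-w, seq_along(w))
  tract_names[ord[seq_len(min(top_n, length(w)))]]
}

#' Summarize atoms: lateralization and dominant tracts
#'
#' @param decomposition An `atom_decomposition` (ideally after
#'   [normalize_and_order_atoms()]).
#' @param atlas The `tract_atlas` the load matrix was built against.
#' @param top_n Tracts per atom name (default 3).
#' @return Tibble with `atom`, `li`, `name` (dominant tracts joined by
#'   `" + "`), and a `top_tracts` list-column.
#' @export
atom_summary <- function(decomposition, atlas, top_n = 3) {
  W <- decomposition$W
  purrr::map_dfr(seq_len(ncol(W)), function(a) {
    w <- W[, a]
    li <- if (sum(w[atlas$hemisphere != "bilateral"]) > 0) {
      lateralization_index(w, atlas$hemisphere)
    } else NA_real_
    top <- name_atom(w, atlas$tract_names, top_n)
    tibble::tibble(atom = a, li = li,
                   name = paste(top, collapse = " + "),
                   top_tracts = list(top))
  })
}

#' Pearson correlations between atom expressions and outcomes
#'
#' One correlation per (atom, outcome) pair, on pairwise-complete
#' observations. Zero-variance pairs yield `NA` with a warning rather than
#' an error. Expressions and outcomes enter unadjusted, matching the
#' descriptive ranking stage of the analysis.
#'
#' @param H k x n expression matrix (or an `atom_decomposition`).
#' @param outcomes Data frame of outcome columns, rows aligned to patients.
#' @return Tibble with `atom`, `outcome`, `r`, and `n_used`.
#' @export
atom_outcome_correlations <- function(H, outcomes) {
  if (inherits(H, "atom_decomposition")) H <- H$H
  outcomes <- tibble::as_tibble(outcomes)
  if (ncol(H) != nrow(outcomes)) {
    abort("outcomes must have one row per H column")
  }
  purrr::map_dfr(seq_len(nrow(H)), function(a) {
    purrr::map_dfr(names(outcomes), function(oc) {
      x <- H[a, ]; y <- outcomes[[oc]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        warn(sprintf("fewer than 3 complete pairs for atom %d ~ %s", a, oc))
        r <- NA_real_
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warn(sprintf("zero variance for atom %d ~ %s; correlation set to NA",
                     a, oc))
        r <- NA_real_
      } else {
        r <- stats::cor(x[ok], y[ok])
      }
      tibble::tibble(atom = a, outcome = oc, r = r, n_used = sum(ok))
    })
  })
}

#' Rank atoms by summed absolute outcome correlations
#'
#' The clinical-relevance score of an atom is the sum of `|r|` over all
#' outcomes (missing correlations contribute 0). Atoms are ranked in
#' descending score order; ties are broken by atom index.
#'
#' @param correlations Tibble from [atom_outcome_correlations()].
#' @return Tibble with `atom`, `score`, `rank`, ordered by rank.
#' @export
rank_atoms <- function(correlations) {
  if (nrow(correlations) == 0) abort("empty correlation table")
  correlations |>
    dplyr::group_by(.data$atom) |>
    dplyr::summarise(score = sum(abs(.data$r), na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$atom) |>
    dplyr::mutate(rank = dplyr::row_number())
}
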