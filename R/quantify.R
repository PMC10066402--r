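#' Compute per-tract lesion loads for one patient
#'
#' The lesion load of a tract is the atlas-weighted count of lesioned voxels
#' falling inside its map: `load_t = sum_v weight_t(v) * mask(v)`. For binary
#' maps this is the overlap voxel count, the convention of the tract-wise
#' lesion-load literature.
#'
#' @param mask Binary 3-D array on the atlas grid, or an integer vector of
#'   lesioned voxel linear indices.
#' @param atlas A [tract_atlas()].
#' @return Named numeric vector of length m (one load per tract).
#' @export
compute_tract_loads <- function(mask, atlas) {
  if (is.array(mask)) {
    if (!identical(dim(mask), as.integer(atlas$grid_shape))) {
      abort(sprintf("mask grid %s does not match atlas grid %s",
                    paste(dim(mask), collapse = "x"),
                    paste(atlas$grid_shape, collapse = "x")))
    }
    if (!is_binary(mask)) abort("mask must be binary (values in {0, 1})")
    loads <- vapply(atlas$maps, function(m) {
      sum(m$weights * mask[m$voxels])
    }, numeric(1))
  } else {
    idx <- as.integer(mask)
    if (length(idx) > 0 &&
        (min(idx) < 1 || max(idx) > prod(atlas$grid_shape))) {
      abort("mask voxel indices fall outside the atlas grid")
    }
    loads <- vapply(atlas$maps, function(m) {
      sum(m$weights[m$voxels %in% idx])
    }, numeric(1))
  }
  names(loads) <- atlas$tract_names
  loads
}

#' Build the tracts-by-patients lesion-load matrix V
#'
#' @param masks List of n patient masks (arrays or voxel-index vectors).
#' @param atlas A `tract_atlas`.
#' @param patient_ids Optional patient identifiers (default `P0001`...).
#' @return A `lesion_load_matrix`: list with `values` (m x n matrix),
#'   `tract_names`, `patient_ids`, and `transformed` flag.
#' @export
lesion_load_matrix <- function(masks, atlas, patient_ids = NULL) {
  n <- length(masks)
  ids <- patient_ids %||% sprintf("P%04d", seq_len(n))
  stopifnot(length(ids) == n)
  values <- vapply(masks, compute_tract_loads, numeric(n_tracts(atlas)),
                   atlas = atlas)
  values <- matrix(values, nrow = n_tracts(atlas),
                   dimnames = list(atlas$tract_names, ids))
  new_load_matrix(values, transformed = FALSE)
}

new_load_matrix <- function(values, transformed) {
  if (any(values < 0)) abort("lesion loads must be non-negative")
  structure(list(values = values,
                 tract_names = rownames(values),
                 patient_ids = colnames(values),
                 transformed = transformed),
            class = "lesion_load_matrix")
}

#' @export
print.lesion_load_matrix <- function(x, ...) {
  cat(sprintf("<lesion_load_matrix> %d tracts x %d patients (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "log2-stabilized" else "raw counts"))
  invisible(x)
}

#' Tidy a lesion-load matrix into long format
#'
#' @param x A `lesion_load_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `tract`, `patient`, `load`.
#' @export
tidy.lesion_load_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "tract") |>
    tidyr::pivot_longer(-"tract", names_to = "patient", values_to = "load")
}

#' Log2-stabilize a lesion-load matrix
#'
#' Applies `log2(pseudocount + load)` entrywise. The transform is strictly
#' monotone, so per-tract patient orderings are preserved. Zero loads are
#' common, hence the default pseudocount of 1.
#'
#' @param V A raw `lesion_load_matrix` (or plain non-negative matrix).
#' @param pseudocount Non-negative offset; must be positive if any load is 0.
#' @return A `lesion_load_matrix` flagged as transformed.
#' @export
log_stabilize <- function(V, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", min = 0)
  vals <- if (inherits(V, "lesion_load_matrix")) V$values else as.matrix(V)
  if (any(vals < 0)) abort("lesion loads must be non-negative")
  if (pseudocount == 0 && any(vals == 0)) {
    abort("zero loads present: `pseudocount` must be positive")
  }
  out <- log2(pseudocount + vals)
  if (inherits(V, "lesion_load_matrix")) {
    if (isTRUE(V$transformed)) warn("load matrix is already log-stabilized")
    dimnames(out) <- dimnames(V$values)
  }
  new_load_matrix(out, transformed = TRUE)
}

#' Z-score the continuous columns of a table
#'
#' Mean-centres to zero and scales each selected column to unit sample
#' standard deviation (n - 1 denominator). The per-column centre and scale
#' are stored so the transform is exactly invertible.
#'
#' @param data A data frame.
#' @param cols Character vector of columns to standardize (default: all
#'   numeric columns).
#' @return A tibble with the selected columns replaced by their z-scores and
#'   an attribute `"standardization"`: a tibble of (`variable`, `center`,
#'   `scale`).
#' @export
standardize_columns <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
  out <- tibble::as_tibble(data)
  info <- tibble::tibble(variable = cols, center = NA_real_, scale = NA_real_)
  for (i in seq_along(cols)) {
    v <- out[[cols[i]]]
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("column '%s' is constant: cannot standardize", cols[i]))
    }
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    info$center[i] <- mu
    info$scale[i] <- s
    out[[cols[i]]] <- (v - mu) / s
  }
  attr(out, "standardization") <- info
  out
}

#' Invert a standardization
#'
#' @param data Tibble returned by [standardize_columns()] (or any data frame,
#'   with `info` supplied).
#' @param info Standardization tibble; defaults to the attribute stored on
#'   `data`.
#' @return Tibble on the original scale.
#' @export
unstandardize_columns <- function(data, info = attr(data, "standardization")) {
  if (is.null(info)) abort("no standardization info available")
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(info))) {
    v <- info$variable[i]
    out[[v]] <- out[[v]] * info$scale[i] + info$center[i]
  }
  attr(out, "standardization") <- NULL
  out
}

standardize_vector <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardize a constant vector")
  list(values = (x - mean(x)) / s, center = mean(x), scale = s)
}
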