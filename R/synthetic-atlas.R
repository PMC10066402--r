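#' Construct a tract atlas
#'
#' The atlas holds per-tract spatial maps on one shared voxel grid, a
#' hemisphere label per tract (`L`, `R`, or `bilateral`), and the left/right
#' homolog pairing used by the lateralization index. Maps may be binary or
#' probabilistic (weights in \[0, 1\]); internally they are stored sparsely as
#' voxel indices plus weights.
#'
#' @param maps List of m maps; each either a 3-D array of weights in \[0,1\]
#'   or a list `list(voxels = <linear indices>, weights = <numeric>)`.
#' @param tract_names Character vector of m unique tract identifiers.
#' @param hemisphere Character vector of m labels in `L`/`R`/`bilateral`.
#' @param pairs Two-column data frame (`left`, `right`) of homolog indices.
#' @param grid_shape Integer vector of length 3.
#' @return A `tract_atlas` object.
#' @export
tract_atlas <- function(maps, tract_names, hemisphere, pairs, grid_shape) {
  m <- length(maps)
  stopifnot(m >= 1, length(tract_names) == m, length(hemisphere) == m,
            length(grid_shape) == 3)
  if (anyDuplicated(tract_names)) abort("tract names must be unique")
  if (!all(hemisphere %in% c("L", "R", "bilateral"))) {
    abort("hemisphere labels must be 'L', 'R' or 'bilateral'")
  }
  sparse <- lapply(maps, function(mp) {
    if (is.array(mp)) {
      if (!identical(dim(mp), as.integer(grid_shape))) {
        abort("map grid shape does not match atlas grid")
      }
      idx <- which(mp > 0)
      list(voxels = idx, weights = as.numeric(mp[idx]))
    } else {
      list(voxels = as.integer(mp$voxels), weights = as.numeric(mp$weights))
    }
  })
  for (s in sparse) {
    if (any(s$weights < 0 | s$weights > 1)) {
      abort("atlas map weights must lie in [0, 1]")
    }
  }
  if (anyDuplicated(pairs$left) || anyDuplicated(pairs$right)) {
    abort("each tract may appear in at most one homolog pair")
  }
  structure(list(
    tract_names = as.character(tract_names),
    hemisphere = as.character(hemisphere),
    maps = sparse,
    pairs = tibble::as_tibble(pairs),
    grid_shape = as.integer(grid_shape)
  ), class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat(sprintf("<tract_atlas> %d tracts on %s grid (%d L, %d R, %d bilateral)\n",
              length(x$tract_names), paste(x$grid_shape, collapse = "x"),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              sum(x$hemisphere == "bilateral")))
  invisible(x)
}

n_tracts <- function(atlas) length(atlas$tract_names)

tract_voxel_counts <- function(atlas) {
  vapply(atlas$maps, function(m) length(m$voxels), integer(1))
}

#' Specification for a synthetic paired left/right atlas
#'
#' Defaults give 13 homolog pairs plus 2 bilateral tracts = 28 tracts on a
#' 32x32x16 grid, mimicking a 28-tract white-matter reference atlas. Left
#' tracts live strictly in the left half of the first grid axis and each
#' right tract is the mirror image of its left homolog across the
#' mid-sagittal plane.
#'
#' @param grid_shape Voxel grid dimensions (length 3).
#' @param n_tract_pairs Number of left/right homolog pairs.
#' @param n_bilateral_tracts Number of mirror-symmetric bilateral tracts.
#' @param tract_size Voxels per tract.
#' @return A `synthetic_atlas_spec` list.
#' @export
synthetic_atlas_spec <- function(grid_shape = c(32, 32, 16),
                                 n_tract_pairs = 13,
                                 n_bilateral_tracts = 2,
                                 tract_size = 150) {
  spec <- list(grid_shape = as.integer(grid_shape),
               n_tract_pairs = as.integer(n_tract_pairs),
               n_bilateral_tracts = as.integer(n_bilateral_tracts),
               tract_size = as.integer(tract_size))
  stopifnot(all(spec$grid_shape >= 2), spec$n_tract_pairs >= 1,
            spec$n_bilateral_tracts >= 0, spec$tract_size >= 2)
  class(spec) <- "synthetic_atlas_spec"
  spec
}

default_pair_names <- function(n) {
  canon <- c("arcuate_long", "arcuate_anterior", "arcuate_posterior",
             "uncinate", "ifof", "ilf", "cingulum", "fornix",
             "cst", "internal_capsule", "cortico_pontine_cerebellar",
             "optic_radiation", "inferior_cerebellar_peduncle")
  if (n <= length(canon)) canon[seq_len(n)] else
    c(canon, sprintf("tract_pair_%02d", seq_len(n - length(canon))))
}

default_bilateral_names <- function(n) {
  canon <- c("corpus_callosum", "middle_cerebellar_peduncle")
  if (n <= length(canon)) canon[seq_len(n)] else
    c(canon, sprintf("bilateral_tract_%02d", seq_len(n - length(canon))))
}

#' Mirror voxel linear indices across the mid-sagittal plane
#'
#' Reflection is across the first grid axis; on an odd-sized axis the
#' mid-plane column maps to itself and is assigned to neither hemisphere.
#'
#' @param idx Integer linear voxel indices.
#' @param grid_shape Grid dimensions.
#' @return Mirrored linear indices.
#' @export
mirror_voxels <- function(idx, grid_shape) {
  coords <- arrayInd(idx, .dim = grid_shape)
  coords[, 1] <- grid_shape[1] + 1L - coords[, 1]
  as.integer(coords[, 1] +
               grid_shape[1] * (coords[, 2] - 1L) +
               grid_shape[1] * grid_shape[2] * (coords[, 3] - 1L))
}

#' Generate a synthetic mirror-symmetric tract atlas
#'
#' Tracts are pairwise disjoint binary voxel sets: left tracts are sampled in
#' the left half-grid, right tracts are their exact mirror images, and
#' bilateral tracts are self-mirrored voxel sets straddling both halves.
#' Disjointness makes tract-load quantification exactly invertible, which the
#' recovery tests exploit.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @param seed Integer seed.
#' @return A `tract_atlas`.
#' @export
generate_atlas <- function(spec = synthetic_atlas_spec(), seed = 1) {
  gs <- spec$grid_shape
  half_x <- gs[1] %/% 2L
  left_pool <- which(slice.index(array(0, gs), 1) <= half_x)
  need <- spec$n_tract_pairs * spec$tract_size +
    spec$n_bilateral_tracts * ceiling(spec$tract_size / 2)
  if (need > length(left_pool)) {
    abort(sprintf(
      "requested tract volumes (%d voxels) exceed half-grid capacity (%d)",
      need, length(left_pool)))
  }
  set.seed(seed)

  pool <- sample(left_pool, need, replace = FALSE)
  pos <- 0L
  maps <- list(); names_v <- character(0); hemi <- character(0)
  pair_left <- integer(0); pair_right <- integer(0)
  pnames <- default_pair_names(spec$n_tract_pairs)
  for (p in seq_len(spec$n_tract_pairs)) {
    lv <- sort(pool[pos + seq_len(spec$tract_size)])
    pos <- pos + spec$tract_size
    rv <- sort(mirror_voxels(lv, gs))
    maps <- c(maps, list(list(voxels = lv, weights = rep(1, length(lv))),
                         list(voxels = rv, weights = rep(1, length(rv)))))
    names_v <- c(names_v, paste0(pnames[p], "_L"), paste0(pnames[p], "_R"))
    hemi <- c(hemi, "L", "R")
    pair_left <- c(pair_left, length(names_v) - 1L)
    pair_right <- c(pair_right, length(names_v))
  }
  bnames <- default_bilateral_names(spec$n_bilateral_tracts)
  for (b in seq_len(spec$n_bilateral_tracts)) {
    nb <- ceiling(spec$tract_size / 2)
    lv <- pool[pos + seq_len(nb)]
    pos <- pos + nb
    bv <- sort(unique(c(lv, mirror_voxels(lv, gs))))
    maps <- c(maps, list(list(voxels = bv, weights = rep(1, length(bv)))))
    names_v <- c(names_v, bnames[b])
    hemi <- c(hemi, "bilateral")
  }
  tract_atlas(maps, names_v, hemi,
              tibble::tibble(left = pair_left, right = pair_right), gs)
}

#' Write an atlas as per-tract NIfTI volumes plus a JSON manifest
#'
#' @param atlas A `tract_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_tracts(atlas))
  for (t in seq_len(n_tracts(atlas))) {
    arr <- array(0, atlas$grid_shape)
    arr[atlas$maps[[t]]$voxels] <- atlas$maps[[t]]$weights
    files[t] <- file.path(dir, paste0(atlas$tract_names[t], ".nii.gz"))
    write_volume(arr, files[t])
  }
  meta <- list(tract_names = atlas$tract_names, hemisphere = atlas$hemisphere,
               pairs = atlas$pairs, grid_shape = atlas$grid_shape,
               files = basename(files))
  jsonlite::write_json(meta, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param dir Directory containing `atlas.json` and per-tract volumes.
#' @return A `tract_atlas`.
#' @export
read_atlas <- function(dir) {
  meta_path <- file.path(dir, "atlas.json")
  if (!file.exists(meta_path)) abort(sprintf("no atlas.json in %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  maps <- lapply(meta$files, function(f) read_volume(file.path(dir, f))$data)
  tract_atlas(maps, meta$tract_names, meta$hemisphere,
              tibble::as_tibble(meta$pairs), meta$grid_shape)
}
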