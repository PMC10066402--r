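nndsvd_init <- function(V, k) {
  # non-negative double SVD (deterministic); 'a' variant fills the
  # sign-split zeros with the matrix mean so no atom starts dead
  sv <- svd(V, nu = k, nv = k)
  m <- nrow(V); n <- ncol(V)
  W <- matrix(0, m, k); H <- matrix(0, k, n)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
      nyp <- sqrt(sum(yp^2)); nyn <- sqrt(sum(yn^2))
      mp <- nxp * nyp; mn <- nxn * nyn
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(sv$d[j] * mp) * xp / nxp
        H[j, ] <- sqrt(sv$d[j] * mp) * yp / nyp
      } else if (mn > 0) {
        W[, j] <- sqrt(sv$d[j] * mn) * xn / nxn
        H[j, ] <- sqrt(sv$d[j] * mn) * yn / nyn
      }
    }
  }
  avg <- mean(V)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

# Hierarchical alternating least squares: exact non-negative coordinate
# minimization per atom row/column, so the objective is non-increasing and
# converges much faster near the optimum than multiplicative updates.
hals_iterate <- function(V, W, H, tol, max_iter) {
  eps <- 1e-12
  k <- ncol(W)
  obj <- numeric(max_iter)
  prev <- frobenius(V - W %*% H)^2
  for (it in seq_len(max_iter)) {
    WtV <- crossprod(W, V)
    WtW <- crossprod(W)
    for (j in seq_len(k)) {
      d <- WtW[j, j]
      if (d < eps) next
      H[j, ] <- pmax(0, H[j, ] + (WtV[j, ] - WtW[j, ] %*% H) / d)
    }
    VHt <- tcrossprod(V, H)
    HHt <- tcrossprod(H)
    for (j in seq_len(k)) {
      d <- HHt[j, j]
      if (d < eps) next
      W[, j] <- pmax(0, W[, j] + (VHt[, j] - W %*% HHt[, j]) / d)
    }
    cur <- frobenius(V - W %*% H)^2
    obj[it] <- cur
    if (prev > 0 && (prev - cur) / prev < tol) {
      obj <- obj[seq_len(it)]
      break
    }
    prev <- cur
  }
  list(W = W, H = H, objective = obj, iterations = length(obj))
}

#' Factorize a lesion-load matrix into non-negative lesion atoms
#'
#' Approximates `V ~ W H` with `W` (tracts x k) and `H` (k x patients)
#' entrywise non-negative, minimizing the Frobenius reconstruction error by
#' hierarchical alternating least squares. The first run starts from a deterministic
#' non-negative double-SVD initialization; further restarts are random, and
#' the best objective is kept. Within a run the objective is non-increasing.
#'
#' @param V A `lesion_load_matrix` (typically log2-stabilized) or a plain
#'   non-negative matrix.
#' @param k Number of atoms, `1 <= k <= min(m, n)`.
#' @param seed Integer seed for the random restarts.
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param max_iter Maximum update iterations per run (default 2000).
#' @param n_restarts Number of runs (default 5; first is deterministic).
#' @return An `atom_decomposition`: `W`, `H`, `recon_error` (Frobenius norm
#'   of `V - WH`), `rel_error`, per-run objectives, and bookkeeping.
#' @export
fit_nnmf <- function(V, k, seed = 1, tol = 1e-6, max_iter = 2000,
                     n_restarts = 5) {
  vals <- if (inherits(V, "lesion_load_matrix")) V$values else as.matrix(V)
  if (any(vals < 0)) abort("V must be entrywise non-negative")
  m <- nrow(vals); n <- ncol(vals)
  assert_scalar_number(k, "k", min = 1, max = min(m, n), integer = TRUE)
  normV <- frobenius(vals)
  if (normV == 0) {
    dec <- list(W = matrix(0, m, k), H = matrix(0, k, n),
                recon_error = 0, rel_error = 0,
                objective = 0, iterations = 0L, restart = 1L,
                restart_objectives = rep(0, n_restarts), k = as.integer(k),
                tract_names = rownames(vals), patient_ids = colnames(vals))
    class(dec) <- "atom_decomposition"
    return(dec)
  }
  set.seed(seed)
  best <- NULL
  restart_obj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1) {
      nndsvd_init(vals, k)
    } else {
      scale0 <- sqrt(mean(vals) / k)
      list(W = matrix(runif(m * k, 0, 2 * scale0), m, k),
           H = matrix(runif(k * n, 0, 2 * scale0), k, n))
    }
    run <- hals_iterate(vals, init$W, init$H, tol, max_iter)
    restart_obj[r] <- run$objective[run$iterations]
    if (is.null(best) || restart_obj[r] < best$objective[best$iterations]) {
      best <- run
      best$restart <- r
    }
  }
  W <- best$W; H <- best$H
  dimnames(W) <- list(rownames(vals), sprintf("atom_%02d", seq_len(k)))
  dimnames(H) <- list(colnames(W), colnames(vals))
  err <- frobenius(vals - W %*% H)
  dec <- list(W = W, H = H, recon_error = err, rel_error = err / normV,
              objective = best$objective, iterations = best$iterations,
              restart = best$restart, restart_objectives = restart_obj,
              k = as.integer(k),
              tract_names = rownames(vals), patient_ids = colnames(vals))
  class(dec) <- "atom_decomposition"
  dec
}

#' @export
print.atom_decomposition <- function(x, ...) {
  cat(sprintf("<atom_decomposition> %d tracts x %d atoms x %d patients\n",
              nrow(x$W), x$k, ncol(x$H)))
  cat(sprintf("  relative Frobenius error: %.3g (restart %d, %d iterations)\n",
              x$rel_error, x$restart, x$iterations))
  invisible(x)
}

#' Resolve scale ambiguity and order atoms by expression variance
#'
#' Rescales each basis column of `W` to unit Euclidean norm, absorbing the
#' inverse scale into the matching row of `H` (so `W %*% H` is unchanged),
#' then reorders atoms by descending variance of their expression rows.
#' All-zero atoms trigger a warning and are ordered last.
#'
#' @param decomposition An `atom_decomposition`.
#' @return The decomposition with unit-norm `W` columns, reordered atoms and
#'   an `atom_order` permutation recording the applied ordering.
#' @export
normalize_and_order_atoms <- function(decomposition) {
  W <- decomposition$W; H <- decomposition$H
  norms <- sqrt(colSums(W^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero atom(s); ordered last", sum(zero)))
  }
  nz <- which(!zero)
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2, norms[nz], "/")
  H[nz, ] <- sweep(H[nz, , drop = FALSE], 1, norms[nz], "*")
  rv <- apply(H, 1, stats::var)
  rv[zero] <- -Inf
  ord <- order(rv, decreasing = TRUE)
  decomposition$W <- W[, ord, drop = FALSE]
  decomposition$H <- H[ord, , drop = FALSE]
  colnames(decomposition$W) <- sprintf("atom_%02d", seq_len(ncol(W)))
  rownames(decomposition$H) <- colnames(decomposition$W)
  decomposition$atom_order <- ord
  decomposition$normalized <- TRUE
  decomposition
}
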