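# Pressure projection on the mapped grid.
#
# The divergence of a cell is expressed through contravariant volume fluxes:
# Qx = u * (face height) through x-faces and Qz = dx * (w - u dz/dx) through
# sigma-faces. Correcting the fluxes themselves with face-coefficient
# pressure differences makes the projection operator a symmetric 5-point
# variable-coefficient Laplacian (SPD with the p = 0 surface condition), so
# a cached sparse Cholesky factorisation can be reused while the grid
# deforms, refreshed only when the deformation since the last factorisation
# exceeds `refactor_tol`, with iterative refinement in between.

# Build the solver environment for a given grid size. The sparsity pattern
# is fixed; only the numeric values change as the grid deforms.
poisson_env <- function(N_i, N_k) {
  n <- N_i * N_k
  idx <- function(i, k) i + (k - 1L) * N_i
  ii <- integer(0); jj <- integer(0); slot <- integer(0)
  # slot ids: 1..n diag; n + (1..nax) x-couplings; then z-couplings
  # x-faces between (i,k) and (i+1,k), i = 1..N_i-1
  gx <- expand.grid(i = seq_len(N_i - 1L), k = seq_len(N_k))
  nax <- nrow(gx)
  # z-faces between (i,k) and (i,k+1), k = 1..N_k-1
  gz <- expand.grid(i = seq_len(N_i), k = seq_len(N_k - 1L))
  naz <- nrow(gz)
  tri_i <- c(seq_len(n),                      # diagonal
             idx(gx$i, gx$k), idx(gx$i + 1L, gx$k),
             idx(gz$i, gz$k), idx(gz$i, gz$k + 1L))
  tri_j <- c(seq_len(n),
             idx(gx$i + 1L, gx$k), idx(gx$i, gx$k),
             idx(gz$i, gz$k + 1L), idx(gz$i, gz$k))
  A0 <- Matrix::sparseMatrix(i = tri_i, j = tri_j,
                             x = seq_along(tri_i) * 0 + 1,
                             dims = c(n, n))
  # map each triplet to its position in A0@x (column-compressed order)
  keys <- integer(length(A0@i))
  pcol <- rep(seq_len(n), diff(A0@p))
  keys <- (A0@i + 1) + (pcol - 1) * n
  tri_key <- tri_i + (tri_j - 1) * n
  pos <- match(tri_key, keys)
  env <- new.env(parent = emptyenv())
  env$N_i <- N_i; env$N_k <- N_k; env$n <- n
  env$A <- A0
  env$pos <- pos
  env$nax <- nax; env$naz <- naz
  env$chol <- NULL
  env$hg_fact <- NULL; env$h_fact <- NULL
  env
}

# Assemble coefficient values and (if `refactor`) refresh the factorisation.
# ax: N_i-1 x N_k (interior x-face weights), az: N_i x N_k-1 (interior
# z-face weights), az_top: N_i (surface Dirichlet closure).
poisson_assemble <- function(env, ax, az, az_top, refactor = TRUE) {
  N_i <- env$N_i; N_k <- env$N_k
  diagv <- matrix(0, N_i, N_k)
  diagv[-N_i, ] <- diagv[-N_i, ] + ax
  diagv[-1L, ] <- diagv[-1L, ] + ax
  diagv[, -N_k] <- diagv[, -N_k] + az
  diagv[, -1L] <- diagv[, -1L] + az
  diagv[, N_k] <- diagv[, N_k] + az_top
  vals <- c(as.numeric(diagv),
            -as.numeric(ax), -as.numeric(ax),
            -as.numeric(az), -as.numeric(az))
  x <- numeric(length(env$A@x))
  x[env$pos] <- vals      # every (i, j) pair appears exactly once
  env$A@x <- x
  env$Asym <- Matrix::forceSymmetric(env$A)
  if (is.null(env$chol)) {
    env$chol <- Matrix::Cholesky(env$Asym, LDL = FALSE)
  } else if (refactor) {
    env$chol <- Matrix::update(env$chol, env$Asym)
  }
  invisible(env)
}

# Solve A p = b with the cached factor plus iterative refinement against the
# current operator (guards against a slightly stale factorisation).
poisson_solve <- function(env, b, tol = 1e-11, max_refine = 30L) {
  x <- as.numeric(Matrix::solve(env$chol, b, system = "A"))
  sc <- max(abs(b), 1e-300)
  for (i in seq_len(max_refine)) {
    r <- b - as.numeric(env$Asym %*% x)
    if (max(abs(r)) <= tol * sc) break
    x <- x + as.numeric(Matrix::solve(env$chol, r, system = "A"))
  }
  x
}
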