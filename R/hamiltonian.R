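# Hamiltonian assembly over a CSF basis.
#
# H = sum_ij t_ij E_ij + 1/2 sum_ijkl V_ijkl e_ij,kl, with e_ij,kl built
# from products of the cached one-body generator matrices.  Assembled
# matrices are cached on the integral set keyed by the sector.

sector_key <- function(space) {
  paste(space$n_orbitals, space$n_electrons, space$twice_S, sep = ":")
}

#' Hamiltonian matrix over a CSF basis
#'
#' @param integrals An [integral_set()].
#' @param drt A [build_drt()] for a sector with matching orbital count.
#' @return Sparse symmetric Hamiltonian (`dgCMatrix`), including the core
#'   energy on the diagonal.
#' @export
build_hamiltonian <- function(integrals, drt) {
  assert_integral_set(integrals)
  assert_drt(drt)
  n <- integrals$n_orbitals
  if (n != drt$space$n_orbitals)
    stop("integral dimension does not match the sector's orbital count",
         call. = FALSE)
  key <- paste0("H:", sector_key(drt$space))
  if (!is.null(integrals$cache[[key]])) return(integrals$cache[[key]])
  m <- as.integer(drt$dim)
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(m, m))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (integrals$t_one[i, j] != 0)
      H <- H + integrals$t_one[i, j] * generator_matrix(drt, i, j)
  }
  nz <- which(integrals$v_two != 0, arr.ind = TRUE)
  if (nrow(nz) > 0L) {
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1L]; j <- nz[r, 2L]; k <- nz[r, 3L]; l <- nz[r, 4L]
      H <- H + (0.5 * integrals$v_two[i, j, k, l]) * two_body_matrix(drt, i, j, k, l)
    }
  }
  if (integrals$core_energy != 0)
    H <- H + Matrix::Diagonal(m, integrals$core_energy)
  H <- methods::as(Matrix::drop0(H, tol = 1e-14), "CsparseMatrix")
  integrals$cache[[key]] <- H
  H
}

#' Single Hamiltonian column
#'
#' The sparse vector of elements `<nu|H|mu>` for a fixed ket CSF `mu`,
#' sliced from the assembled (cached) sector Hamiltonian.
#'
#' @inheritParams build_hamiltonian
#' @param x A [csf()] or a CSF index.
#' @return Sparse column vector of length `drt$dim`.
#' @export
hamiltonian_column <- function(integrals, drt, x) {
  idx <- if (is_csf(x)) csf_to_index(drt, x) else as.integer(x)
  if (idx < 1L || idx > drt$dim) stop("CSF index out of range", call. = FALSE)
  build_hamiltonian(integrals, drt)[, idx, drop = FALSE]
}

# Ground eigenpairs of a sparse symmetric matrix: dense below `dense_cutoff`,
# otherwise Lanczos with full reorthogonalization.
lowest_eigen <- function(H, k = 1L, dense_cutoff = 1500L,
                         maxiter = 400L, tol = 1e-11) {
  m <- nrow(H)
  k <- min(k, m)
  if (m <= dense_cutoff) {
    e <- eigen(as.matrix(Matrix::symmpart(H)), symmetric = TRUE)
    ord <- order(e$values)
    return(list(values = e$values[ord][seq_len(k)],
                vectors = e$vectors[, ord[seq_len(k)], drop = FALSE]))
  }
  lanczos_lowest(H, k = k, maxiter = maxiter, tol = tol)
}

# Minimal Lanczos with full reorthogonalization; adequate for the lowest
# few eigenpairs of desk-scale sparse Hamiltonians.
lanczos_lowest <- function(H, k = 1L, maxiter = 400L, tol = 1e-11) {
  m <- nrow(H)
  maxiter <- min(maxiter, m)
  set_local <- function(n) { v <- rep(1, n); v / sqrt(sum(v^2)) }
  q <- matrix(0, m, maxiter)
  q[, 1] <- set_local(m)
  alpha <- numeric(maxiter); beta <- numeric(maxiter)
  prev_vals <- NULL
  j_used <- maxiter
  for (j in seq_len(maxiter)) {
    w <- as.numeric(H %*% q[, j])
    alpha[j] <- sum(w * q[, j])
    w <- w - alpha[j] * q[, j]
    if (j > 1L) w <- w - beta[j - 1L] * q[, j - 1L]
    # full reorthogonalization
    w <- w - q[, seq_len(j), drop = FALSE] %*% crossprod(q[, seq_len(j), drop = FALSE], w)
    b <- sqrt(sum(w^2))
    if (j %% 10L == 0L || j == maxiter || b < 1e-13) {
      T_j <- diag(alpha[seq_len(j)], j, j)
      if (j > 1L) for (r in seq_len(j - 1L)) {
        T_j[r, r + 1L] <- beta[r]; T_j[r + 1L, r] <- beta[r]
      }
      ev <- eigen(T_j, symmetric = TRUE)
      vals <- sort(ev$values)[seq_len(min(k, j))]
      if (!is.null(prev_vals) && length(prev_vals) == length(vals) &&
          max(abs(prev_vals - vals)) < tol) { j_used <- j; break }
      prev_vals <- vals
      if (b < 1e-13) { j_used <- j; break }
    }
    if (j < maxiter) {
      beta[j] <- b
      q[, j + 1L] <- w / b
    }
    j_used <- j
  }
  j <- j_used
  T_j <- diag(alpha[seq_len(j)], j, j)
  if (j > 1L) for (r in seq_len(j - 1L)) {
    T_j[r, r + 1L] <- beta[r]; T_j[r + 1L, r] <- beta[r]
  }
  ev <- eigen(T_j, symmetric = TRUE)
  ord <- order(ev$values)[seq_len(min(k, j))]
  vecs <- q[, seq_len(j), drop = FALSE] %*% ev$vectors[, ord, drop = FALSE]
  vecs <- apply(vecs, 2L, function(v) v / sqrt(sum(v^2)))
  list(values = ev$values[ord], vectors = matrix(vecs, m))
}
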