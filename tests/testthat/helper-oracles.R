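# Independent determinant-basis oracle.
#
# Everything here is built directly on alpha/beta occupation bitstrings
# with its own operator conventions (alpha block before beta block) and
# shares no code with the package's CSF machinery.  Spectra and scalar
# expectation values are basis-convention independent, which is what the
# dual-route tests compare.

# All determinants of (n orbitals, N electrons) with fixed 2M = n_a - n_b.
sd_basis <- function(n, N, m2) {
  n_a <- (N + m2) / 2
  n_b <- (N - m2) / 2
  if (n_a != round(n_a) || n_a < 0 || n_b < 0 || n_a > n || n_b > n)
    return(list())
  occs <- function(k) {
    if (k == 0) return(list(rep(FALSE, n)))
    cmb <- utils::combn(n, k)
    lapply(seq_len(ncol(cmb)), function(i) {
      v <- rep(FALSE, n); v[cmb[, i]] <- TRUE; v
    })
  }
  out <- list()
  for (a in occs(n_a)) for (b in occs(n_b))
    out[[length(out) + 1L]] <- list(a = a, b = b)
  out
}

sd_key <- function(det) paste(c(det$a, det$b), collapse = "")

# a_{p,spin} with ordering: alpha creation operators (ascending orbital)
# before beta ones.
sd_annihilate <- function(det, p, spin) {
  occ <- det[[spin]]
  if (!occ[p]) return(NULL)
  n_before <- if (spin == "a") sum(det$a[seq_len(p - 1L)])
              else sum(det$a) + sum(det$b[seq_len(p - 1L)])
  det[[spin]][p] <- FALSE
  list(det = det, sign = if (n_before %% 2 == 0) 1 else -1)
}

sd_create <- function(det, p, spin) {
  occ <- det[[spin]]
  if (occ[p]) return(NULL)
  n_before <- if (spin == "a") sum(det$a[seq_len(p - 1L)])
              else sum(det$a) + sum(det$b[seq_len(p - 1L)])
  det[[spin]][p] <- TRUE
  list(det = det, sign = if (n_before %% 2 == 0) 1 else -1)
}

# Sparse matrix of sum_sigma a^+_{i sigma} a_{j sigma} over a det basis.
sd_E <- function(basis, i, j, keys = vapply(basis, sd_key, "")) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (col in seq_along(basis)) {
    for (spin in c("a", "b")) {
      an <- sd_annihilate(basis[[col]], j, spin)
      if (is.null(an)) next
      cr <- sd_create(an$det, i, spin)
      if (is.null(cr)) next
      row <- match(sd_key(cr$det), keys)
      ii <- c(ii, row); jj <- c(jj, col); xx <- c(xx, an$sign * cr$sign)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(basis), length(basis)))
}

# Determinant-basis Hamiltonian from the same integral convention:
# H = sum t_ij E_ij + 1/2 sum V_ijkl (E_ij E_kl - delta_jk E_il) + core.
sd_hamiltonian <- function(ints, basis) {
  n <- ints$n_orbitals
  m <- length(basis)
  keys <- vapply(basis, sd_key, "")
  Es <- vector("list", n * n)
  dim(Es) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) Es[[i, j]] <- sd_E(basis, i, j, keys)
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(m, m))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (ints$t_one[i, j] != 0) H <- H + ints$t_one[i, j] * Es[[i, j]]
  nz <- which(ints$v_two != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]; k <- nz[r, 3]; l <- nz[r, 4]
    term <- Es[[i, j]] %*% Es[[k, l]]
    if (j == k) term <- term - Es[[i, l]]
    H <- H + 0.5 * ints$v_two[i, j, k, l] * term
  }
  if (ints$core_energy != 0)
    H <- H + Matrix::Diagonal(m, ints$core_energy)
  H
}

# S^2 on a fixed-M det basis via S^2 = S- S+ + M (M + 1):
# S+ = sum_p a^+_{p alpha} a_{p beta} maps into the (M + 1) basis.
sd_s2 <- function(n, N, m2, basis = sd_basis(n, N, m2)) {
  up_basis <- sd_basis(n, N, m2 + 2L)
  m <- length(basis)
  if (length(up_basis) == 0L) {
    Splus <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(0, m))
  } else {
    up_keys <- vapply(up_basis, sd_key, "")
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (col in seq_along(basis)) {
      for (p in seq_len(n)) {
        an <- sd_annihilate(basis[[col]], p, "b")
        if (is.null(an)) next
        cr <- sd_create(an$det, p, "a")
        if (is.null(cr)) next
        ii <- c(ii, match(sd_key(cr$det), up_keys))
        jj <- c(jj, col); xx <- c(xx, an$sign * cr$sign)
      }
    }
    Splus <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(length(up_basis), m))
  }
  M <- m2 / 2
  Matrix::crossprod(Splus) + Matrix::Diagonal(m, M * (M + 1))
}

# <v| S_p . S_q |v> on a det basis, from per-orbital spin operators.
# Ladder-operator products are composed at the determinant level (the
# intermediate lives outside the fixed-M basis) and only the final
# determinant is matched back.
sd_spin_corr <- function(basis, p, q, v) {
  m <- length(basis)
  keys <- vapply(basis, sd_key, "")
  sz <- function(det, p) (det$a[p] - det$b[p]) / 2
  plus_op <- function(p) function(det) {
    an <- sd_annihilate(det, p, "b"); if (is.null(an)) return(NULL)
    cr <- sd_create(an$det, p, "a"); if (is.null(cr)) return(NULL)
    list(det = cr$det, sign = an$sign * cr$sign)
  }
  minus_op <- function(p) function(det) {
    an <- sd_annihilate(det, p, "a"); if (is.null(an)) return(NULL)
    cr <- sd_create(an$det, p, "b"); if (is.null(cr)) return(NULL)
    list(det = cr$det, sign = an$sign * cr$sign)
  }
  compose <- function(f, g) function(det) {  # applies g first, then f
    r1 <- g(det); if (is.null(r1)) return(NULL)
    r2 <- f(r1$det); if (is.null(r2)) return(NULL)
    list(det = r2$det, sign = r1$sign * r2$sign)
  }
  expectation <- function(op) {
    tot <- 0
    for (col in which(v != 0)) {
      r <- op(basis[[col]])
      if (is.null(r)) next
      row <- match(sd_key(r$det), keys)
      if (!is.na(row)) tot <- tot + v[row] * r$sign * v[col]
    }
    tot
  }
  zz <- sum(vapply(seq_along(basis), function(col)
    sz(basis[[col]], p) * sz(basis[[col]], q) * v[col]^2, 1))
  pm <- expectation(compose(plus_op(p), minus_op(q))) / 2
  mp <- expectation(compose(minus_op(p), plus_op(q))) / 2
  zz + pm + mp
}

# Random 8-fold-symmetric integral set.
random_integrals <- function(n, seed, v_scale = 0.5) {
  set.seed(seed)
  tm <- matrix(stats::rnorm(n * n), n)
  tm <- (tm + t(tm)) / 2
  v <- array(stats::rnorm(n^4, sd = v_scale), rep(n, 4L))
  integral_set(tm, v)
}

# Eigenvalues of the det-basis Hamiltonian restricted to spin S (labelled
# by S^2 expectation), at projection M = S.
sd_sector_eigenvalues <- function(ints, N, S2twice) {
  n <- ints$n_orbitals
  basis <- sd_basis(n, N, S2twice)
  H <- as.matrix(sd_hamiltonian(ints, basis))
  S2 <- as.matrix(sd_s2(n, N, S2twice, basis))
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lab <- colSums(e$vectors * (S2 %*% e$vectors))
  S_target <- (S2twice / 2) * (S2twice / 2 + 1)
  sort(e$values[abs(lab - S_target) < 1e-6])
}
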