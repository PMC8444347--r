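#' Spin-free one- and two-body reduced density matrices
#'
#' Container for the spin-free RDMs `gamma_ij = <E_ij>` and
#' `Gamma_ij,kl = <e_ij,kl>` (no 1/2 prefactor; the 1/2 is carried in the
#' energy contraction `E = sum t gamma + 1/2 sum V Gamma + E_core`). After
#' finalization, `gamma` is symmetric, `trace(gamma) = N`, and the partial
#' trace obeys `sum_k Gamma_ij,kk = (N - 1) gamma_ij`.
#'
#' @param gamma `n x n` one-body RDM.
#' @param Gamma `n^4` array, `Gamma[i,j,k,l] = <e_ij,kl>`.
#' @param n_electrons,twice_S Sector metadata.
#' @param finalized Logical; whether symmetrization/normalization has run.
#' @param meta Optional list (sampling window, seeds, ...).
#' @return An object of class `"rdm_pair"`.
#' @export
rdm_pair <- function(gamma, Gamma, n_electrons, twice_S,
                     finalized = FALSE, meta = list()) {
  gamma <- as.matrix(gamma)
  n <- nrow(gamma)
  if (!identical(dim(Gamma), rep(n, 4L)))
    stop("`Gamma` must be an n^4 array matching `gamma`", call. = FALSE)
  structure(
    list(gamma = gamma, Gamma = Gamma, n_orbitals = n,
         n_electrons = as.integer(n_electrons),
         twice_S = as.integer(twice_S),
         finalized = isTRUE(finalized), meta = meta),
    class = "rdm_pair")
}

is_rdm_pair <- function(x) inherits(x, "rdm_pair")

assert_finalized_rdms <- function(x) {
  if (!is_rdm_pair(x)) stop("expected an `rdm_pair`", call. = FALSE)
  if (!x$finalized)
    stop("RDMs must be finalized before observables are computed; ",
         "see `finalize_rdms()`", call. = FALSE)
  invisible(x)
}

#' @export
print.rdm_pair <- function(x, ...) {
  cat(sprintf(
    "<rdm_pair> n = %d orbitals, N = %d, S = %s, %s\n  trace(gamma) = %.10g\n",
    x$n_orbitals, x$n_electrons, format_half_integer(x$twice_S),
    if (x$finalized) "finalized" else "accumulating", sum(diag(x$gamma))))
  invisible(x)
}

#' Energy from RDM contraction
#'
#' `E = sum_ij t_ij gamma_ij + 1/2 sum_ijkl V_ijkl Gamma_ij,kl + E_core`.
#' For exact RDMs this reproduces the variational eigenvalue; for sampled
#' RDMs it is an energy estimator consistent with the projected energy
#' within stochastic error.
#'
#' @param rdms An [rdm_pair()].
#' @param integrals An [integral_set()] over the same orbitals.
#' @return Energy (numeric scalar).
#' @export
rdm_energy <- function(rdms, integrals) {
  assert_integral_set(integrals)
  if (!is_rdm_pair(rdms)) stop("expected an `rdm_pair`", call. = FALSE)
  if (rdms$n_orbitals != integrals$n_orbitals)
    stop("orbital dimension mismatch between RDMs and integrals", call. = FALSE)
  sum(integrals$t_one * rdms$gamma) + 0.5 * sum(integrals$v_two * rdms$Gamma) +
    integrals$core_energy
}

#' Total spin expectation from RDMs
#'
#' Contracts the spin-free RDMs with the operator identity
#' `S^2 = sum_p S_p^2 + sum_{p != q} S_p . S_q`. On a spin-pure state this
#' equals `S (S + 1)` — the spin-purity diagnostic asserted for every run.
#'
#' @param rdms A finalized [rdm_pair()].
#' @return `<S^2>` (numeric scalar).
#' @export
rdm_s2 <- function(rdms) {
  assert_finalized_rdms(rdms)
  n <- rdms$n_orbitals
  val <- 0
  for (p in seq_len(n)) {
    val <- val + orbital_spin_correlation(rdms, p, p)
    for (q in seq_len(n)) {
      if (q != p) val <- val + orbital_spin_correlation(rdms, p, q)
    }
  }
  val
}

# Exact RDMs of an arbitrary CI vector over a sector, via the generator
# matrices: gamma_ij = v' E_ij v, Gamma_ij,kl = (E_ji v).(E_kl v) -
# delta_jk v.(E_il v).
rdms_from_vector <- function(drt, v, meta = list()) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  m <- as.integer(drt$dim)
  v <- as.numeric(v)
  if (length(v) != m) stop("vector length does not match basis", call. = FALSE)
  w <- vector("list", n * n)
  dim(w) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    w[[i, j]] <- as.numeric(generator_matrix(drt, i, j) %*% v)
  gamma <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    gamma[i, j] <- sum(v * w[[i, j]])
  Gamma <- array(0, rep(n, 4L))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    wji <- w[[j, i]]
    for (k in seq_len(n)) for (l in seq_len(n)) {
      val <- sum(wji * w[[k, l]])
      if (j == k) val <- val - gamma[i, l]
      Gamma[i, j, k, l] <- val
    }
  }
  rdm_pair(gamma, Gamma, drt$space$n_electrons, drt$space$twice_S,
           finalized = TRUE, meta = c(meta, list(source = "exact")))
}
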