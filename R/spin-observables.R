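# Spin observables from spin-free RDMs.
#
# Working formulas, derived from the operator identity
# e_pq,qp = -1/2 e_pp,qq - 2 S_p.S_q (p != q) and
# S_p^2 = 3/4 (n_p - e_pp,pp):
#   <S_p.S_q> = -1/2 Gamma_pq,qp - 1/4 Gamma_pp,qq   (p != q)
#   <S_p^2>   =  3/4 (gamma_pp - Gamma_pp,pp)
# These are representation-dependent quantities: they depend on the orbital
# basis (localized vs delocalized); all tests fix the orbital basis
# explicitly.

#' Orbital-resolved spin-spin correlation
#'
#' `<S_p . S_q>` between two spatial orbitals (or the single-orbital
#' `<S_p^2>` when `p == q`), from finalized spin-free RDMs. Two
#' ferromagnetically coupled singly occupied orbitals give `+1/4`, an
#' antiferromagnetic singlet pair gives `-3/4`, and a doubly occupied or
#' empty orbital carries no spin.
#'
#' @param rdms A finalized [rdm_pair()].
#' @param p,q Spatial orbital indices.
#' @return Numeric scalar.
#' @export
orbital_spin_correlation <- function(rdms, p, q) {
  assert_finalized_rdms(rdms)
  n <- rdms$n_orbitals
  p <- as.integer(p); q <- as.integer(q)
  if (any(c(p, q) < 1L) || any(c(p, q) > n))
    stop("orbital indices out of range", call. = FALSE)
  if (p == q) {
    0.75 * (rdms$gamma[p, p] - rdms$Gamma[p, p, p, p])
  } else {
    -0.5 * rdms$Gamma[p, q, q, p] - 0.25 * rdms$Gamma[p, p, q, q]
  }
}

#' Local spin of an orbital fragment
#'
#' `<S_A^2> = sum_{p in A} <S_p^2> + sum_{p != q in A} <S_p . S_q>` for a
#' fragment `A` of spatial orbitals. Five singly occupied orbitals coupled
#' ferromagnetically (a local spin-5/2 center) give the maximal 8.75; the
#' full orbital set gives `S (S + 1)` of the sector.
#'
#' @param rdms A finalized [rdm_pair()].
#' @param fragment Integer vector of orbital indices (1-based, distinct).
#' @return `<S_A^2>` (numeric scalar).
#' @export
local_spin <- function(rdms, fragment) {
  assert_finalized_rdms(rdms)
  fragment <- check_fragment(rdms, fragment)
  if (length(fragment) == 0L) {
    warning("empty fragment: local spin is 0")
    return(0)
  }
  val <- 0
  for (p in fragment) for (q in fragment)
    val <- val + orbital_spin_correlation(rdms, p, q)
  val
}

#' Spin of a sum of fragments
#'
#' `<(sum_A S_A)^2>` for pairwise-disjoint orbital fragments, expanded as
#' `sum_A <S_A^2> + sum_{A != B} <S_A . S_B>` with
#' `<S_A . S_B> = sum_{p in A, q in B} <S_p . S_q>`.
#'
#' @param rdms A finalized [rdm_pair()].
#' @param fragments List of integer vectors of orbital indices; must be
#'   pairwise disjoint.
#' @return Numeric scalar.
#' @export
fragment_spin_sum <- function(rdms, fragments) {
  assert_finalized_rdms(rdms)
  if (!is.list(fragments)) fragments <- list(fragments)
  fragments <- lapply(fragments, function(f) check_fragment(rdms, f))
  all_idx <- unlist(fragments)
  if (anyDuplicated(all_idx))
    stop("fragments must be pairwise disjoint", call. = FALSE)
  val <- 0
  for (p in all_idx) for (q in all_idx)
    val <- val + orbital_spin_correlation(rdms, p, q)
  val
}

#' Spin-spin correlation profile from a reference orbital
#'
#' The vector `<S_p . S_i>` between a fixed reference orbital `p` and all
#' orbitals `i` (the single-orbital `<S_p^2>` at `i = p`). Magnetically
#' inert (doubly occupied or empty) orbitals report values near zero.
#'
#' @param rdms A finalized [rdm_pair()].
#' @param p Reference orbital (1-based).
#' @return A tibble with columns `orbital` and `correlation`.
#' @export
correlation_profile <- function(rdms, p) {
  assert_finalized_rdms(rdms)
  n <- rdms$n_orbitals
  tibble::tibble(
    orbital = seq_len(n),
    correlation = vapply(seq_len(n), function(i)
      orbital_spin_correlation(rdms, p, i), 1))
}

check_fragment <- function(rdms, fragment) {
  fragment <- as.integer(fragment)
  if (anyNA(fragment) || any(fragment < 1L) || any(fragment > rdms$n_orbitals))
    stop("fragment indices out of the orbital range", call. = FALSE)
  if (anyDuplicated(fragment))
    stop("fragment indices must be distinct", call. = FALSE)
  fragment
}
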