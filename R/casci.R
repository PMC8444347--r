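#' Exact CASCI diagonalization of a spin sector
#'
#' Builds the spin-adapted Hamiltonian of the sector and solves for its
#' lowest eigenpairs exactly (dense below 1500 basis states, Lanczos
#' above), then forms the exact spin-free 1- and 2-RDMs of the requested
#' root. Refuses sectors beyond `max_dim` and directs the caller to the
#' stochastic FCIQMC engine instead.
#'
#' @param integrals An [integral_set()].
#' @param space A [spin_space()].
#' @param n_roots Number of lowest eigenpairs to return.
#' @param root Root (1-based, among the computed ones) whose RDMs to form.
#' @param max_dim Refusal cap on the basis dimension (default `2e5`).
#' @return An object of class `"casci_result"`: list with `energy` (ground
#'   energy of the sector), `values`, `vectors`, `rdms` (an [rdm_pair()]),
#'   `drt`, `space`.
#' @examples
#' res <- exact_casci(hubbard_model(2, 1, 4), spin_space(2, 2, 0))
#' res$energy  # U/2 - sqrt(U^2/4 + 4 t^2) = -0.8284271
#' @export
exact_casci <- function(integrals, space, n_roots = 1L, root = 1L,
                        max_dim = 2e5) {
  assert_integral_set(integrals)
  assert_spin_space(space)
  dim <- csf_dimension(space)
  if (dim > max_dim)
    stop(sprintf(paste0(
      "sector dimension %g exceeds the exact-diagonalization cap %g; ",
      "use the stochastic eigensolver `run_fciqmc()` instead"),
      dim, max_dim), call. = FALSE)
  drt <- build_drt(space)
  H <- build_hamiltonian(integrals, drt)
  eig <- lowest_eigen(H, k = n_roots)
  if (root > length(eig$values))
    stop("`root` exceeds the number of computed roots", call. = FALSE)
  v <- eig$vectors[, root]
  rdms <- rdms_from_vector(drt, v, meta = list(root = root))
  structure(
    list(energy = eig$values[1L], values = eig$values,
         vectors = eig$vectors, rdms = rdms, drt = drt, space = space,
         integrals = integrals),
    class = "casci_result")
}

#' @export
print.casci_result <- function(x, ...) {
  cat(sprintf("<casci_result> sector (n=%d, N=%d, S=%s), dim %g\n",
              x$space$n_orbitals, x$space$n_electrons,
              format_half_integer(x$space$twice_S), x$drt$dim))
  cat("  energies:", paste(sprintf("%.8f", x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.casci_result <- function(x, ...) {
  tibble::tibble(root = seq_along(x$values), energy = x$values)
}

#' @export
glance.casci_result <- function(x, ...) {
  tibble::tibble(
    n_orbitals = x$space$n_orbitals,
    n_electrons = x$space$n_electrons,
    twice_S = x$space$twice_S,
    dim = x$drt$dim,
    energy = x$energy,
    rdm_energy = rdm_energy(x$rdms, x$integrals),
    s2 = rdm_s2(x$rdms))
}
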