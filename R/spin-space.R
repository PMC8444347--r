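#' Define a spin sector
#'
#' A spin sector is the triple (number of spatial orbitals, number of
#' electrons, total spin S) that fixes a spin-adapted CSF basis. The total
#' spin is stored internally as the integer `2S` so that half-integer spins
#' are represented exactly.
#'
#' @param n_orbitals Number of spatial orbitals (positive integer).
#' @param n_electrons Number of electrons (non-negative integer,
#'   at most `2 * n_orbitals`).
#' @param twice_S Twice the total spin quantum number, an integer with the
#'   same parity as `n_electrons` and `twice_S <= n_electrons`.
#'
#' @return An object of class `"spin_space"` with fields `n_orbitals`,
#'   `n_electrons`, `twice_S`.
#' @examples
#' spin_space(6, 6, 0)        # 6 orbitals, 6 electrons, singlet
#' spin_space(5, 5, 5)        # five electrons coupled to S = 5/2
#' @export
spin_space <- function(n_orbitals, n_electrons, twice_S) {
  n_orbitals <- as.integer(n_orbitals)
  n_electrons <- as.integer(n_electrons)
  twice_S <- as.integer(twice_S)
  if (length(n_orbitals) != 1L || is.na(n_orbitals) || n_orbitals < 1L)
    stop("`n_orbitals` must be a single positive integer", call. = FALSE)
  if (length(n_electrons) != 1L || is.na(n_electrons) || n_electrons < 0L)
    stop("`n_electrons` must be a single non-negative integer", call. = FALSE)
  if (length(twice_S) != 1L || is.na(twice_S) || twice_S < 0L)
    stop("`twice_S` must be a single non-negative integer", call. = FALSE)
  if (n_electrons > 2L * n_orbitals)
    stop(sprintf(
      "invalid sector: n_electrons = %d exceeds 2 * n_orbitals = %d",
      n_electrons, 2L * n_orbitals), call. = FALSE)
  if (twice_S > n_electrons)
    stop(sprintf(
      "invalid sector: 2S = %d exceeds n_electrons = %d (spin bound violated)",
      twice_S, n_electrons), call. = FALSE)
  if ((n_electrons - twice_S) %% 2L != 0L)
    stop(sprintf(
      "invalid sector: n_electrons = %d and 2S = %d differ in parity",
      n_electrons, twice_S), call. = FALSE)
  structure(
    list(n_orbitals = n_orbitals, n_electrons = n_electrons, twice_S = twice_S),
    class = "spin_space")
}

#' @export
print.spin_space <- function(x, ...) {
  cat(sprintf("<spin_space> n = %d orbitals, N = %d electrons, S = %s\n",
              x$n_orbitals, x$n_electrons, format_half_integer(x$twice_S)))
  invisible(x)
}

format_half_integer <- function(twice_x) {
  if (twice_x %% 2L == 0L) as.character(twice_x %/% 2L)
  else sprintf("%d/2", twice_x)
}

is_spin_space <- function(x) inherits(x, "spin_space")

assert_spin_space <- function(x) {
  if (!is_spin_space(x)) stop("expected a `spin_space` object", call. = FALSE)
  invisible(x)
}
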