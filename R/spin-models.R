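#' Define a Heisenberg spin model
#'
#' Sites carry fixed spins `s_i` (half-integers allowed); the Hamiltonian is
#' `H = sum_{i<j} J_ij S_i . S_j + sum_{i<j} J'_ij (S_i . S_j)^2` with the
#' convention that `J > 0` is antiferromagnetic (singlet ground state for
#' two sites).
#'
#' @param spins Numeric vector of site spins (e.g. `rep(5/2, 4)`).
#' @param J Symmetric coupling matrix with zero diagonal, or a scalar
#'   applied to every pair (complete graph).
#' @param J_biquadratic Optional biquadratic couplings, same shape rules.
#' @return An object of class `"spin_model"`.
#' @examples
#' spin_model(rep(5/2, 4), J = 1)       # complete-graph tetramer
#' @export
spin_model <- function(spins, J, J_biquadratic = NULL) {
  twice_spins <- as.integer(round(2 * spins))
  if (any(twice_spins < 1L))
    stop("site spins must be positive half-integers", call. = FALSE)
  n <- length(twice_spins)
  expand <- function(x, name) {
    if (is.null(x)) return(matrix(0, n, n))
    if (length(x) == 1L) {
      m <- matrix(as.numeric(x), n, n); diag(m) <- 0
      return(m)
    }
    m <- as.matrix(x)
    if (!identical(dim(m), c(n, n)))
      stop(sprintf("`%s` must be scalar or an n x n matrix", name),
           call. = FALSE)
    if (any(diag(m) != 0))
      stop(sprintf("`%s` must have a zero diagonal", name), call. = FALSE)
    if (max(abs(m - t(m))) > 1e-12)
      stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
    m
  }
  structure(
    list(twice_spins = twice_spins, J = expand(J, "J"),
         J_biquadratic = expand(J_biquadratic, "J_biquadratic"),
         dim = prod(twice_spins + 1)),
    class = "spin_model")
}

is_spin_model <- function(x) inherits(x, "spin_model")

#' @export
print.spin_model <- function(x, ...) {
  cat(sprintf("<spin_model> %d sites (2s = %s), product dimension %g\n",
              length(x$twice_spins), paste(x$twice_spins, collapse = ","),
              x$dim))
  invisible(x)
}

# Dense spin matrices for one site of spin s = ts/2, basis ordered by
# descending m (m = s, s-1, ..., -s).
site_spin_matrices <- function(ts) {
  d <- ts + 1L
  m <- (ts - 2 * (seq_len(d) - 1L)) / 2
  Sz <- diag(m, d, d)
  Sp <- matrix(0, d, d)
  s <- ts / 2
  for (i in 2:d) if (d >= 2)
    Sp[i - 1L, i] <- sqrt(s * (s + 1) - m[i] * (m[i] + 1))
  list(Sz = Sz, Sp = Sp, Sm = t(Sp))
}

# Embed a per-site operator at site k: kron of identities, site 1 slowest.
embed_site_op <- function(model, k, op) {
  out <- NULL
  for (i in seq_along(model$twice_spins)) {
    d <- model$twice_spins[i] + 1L
    blk <- if (i == k) Matrix::Matrix(op, sparse = TRUE) else Matrix::Diagonal(d)
    out <- if (is.null(out)) blk else Matrix::kronecker(out, blk)
  }
  methods::as(out, "CsparseMatrix")
}

# S_i . S_j as a sparse operator on the product space (cached per model call
# site pair by the caller when needed).
pair_coupling_op <- function(model, i, j) {
  ops_i <- site_spin_matrices(model$twice_spins[i])
  ops_j <- site_spin_matrices(model$twice_spins[j])
  embed_site_op(model, i, ops_i$Sz) %*% embed_site_op(model, j, ops_j$Sz) +
    0.5 * (embed_site_op(model, i, ops_i$Sp) %*% embed_site_op(model, j, ops_j$Sm) +
           embed_site_op(model, i, ops_i$Sm) %*% embed_site_op(model, j, ops_j$Sp))
}

# Full product-space Hamiltonian (sparse).
spin_model_hamiltonian <- function(model) {
  n <- length(model$twice_spins)
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(model$dim, model$dim))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (model$J[i, j] == 0 && model$J_biquadratic[i, j] == 0) next
    P <- pair_coupling_op(model, i, j)
    if (model$J[i, j] != 0) H <- H + model$J[i, j] * P
    if (model$J_biquadratic[i, j] != 0)
      H <- H + model$J_biquadratic[i, j] * (P %*% P)
  }
  methods::as(H, "CsparseMatrix")
}

# Total S^2 operator = sum_i S_i^2 + 2 sum_{i<j} S_i . S_j.
spin_model_s2 <- function(model) {
  n <- length(model$twice_spins)
  s <- model$twice_spins / 2
  out <- Matrix::Diagonal(model$dim, sum(s * (s + 1)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out <- out + 2 * pair_coupling_op(model, i, j)
  methods::as(out, "CsparseMatrix")
}

# Vector of total 2M over the product basis (site 1 slowest, matching the
# kronecker ordering of the embedded operators).
spin_model_m2 <- function(model) {
  out <- 0
  for (ts in model$twice_spins) {
    m2_site <- ts - 2 * (seq_len(ts + 1L) - 1L)
    out <- as.vector(t(outer(out, m2_site, `+`)))
  }
  out
}

#' Exact spectrum of a Heisenberg spin model
#'
#' Diagonalizes `H = sum J_ij S_i.S_j + sum J'_ij (S_i.S_j)^2` exactly,
#' optionally restricted to one total-projection (`M`) block, and labels
#' every eigenstate with its total spin via the `S^2` expectation value.
#'
#' @param model A [spin_model()].
#' @param total_Sz Restrict to the block with this total projection
#'   (default: the lowest `|M|` block, which contains one copy of every
#'   spin multiplet).
#' @param total_S If given, keep only eigenstates with this total spin.
#' @param max_dim Refusal cap on the (block) dimension.
#' @return An object of class `"spin_spectrum"`: `values`, `S` (total-spin
#'   labels), `vectors` (columns, in the block basis), `basis_indices`
#'   (product-basis positions of the block), `model`.
#' @examples
#' m <- spin_model(c(5/2, 5/2), J = 1)
#' sp <- heisenberg_exact(m)
#' tidy(sp)   # Lande ladder E(S) = (J/2) [S(S+1) - 35/2]
#' @export
heisenberg_exact <- function(model, total_Sz = NULL, total_S = NULL,
                             max_dim = 1e5) {
  if (!is_spin_model(model)) stop("expected a `spin_model`", call. = FALSE)
  if (model$dim > max_dim)
    stop(sprintf("product dimension %g exceeds cap %g", model$dim, max_dim),
         call. = FALSE)
  m2 <- spin_model_m2(model)
  tm <- if (is.null(total_Sz)) min(abs(m2)) else as.integer(round(2 * total_Sz))
  block <- which(m2 == tm)
  if (length(block) == 0L)
    stop("no basis states with the requested total Sz", call. = FALSE)
  H <- spin_model_hamiltonian(model)[block, block, drop = FALSE]
  e <- eigen(as.matrix(Matrix::symmpart(H)), symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  S2full <- spin_model_s2(model)[block, block, drop = FALSE]
  s2 <- colSums(vectors * as.matrix(S2full %*% vectors))
  S_lab <- (-1 + sqrt(1 + 4 * pmax(s2, 0))) / 2
  S_lab <- round(2 * S_lab) / 2
  if (!is.null(total_S)) {
    keep <- which(abs(S_lab - total_S) < 1e-6)
    values <- values[keep]; vectors <- vectors[, keep, drop = FALSE]
    S_lab <- S_lab[keep]
  }
  structure(
    list(values = values, S = S_lab, vectors = vectors,
         basis_indices = block, total_twice_Sz = tm, model = model),
    class = "spin_spectrum")
}

#' @export
print.spin_spectrum <- function(x, ...) {
  cat(sprintf("<spin_spectrum> %d states in the 2M = %d block\n",
              length(x$values), x$total_twice_Sz))
  invisible(x)
}

#' @export
tidy.spin_spectrum <- function(x, ...) {
  tibble::tibble(S = x$S, energy = x$values)
}

#' Spin ladder of a Heisenberg model
#'
#' The lowest energy in each total-spin sector, from the exact spectrum of
#' the minimal-`|M|` block (which contains one representative of every
#' multiplet).
#'
#' @param model A [spin_model()].
#' @return A tibble with columns `S` and `energy`, one row per total spin.
#' @export
heisenberg_ladder <- function(model) {
  sp <- heisenberg_exact(model)
  td <- tidy(sp)
  td <- dplyr::summarise(dplyr::group_by(td, .data$S),
                         energy = min(.data$energy), .groups = "drop")
  dplyr::arrange(td, .data$S)
}

#' Fragment spin expectation in a spin model
#'
#' `<psi| (sum_{i in sites} S_i)^2 |psi>` for an eigenstate of a
#' [heisenberg_exact()] spectrum (given by its column index or as a vector
#' over the spectrum's block basis), or for an explicit state vector over
#' the full product basis of a [spin_model()] (e.g. one built with
#' [pair_coupled_state()]).
#'
#' @param x A `"spin_spectrum"` from [heisenberg_exact()], or a
#'   [spin_model()].
#' @param state For a spectrum: eigenstate column index (default 1, the
#'   lowest) or a numeric vector over the block basis. For a model: a
#'   numeric vector over the full product basis.
#' @param sites Integer site indices of the fragment.
#' @return Numeric scalar.
#' @export
spin_fragment_expectation <- function(x, sites, state = 1L) {
  model <- if (inherits(x, "spin_spectrum")) x$model
           else if (is_spin_model(x)) x
           else stop("expected a `spin_spectrum` or `spin_model`",
                     call. = FALSE)
  sites <- as.integer(sites)
  if (any(sites < 1L) || any(sites > length(model$twice_spins)))
    stop("site indices out of range", call. = FALSE)
  if (is_spin_model(x)) {
    v <- as.numeric(state)
    if (length(v) != model$dim)
      stop("`state` must be a vector over the full product basis",
           call. = FALSE)
    return(fragment_spin_product_state(model, v, sites))
  }
  v <- if (length(state) == 1L) x$vectors[, state] else as.numeric(state)
  s <- model$twice_spins / 2
  op <- Matrix::Diagonal(model$dim, sum(s[sites] * (s[sites] + 1)))
  if (length(sites) > 1L) {
    for (a in seq_along(sites)[-length(sites)])
      for (b in (a + 1L):length(sites))
        op <- op + 2 * pair_coupling_op(model, sites[a], sites[b])
  }
  blk <- x$basis_indices
  op_b <- op[blk, blk, drop = FALSE]
  sum(v * as.numeric(op_b %*% v))
}

#' Clebsch-Gordan coefficient
#'
#' `<j1 m1; j2 m2 | J M>` with `M = m1 + m2`, by Racah's closed form.
#' Arguments are ordinary (half-integer) angular momenta.
#'
#' @param j1,m1,j2,m2,J Angular momentum quantum numbers.
#' @return Numeric scalar.
#' @export
clebsch_gordan <- function(j1, m1, j2, m2, J) {
  M <- m1 + m2
  if (J < abs(j1 - j2) || J > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(M) > J) return(0)
  ints <- c(j1 + j2 - J, j1 - j2 + J, -j1 + j2 + J,
            j1 - m1, j1 + m1, j2 - m2, j2 + m2, J - M, J + M)
  if (any(abs(ints - round(ints)) > 1e-9)) return(0)
  lf <- function(x) lfactorial(round(x))
  pref <- 0.5 * (log(2 * J + 1) + lf(j1 + j2 - J) + lf(j1 - j2 + J) +
                   lf(-j1 + j2 + J) - lf(j1 + j2 + J + 1) +
                   lf(J + M) + lf(J - M) + lf(j1 - m1) + lf(j1 + m1) +
                   lf(j2 - m2) + lf(j2 + m2))
  k_min <- max(0, round(j2 - J - m1), round(j1 + m2 - J))
  k_max <- min(round(j1 + j2 - J), round(j1 - m1), round(j2 + m2))
  if (k_min > k_max) return(0)
  total <- 0
  for (k in k_min:k_max) {
    lterm <- pref - (lf(k) + lf(j1 + j2 - J - k) + lf(j1 - m1 - k) +
                       lf(j2 + m2 - k) + lf(J - j2 + m1 + k) +
                       lf(J - j1 - m2 + k))
    total <- total + (-1)^k * exp(lterm)
  }
  total
}

#' Pair-coupled states of a spin model
#'
#' Constructs `|((1,2) S_12, (3,4) S_34) S M>` for a four-site model (or
#' `|(1,2) S M>` for two sites) by explicit Clebsch-Gordan coupling in the
#' product basis — e.g. the state of a spin-5/2 tetramer with two
#' ferromagnetic pairs (`S_12 = S_34 = 5`) coupled to a global singlet.
#'
#' @param model A [spin_model()] with two or four sites.
#' @param S_pairs For four sites, `c(S_12, S_34)`; ignored for two sites.
#' @param S,M Total spin and projection of the coupled state.
#' @return Numeric vector over the full product basis (unit norm).
#' @export
pair_coupled_state <- function(model, S, M = NULL, S_pairs = NULL) {
  if (!is_spin_model(model)) stop("expected a `spin_model`", call. = FALSE)
  n <- length(model$twice_spins)
  s <- model$twice_spins / 2
  if (is.null(M)) M <- if ((round(2 * S) %% 2L) == 0L) 0 else 1 / 2
  pair_vec <- function(s1, s2, S12, M12) {
    d1 <- round(2 * s1) + 1L; d2 <- round(2 * s2) + 1L
    v <- numeric(d1 * d2)
    for (i1 in seq_len(d1)) {
      m1 <- s1 - (i1 - 1L)
      m2 <- M12 - m1
      if (abs(m2) > s2 + 1e-9) next
      i2 <- round(s2 - m2) + 1L
      v[(i1 - 1L) * d2 + i2] <- clebsch_gordan(s1, m1, s2, m2, S12)
    }
    v
  }
  if (n == 2L) {
    v <- pair_vec(s[1], s[2], S, M)
  } else if (n == 4L) {
    if (is.null(S_pairs) || length(S_pairs) != 2L)
      stop("`S_pairs = c(S_12, S_34)` is required for four sites",
           call. = FALSE)
    v <- numeric(model$dim)
    for (twoM12 in seq(-2 * S_pairs[1], 2 * S_pairs[1], by = 2)) {
      M12 <- twoM12 / 2
      M34 <- M - M12
      if (abs(M34) > S_pairs[2] + 1e-9) next
      cg <- clebsch_gordan(S_pairs[1], M12, S_pairs[2], M34, S)
      if (cg == 0) next
      v <- v + cg * kronecker(pair_vec(s[1], s[2], S_pairs[1], M12),
                              pair_vec(s[3], s[4], S_pairs[2], M34))
    }
  } else {
    stop("pair coupling is implemented for two- and four-site models",
         call. = FALSE)
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12)
    stop("requested coupled state vanishes (invalid quantum numbers)",
         call. = FALSE)
  v / nv
}

# Expectation of (sum_{i in sites} S_i)^2 for a full product-basis vector.
fragment_spin_product_state <- function(model, v, sites) {
  s <- model$twice_spins / 2
  op <- Matrix::Diagonal(model$dim, sum(s[sites] * (s[sites] + 1)))
  if (length(sites) > 1L) {
    for (a in seq_along(sites)[-length(sites)])
      for (b in (a + 1L):length(sites))
        op <- op + 2 * pair_coupling_op(model, sites[a], sites[b])
  }
  sum(v * as.numeric(op %*% v))
}
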