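# Stochastic accumulation of spin-free RDMs from two-replica FCIQMC.
#
# gamma_ij    = sum_{mu nu} c_mu^A c_nu^B <nu|E_ij|mu>   / (sum c^A c^B)
# Gamma_ij,kl = sum_{mu nu} c_mu^A c_nu^B <nu|e_ij,kl|mu> / (sum c^A c^B)
#
# Diagonal pairs (mu = nu) are accumulated explicitly every iteration:
# gamma_ii from occupations, Gamma_ii,kk from occupation products, and the
# exchange-diagonal Gamma_ij,ji from the generator module's diagonal
# coupling coefficients.  Products c^A c^B of two statistically independent
# replicas remove the strictly positive bias a single replica would have.
# Off-diagonal pairs are harvested from the spawning stream: each sampled
# parent-child event carries the parent coefficient, the attempt count and
# the generation probability of its route, and contributes
# c_mu^A c_nu^B <nu|e_r|mu> / (N_att p(route)) to the entries addressed by
# the pair's index routes.  Pairs inside the deterministic core never
# appear in the spawn stream and are accumulated exactly each iteration.

#' Create an RDM accumulator for an FCIQMC engine
#'
#' Precomputes the per-CSF diagonal contribution tables and, when a
#' deterministic core is active, the exact core-pair contribution tables.
#'
#' @param engine An [fciqmc_engine()].
#' @return An environment of class `"rdm_accumulator"`.
#' @export
rdm_accumulator <- function(engine) {
  if (is.null(engine$pair_tables))
    stop("engine was built without RDM support; use `fciqmc_engine(..., rdm = TRUE)`",
         call. = FALSE)
  n <- engine$space$n_orbitals
  acc <- new.env(parent = emptyenv())
  acc$engine <- engine
  acc$n <- n
  acc$accG <- numeric(n * n)
  acc$accGam <- numeric(n^4)
  acc$norm <- 0
  acc$iterations <- 0L
  acc$Dg <- engine$pair_tables$Dg
  acc$DG <- engine$pair_tables$DG
  # scalar factor accumulator over the sector's ordered CSF pairs
  acc$pair_acc <- numeric(length(engine$pair_tables$pair_keys))
  if (engine$n_core > 0L) {
    core <- engine$core
    grid <- expand.grid(nu = core, mu = core)   # nu = bra, mu = ket
    grid <- grid[grid$nu != grid$mu, ]
    ids <- match((grid$mu - 1) * engine$dim + grid$nu,
                 engine$pair_tables$pair_keys)
    keep <- !is.na(ids)
    acc$core_mu <- grid$mu[keep]
    acc$core_nu <- grid$nu[keep]
    acc$core_ids <- ids[keep]
  }
  class(acc) <- "rdm_accumulator"
  acc
}

flat_g <- function(n, i, j) i + (j - 1L) * n

flat_G <- function(n, i, j, k, l)
  i + (j - 1L) * n + (k - 1L) * n^2 + (l - 1L) * n^3


#' Accumulate explicit diagonal RDM contributions
#'
#' Adds the `c_mu^A c_mu^B`-weighted occupation products (and exchange
#' diagonals) of every CSF occupied in both replicas, and advances the
#' overlap normalization `sum_mu c_mu^A c_mu^B`.
#'
#' @param acc An [rdm_accumulator()].
#' @param population_a,population_b Replica weight vectors at the same
#'   iteration.
#' @return The accumulator, invisibly.
#' @export
accumulate_diagonal <- function(acc, population_a, population_b) {
  w <- population_a * population_b
  acc$norm <- acc$norm + sum(w)
  acc$iterations <- acc$iterations + 1L
  nz <- which(w != 0)
  if (length(nz) > 0L) {
    wv <- numeric(length(w)); wv[nz] <- w[nz]
    acc$accG <- acc$accG + as.numeric(Matrix::crossprod(acc$Dg, wv))
    acc$accGam <- acc$accGam + as.numeric(Matrix::crossprod(acc$DG, wv))
  }
  invisible(acc)
}

#' Accumulate off-diagonal RDM contributions from the spawn stream
#'
#' For each spawn `mu -> nu` the contribution
#' `c_mu^A c_nu^B <nu|e_r|mu> / (N_att p(route))` is added to every RDM
#' entry addressed by the pair's index routes, using the route probability
#' recorded at sampling time. Records without a positive route probability
#' are rejected.
#'
#' @param acc An [rdm_accumulator()].
#' @param spawns Spawn tibble from [spawn_step()] (parent coefficients of
#'   the spawning replica recorded at spawn time).
#' @param population_other Weight vector of the other replica at the same
#'   iteration.
#' @param scale Overall factor (1/2 when both replicas' spawn streams are
#'   accumulated, so the two independent estimates average).
#' @return The accumulator, invisibly.
#' @export
accumulate_offdiagonal <- function(acc, spawns, population_other, scale = 1) {
  if (nrow(spawns) == 0L) return(invisible(acc))
  p_gen <- spawns$p_gen
  if (any(!is.finite(p_gen)) || any(p_gen <= 0))
    stop("spawn record without a positive route probability; ",
         "cannot unbias the RDM contribution", call. = FALSE)
  child <- spawns$child
  f_all <- scale * spawns$parent_coeff * population_other[child] *
    spawns$count / (spawns$n_attempts * p_gen)
  keep <- which(f_all != 0)
  if (length(keep) == 0L) return(invisible(acc))
  # bra = child, ket = parent; aggregate scalar factors per pair id
  ids <- match((spawns$parent[keep] - 1) * acc$engine$dim + child[keep],
               acc$engine$pair_tables$pair_keys)
  hit <- which(!is.na(ids))
  if (length(hit) == 0L) return(invisible(acc))
  agg <- rowsum(f_all[keep][hit], ids[hit], reorder = FALSE)
  rows <- as.integer(rownames(agg))
  acc$pair_acc[rows] <- acc$pair_acc[rows] + as.numeric(agg)
  invisible(acc)
}

#' Accumulate exact RDM contributions of the deterministic core
#'
#' All ordered pairs of distinct core CSFs contribute deterministically
#' each iteration (they are excluded from the stochastic spawn stream), so
#' their RDM contributions carry no sampling noise.
#'
#' @inheritParams accumulate_diagonal
#' @return The accumulator, invisibly.
#' @export
accumulate_core_exact <- function(acc, population_a, population_b) {
  if (is.null(acc$core_mu))
    stop("accumulator was built without a deterministic core", call. = FALSE)
  # ket weight from replica A, bra weight from replica B; the ids address
  # the same per-pair factor accumulator the spawn stream feeds
  pf <- population_a[acc$core_mu] * population_b[acc$core_nu]
  acc$pair_acc[acc$core_ids] <- acc$pair_acc[acc$core_ids] + pf
  invisible(acc)
}

#' Finalize sampled RDMs
#'
#' Normalizes by the accumulated replica overlap, symmetrizes
#' (`gamma <- (gamma + gamma^T)/2`; `Gamma` averaged with its
#' `e_ij,kl = e_kl,ij` and hermitian `Gamma_ij,kl = Gamma_ji,lk` images)
#' and runs the invariant checks (`trace(gamma) = N`, partial trace,
#' `<S^2> = S(S+1)`), which are reported in the metadata.
#'
#' @param acc An [rdm_accumulator()].
#' @param meta Extra metadata stored on the result.
#' @return A finalized [rdm_pair()].
#' @export
finalize_rdms <- function(acc, meta = list()) {
  if (!inherits(acc, "rdm_accumulator"))
    stop("expected an `rdm_accumulator`", call. = FALSE)
  if (abs(acc$norm) < 1e-300)
    stop("vanishing replica overlap normalization; RDMs are undefined ",
         "(replicas never shared occupied CSFs in the window)", call. = FALSE)
  n <- acc$n
  pt <- acc$engine$pair_tables
  accG <- acc$accG + as.numeric(Matrix::crossprod(pt$Mg, acc$pair_acc))
  accGam <- acc$accGam + as.numeric(Matrix::crossprod(pt$MG, acc$pair_acc))
  gamma <- matrix(accG / acc$norm, n, n)
  Gamma <- array(accGam / acc$norm, rep(n, 4L))
  gamma <- (gamma + t(gamma)) / 2
  Gamma <- (Gamma + aperm(Gamma, c(3, 4, 1, 2)) +
              aperm(Gamma, c(2, 1, 4, 3)) + aperm(Gamma, c(4, 3, 2, 1))) / 4
  space <- acc$engine$space
  out <- rdm_pair(gamma, Gamma, space$n_electrons, space$twice_S,
                  finalized = TRUE,
                  meta = c(meta, list(iterations = acc$iterations,
                                      overlap_norm = acc$norm)))
  checks <- list(
    trace_gamma = sum(diag(gamma)),
    partial_trace_max_dev = {
      pt <- apply(Gamma, c(1, 2), function(x) sum(diag(matrix(x, n, n))))
      max(abs(pt - (space$n_electrons - 1) * gamma))
    },
    s2 = rdm_s2(out),
    s2_target = space$twice_S / 2 * (space$twice_S / 2 + 1))
  out$meta$checks <- checks
  out
}
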