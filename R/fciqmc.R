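# FCIQMC stochastic eigensolver over a CSF basis.
#
# Imaginary-time projection c(tau + dtau) = [1 - dtau (H - S)] c(tau),
# sampled stochastically: the off-diagonal part by spawning (each walker on
# parent |mu> suggests children |nu> with probability p_gen(nu|mu) and
# spawns weight -dtau H_numu c_mu / p_gen), the diagonal part by a
# deterministic death/clone factor, followed by annihilation of signed
# weights and a stochastic kill threshold.  Excitation generation uses the
# exact-column distribution p_gen(nu|mu) ∝ |H_numu| (optimal at desk
# scale); when RDM sampling is on, a small floor is mixed in over all
# generator-connected children so every density-matrix-contributing pair is
# reachable.  A deterministic core (the N_D energetically lowest CSFs) is
# propagated exactly; spawning within the core is suppressed.

#' Set up an FCIQMC engine for one sector
#'
#' Precomputes the sector Hamiltonian, per-column excitation-generation
#' tables, the deterministic core block, and (when RDM sampling is enabled)
#' the structural generator connectivity and diagonal RDM contribution
#' tables.
#'
#' @param integrals An [integral_set()].
#' @param space A [spin_space()].
#' @param n_core Size `N_D` of the deterministic core (0 disables it).
#' @param rdm Whether RDM sampling support is required.
#' @param rdm_floor Mixing weight of the uniform floor over
#'   generator-connected children, as a fraction of the column's maximum
#'   `|H|` (only with `rdm = TRUE`).
#' @return An environment of class `"fciqmc_engine"`.
#' @export
fciqmc_engine <- function(integrals, space, n_core = 0L, rdm = FALSE,
                          rdm_floor = 0.05) {
  assert_integral_set(integrals)
  assert_spin_space(space)
  drt <- build_drt(space)
  m <- as.integer(drt$dim)
  H <- build_hamiltonian(integrals, drt)
  eng <- new.env(parent = emptyenv())
  eng$integrals <- integrals
  eng$space <- space
  eng$drt <- drt
  eng$dim <- m
  eng$H <- H
  eng$Hdiag <- as.numeric(Matrix::diag(H))
  eng$rdm <- isTRUE(rdm)
  eng$rdm_floor <- rdm_floor
  eng$n_core <- min(as.integer(n_core), m)
  eng$core <- if (eng$n_core > 0L) sort(order(eng$Hdiag)[seq_len(eng$n_core)])
              else integer(0)
  eng$is_core <- rep(FALSE, m)
  eng$is_core[eng$core] <- TRUE
  eng$Hcore <- if (eng$n_core > 0L)
    as.matrix(H[eng$core, eng$core, drop = FALSE]) else NULL
  eng$columns <- vector("list", m)        # lazy p_gen tables, free parents
  eng$columns_core <- vector("list", m)   # lazy tables for core parents
  if (eng$rdm) {
    eng$pair_tables <- sector_pair_tables(drt)
    eng$struct <- eng$pair_tables$struct
  } else {
    eng$pair_tables <- NULL
    eng$struct <- NULL
  }
  eng$csfs <- vector("list", m)           # lazy csf objects
  eng$ref <- which.min(eng$Hdiag)
  class(eng) <- "fciqmc_engine"
  eng
}

#' @export
print.fciqmc_engine <- function(x, ...) {
  cat(sprintf(
    "<fciqmc_engine> dim %d, core N_D = %d, RDM sampling %s\n",
    x$dim, x$n_core, if (x$rdm) "on" else "off"))
  invisible(x)
}

# Union of |E_ij| and |e_ij,kl| supports: the generator connectivity used
# for the RDM sampling floor.
structural_matrix <- function(drt) {
  sector_pair_tables(drt)$struct
}

# One pass over all one- and two-body operator matrices of a sector,
# organized per (bra, ket) CSF pair: for every pair, the flat gamma/Gamma
# slots it contributes to and the coupling coefficients.  This is the
# matrix-route table the RDM accumulators consume (the windowed
# identify_excitation() enumeration is the independent cross-check).
# Cached on the DRT; intended for desk-scale sectors (the only ones RDM
# sampling runs on).
sector_pair_tables <- function(drt) {
  cache <- drt$cache
  if (!is.null(cache$pair_tables)) return(cache$pair_tables)
  n <- drt$space$n_orbitals
  m <- as.integer(drt$dim)
  bra_all <- integer(0); ket_all <- integer(0)
  slot_all <- integer(0); val_all <- numeric(0); kind_all <- integer(0)
  grab <- function(mat, slot, kind) {
    T <- methods::as(Matrix::drop0(mat, tol = 1e-12), "TsparseMatrix")
    if (length(T@x) == 0L) return(invisible(NULL))
    bra_all <<- c(bra_all, T@i + 1L)
    ket_all <<- c(ket_all, T@j + 1L)
    slot_all <<- c(slot_all, rep.int(slot, length(T@x)))
    val_all <<- c(val_all, T@x)
    kind_all <<- c(kind_all, rep.int(kind, length(T@x)))
    invisible(NULL)
  }
  for (i in seq_len(n)) for (j in seq_len(n))
    grab(generator_matrix(drt, i, j), flat_g(n, i, j), 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) for (l in seq_len(n))
    grab(two_body_matrix(drt, i, j, k, l), flat_G(n, i, j, k, l), 2L)
  diag_rows <- bra_all == ket_all
  one_body <- kind_all == 1L
  dsel_g <- diag_rows & one_body
  dsel_G <- diag_rows & !one_body
  # off-diagonal pairs get integer ids; contributions become sparse
  # (pair x slot) matrices so whole iterations reduce to vector updates
  key <- (as.numeric(ket_all) - 1) * m + bra_all
  off <- !diag_rows
  pair_keys <- sort(unique(key[off]))
  pair_id <- match(key[off], pair_keys)
  osel_g <- one_body[off]
  out <- list(
    Dg = Matrix::sparseMatrix(i = bra_all[dsel_g], j = slot_all[dsel_g],
                              x = val_all[dsel_g], dims = c(m, n * n)),
    DG = Matrix::sparseMatrix(i = bra_all[dsel_G], j = slot_all[dsel_G],
                              x = val_all[dsel_G], dims = c(m, n^4)),
    pair_keys = pair_keys,
    Mg = Matrix::sparseMatrix(i = pair_id[osel_g],
                              j = slot_all[off][osel_g],
                              x = val_all[off][osel_g],
                              dims = c(length(pair_keys), n * n)),
    MG = Matrix::sparseMatrix(i = pair_id[!osel_g],
                              j = slot_all[off][!osel_g],
                              x = val_all[off][!osel_g],
                              dims = c(length(pair_keys), n^4)),
    struct = Matrix::sparseMatrix(
      i = ((pair_keys - 1) %% m) + 1,
      j = ((pair_keys - 1) %/% m) + 1,
      x = rep(1, length(pair_keys)), dims = c(m, m)))
  cache$pair_tables <- out
  out
}

# Route table of one ordered (bra, ket) pair, from the sector tables.
pair_route_table <- function(engine, bra, ket) {
  pt <- engine$pair_tables
  id <- match((ket - 1) * engine$dim + bra, pt$pair_keys)
  if (is.na(id))
    return(list(gi = integer(0), gv = numeric(0),
                Gi = integer(0), Gv = numeric(0)))
  g <- pt$Mg[id, , drop = FALSE]
  G <- pt$MG[id, , drop = FALSE]
  gT <- methods::as(g, "TsparseMatrix")
  GT <- methods::as(G, "TsparseMatrix")
  list(gi = gT@j + 1L, gv = gT@x, Gi = GT@j + 1L, Gv = GT@x)
}

engine_csf <- function(eng, i) {
  x <- eng$csfs[[i]]
  if (is.null(x)) {
    x <- drt_csf(eng$drt, i)
    eng$csfs[[i]] <- x
  }
  x
}

# Excitation-generation table for one parent column: children indices,
# probabilities, and H elements.  `from_core` excludes core children
# (core-to-core propagation is deterministic).
engine_column <- function(eng, mu, from_core = FALSE) {
  store <- if (from_core) "columns_core" else "columns"
  tab <- eng[[store]][[mu]]
  if (!is.null(tab)) return(tab)
  hcol <- eng$H[, mu]
  idx <- which(hcol != 0)
  idx <- idx[idx != mu]
  h <- hcol[idx]
  if (eng$rdm) {
    sidx <- which(eng$struct[, mu] != 0)
    sidx <- sidx[sidx != mu]
    extra <- setdiff(sidx, idx)
    if (length(extra) > 0L) {
      idx <- c(idx, extra)
      h <- c(h, rep(0, length(extra)))
    }
    w <- abs(h)
    if (length(w) > 0L) {
      floor_w <- eng$rdm_floor * if (max(w) > 0) max(w) else 1
      w <- w + floor_w
    }
  } else {
    w <- abs(h)
  }
  if (from_core && length(idx) > 0L) {
    keep <- !eng$is_core[idx]
    idx <- idx[keep]; h <- h[keep]; w <- w[keep]
  }
  tab <- if (length(idx) == 0L) {
    list(idx = integer(0), p = numeric(0), h = numeric(0))
  } else {
    list(idx = idx, p = w / sum(w), h = h)
  }
  eng[[store]][[mu]] <- tab
  tab
}

#' Sample one excitation from a parent CSF
#'
#' Draws a child CSF from the exact-column distribution
#' `p_gen(nu|mu) ∝ |H_numu|` (plus the RDM floor when enabled). Any CSF
#' with a nonzero Hamiltonian element to the parent has `p_gen > 0`; the
#' returned `p_gen` is the exact total probability of generating that
#' child. Dead ends (no connected children) return `NULL` child.
#'
#' @param engine An [fciqmc_engine()].
#' @param parent Parent CSF index.
#' @param detail If `TRUE`, attach the [identify_excitation()] record of
#'   the sampled pair.
#' @return List with `child` (index or `NULL`), `p_gen`, `h` (Hamiltonian
#'   element), and optionally `record`.
#' @export
sample_excitation <- function(engine, parent, detail = FALSE) {
  tab <- engine_column(engine, parent, from_core = engine$is_core[parent])
  if (length(tab$idx) == 0L)
    return(list(child = NULL, p_gen = 0, h = 0))
  pick <- if (length(tab$idx) == 1L) 1L
          else sample.int(length(tab$idx), 1L, prob = tab$p)
  out <- list(child = tab$idx[pick], p_gen = tab$p[pick], h = tab$h[pick])
  if (detail)
    out$record <- identify_excitation(engine_csf(engine, tab$idx[pick]),
                                      engine_csf(engine, parent))
  out
}

#' One spawning sweep over a walker population
#'
#' Every occupied parent `mu` makes `N_att = max(1, ceiling(|c_mu|))`
#' attempts; each sampled child `nu` receives weight
#' `-dtau * H_numu * c_mu / (N_att * p_gen(nu|mu))`, so the expected
#' spawned weight onto `nu` is `-dtau * H_numu * c_mu`. Attempts with
#' `dtau * |H| / p_gen > 1` are flagged as blooms (time-step contract).
#'
#' @param engine An [fciqmc_engine()].
#' @param population Numeric weight vector over the basis.
#' @param dtau Imaginary time step.
#' @return A list with `spawns` (tibble: `parent`, `child`, `parent_coeff`,
#'   `n_attempts`, `count`, `p_gen`, `h`, `weight`), `blooms`, and
#'   `null_events`.
#' @export
spawn_step <- function(engine, population, dtau) {
  parents <- which(population != 0)
  blooms <- 0L
  nulls <- 0L
  acc <- list()
  for (mu in parents) {
    cmu <- population[mu]
    natt <- max(1L, as.integer(ceiling(abs(cmu))))
    tab <- engine_column(engine, mu, from_core = engine$is_core[mu])
    if (length(tab$idx) == 0L) { nulls <- nulls + natt; next }
    counts <- if (length(tab$idx) == 1L) natt
              else as.integer(stats::rmultinom(1L, natt, tab$p))
    hit <- which(counts > 0L)
    if (length(hit) == 0L) next
    w <- -dtau * tab$h[hit] * cmu * counts[hit] / (natt * tab$p[hit])
    blooms <- blooms + sum(counts[hit][dtau * abs(tab$h[hit]) / tab$p[hit] > 1])
    acc[[length(acc) + 1L]] <- list(
      parent = rep.int(mu, length(hit)), child = tab$idx[hit],
      parent_coeff = rep.int(cmu, length(hit)),
      n_attempts = rep.int(natt, length(hit)), count = counts[hit],
      p_gen = tab$p[hit], h = tab$h[hit], weight = w)
  }
  cols <- c("parent", "child", "parent_coeff", "n_attempts", "count",
            "p_gen", "h", "weight")
  vals <- if (length(acc) == 0L) {
    list(integer(0), integer(0), numeric(0), integer(0), integer(0),
         numeric(0), numeric(0), numeric(0))
  } else {
    lapply(cols, function(cn) unlist(lapply(acc, `[[`, cn), use.names = FALSE))
  }
  names(vals) <- cols
  spawns <- tibble::new_tibble(vals, nrow = length(vals$parent))
  list(spawns = spawns, blooms = blooms, null_events = nulls)
}

#' Deterministic death/clone step
#'
#' Scales every weight by `1 - dtau (H_mumu - shift)`; no stochastic
#' rounding of the diagonal step. With a deterministic core active, the
#' core block is instead propagated exactly
#' (`c_core <- c_core - dtau (H_core - shift) c_core`), which includes the
#' core's off-diagonal elements — see [semistochastic_project()].
#'
#' @inheritParams spawn_step
#' @param shift Current energy shift.
#' @return Updated population vector.
#' @export
death_clone_step <- function(engine, population, shift, dtau) {
  out <- population * (1 - dtau * (engine$Hdiag - shift))
  if (engine$n_core > 0L)
    out[engine$core] <- semistochastic_project(engine, population, shift, dtau)
  out
}

#' Exact propagation within the deterministic core
#'
#' Applies `[1 - dtau (H_core - shift)]` exactly to the core weights:
#' core-to-core propagation is the exact matrix application and stochastic
#' spawning within the core is suppressed.
#'
#' @inheritParams death_clone_step
#' @return Updated core weights (in core order).
#' @export
semistochastic_project <- function(engine, population, shift, dtau) {
  if (engine$n_core == 0L)
    stop("engine has no deterministic core", call. = FALSE)
  cc <- population[engine$core]
  cc - dtau * (as.numeric(engine$Hcore %*% cc) - shift * cc)
}

#' Annihilation and stochastic kill threshold
#'
#' Sums spawned weights per child into the population (exact cancellation
#' of opposite signs), then removes entries below the kill threshold
#' stochastically with magnitude-preserving expectation: an entry with
#' `|c| < kappa` survives as `sign(c) * kappa` with probability
#' `|c| / kappa`. Core entries are exempt.
#'
#' @param population Numeric weight vector.
#' @param spawns Spawn tibble from [spawn_step()] (or any data frame with
#'   `child` and `weight`).
#' @param kill_threshold Threshold `kappa` (default 1, real walker
#'   weights).
#' @param protect Indices exempt from the stochastic kill (the
#'   deterministic core).
#' @return Updated population vector.
#' @export
annihilate <- function(population, spawns, kill_threshold = 1,
                       protect = integer(0)) {
  out <- population
  if (nrow(spawns) > 0L) {
    add <- rowsum(spawns$weight, spawns$child, reorder = FALSE)
    idx <- as.integer(rownames(add))
    out[idx] <- out[idx] + as.numeric(add)
  }
  if (kill_threshold > 0) {
    small <- which(out != 0 & abs(out) < kill_threshold)
    if (length(protect) > 0L) small <- setdiff(small, protect)
    if (length(small) > 0L) {
      keep <- stats::runif(length(small)) < abs(out[small]) / kill_threshold
      out[small] <- ifelse(keep, sign(out[small]) * kill_threshold, 0)
    }
  }
  out
}

#' Population-control shift update
#'
#' In the variable-shift phase,
#' `shift <- shift - damping / (interval * dtau) * log(N_w / N_w_prev)`;
#' the long-run mean of the shift estimates the ground-state energy.
#'
#' @param shift Current shift.
#' @param n_walkers,n_walkers_prev Total walker number now and `interval`
#'   iterations ago.
#' @param dtau Time step.
#' @param damping Damping factor zeta (default 0.05).
#' @param interval Update interval A in iterations (default 10).
#' @return New shift value.
#' @export
update_shift <- function(shift, n_walkers, n_walkers_prev, dtau,
                         damping = 0.05, interval = 10L) {
  if (n_walkers <= 0 || n_walkers_prev <= 0)
    stop("walker population died out; cannot update the shift", call. = FALSE)
  shift - damping / (interval * dtau) * log(n_walkers / n_walkers_prev)
}

# --- seeded RNG streams ------------------------------------------------

rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  st <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  env <- new.env(parent = emptyenv())
  env$state <- st
  env$seed <- seed
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

rng_fingerprint <- function(seed, n = 8L) {
  st <- rng_stream(seed)
  with_stream(st, stats::runif(n))
}

# --- full dynamics ------------------------------------------------------

#' Run FCIQMC dynamics
#'
#' Two-replica stochastic imaginary-time propagation with spawning,
#' deterministic death/clone, annihilation, adaptive shift control,
#' optional semistochastic core, and unbiased two-replica RDM sampling
#' over the post-burn-in window. Replicas use distinct seeded RNG streams
#' and never share random numbers; identical seeds and configuration give
#' bit-identical trajectories.
#'
#' @param integrals An [integral_set()].
#' @param space A [spin_space()].
#' @param n_iterations Number of propagation steps.
#' @param dtau Imaginary time step (must satisfy the stability contract;
#'   attempts with `dtau |H| / p_gen > 1` are logged as blooms).
#' @param target_walkers Walker number at which the variable-shift
#'   (population control) phase begins.
#' @param seeds Integer seeds for replicas A and B (distinct when RDM
#'   sampling is enabled).
#' @param rdm Sample the spin-free 1- and 2-RDMs (two replicas).
#' @param n_core Deterministic-core size `N_D` (0 disables).
#' @param burnin Fraction of iterations discarded before estimator
#'   averaging and RDM accumulation (default 0.2).
#' @param kill_threshold Stochastic kill threshold (default 1).
#' @param shift_damping,shift_interval Shift-update parameters zeta and A.
#' @param initial_walkers Starting weight on the reference CSF.
#' @param rdm_floor Floor fraction for RDM-aware excitation generation.
#' @param single_replica_rdm Diagnostic mode: accumulate the diagonal RDM
#'   from one replica only (`c^A c^A`), exposing the positive stochastic
#'   bias the replica trick removes. Off-diagonal sampling is unchanged.
#' @return An object of class `"fciqmc_run"`: `trajectory` (tibble with
#'   `iteration`, `shift`, `e_proj`, `n_walkers_a`, `n_walkers_b`,
#'   `blooms`), `rdms` (finalized [rdm_pair()] or `NULL`), `reference`,
#'   `engine`, `config`.
#' @export
run_fciqmc <- function(integrals, space, n_iterations = 2000L, dtau = 0.01,
                       target_walkers = 200, seeds = c(7, 11),
                       rdm = FALSE, n_core = 0L, burnin = 0.2,
                       kill_threshold = 1, shift_damping = 0.05,
                       shift_interval = 10L, initial_walkers = 10,
                       rdm_floor = 0.05, single_replica_rdm = FALSE) {
  if (rdm && length(seeds) >= 2L && seeds[1] == seeds[2])
    stop("RDM sampling requires distinct replica seeds", call. = FALSE)
  if (dtau <= 0) stop("`dtau` must be positive", call. = FALSE)
  eng <- fciqmc_engine(integrals, space, n_core = n_core, rdm = rdm,
                       rdm_floor = rdm_floor)
  m <- eng$dim
  n_rep <- if (rdm) 2L else 1L
  streams <- lapply(seeds[seq_len(n_rep)], rng_stream)
  burn_iter <- as.integer(ceiling(burnin * n_iterations))
  pops <- vector("list", n_rep)
  shifts <- numeric(n_rep)
  variable <- logical(n_rep)
  nw_prev <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pops[[r]] <- numeric(m)
    pops[[r]][eng$ref] <- initial_walkers
    shifts[r] <- eng$Hdiag[eng$ref]
    nw_prev[r] <- initial_walkers
  }
  ref_proj <- eng$ref
  href <- eng$H[ref_proj, ]
  acc <- if (rdm) rdm_accumulator(eng) else NULL
  traj <- list(iteration = integer(n_iterations), shift = numeric(n_iterations),
               e_proj = numeric(n_iterations),
               n_walkers_a = numeric(n_iterations),
               n_walkers_b = numeric(n_iterations),
               blooms = integer(n_iterations))
  for (it in seq_len(n_iterations)) {
    pre <- pops
    blooms_it <- 0L
    spawn_list <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      sp <- with_stream(streams[[r]], spawn_step(eng, pops[[r]], dtau))
      blooms_it <- blooms_it + sp$blooms
      spawn_list[[r]] <- sp$spawns
      newpop <- death_clone_step(eng, pops[[r]], shifts[r], dtau)
      newpop <- with_stream(streams[[r]],
        annihilate(newpop, sp$spawns, kill_threshold, protect = eng$core))
      pops[[r]] <- newpop
      nw <- sum(abs(newpop))
      if (nw == 0)
        stop(sprintf("walker population of replica %d died out at iteration %d",
                     r, it), call. = FALSE)
      if (it %% shift_interval == 0L) {
        if (variable[r]) {
          shifts[r] <- update_shift(shifts[r], nw, nw_prev[r], dtau,
                                    shift_damping, shift_interval)
        } else if (nw >= target_walkers) {
          # entering population control: one undamped correction from the
          # interval-averaged growth puts the shift near the ground energy,
          # so the population stabilizes near the target without overshoot
          variable[r] <- TRUE
          shifts[r] <- shifts[r] -
            log(nw / nw_prev[r]) / (shift_interval * dtau)
        }
        nw_prev[r] <- nw
      }
    }
    if (it == burn_iter) {
      ref_proj <- which.max(abs(pops[[1L]]))
      href <- eng$H[ref_proj, ]
    }
    if (rdm && it > burn_iter) {
      cA <- pre[[1L]]
      cB <- if (single_replica_rdm) pre[[1L]] else pre[[2L]]
      accumulate_diagonal(acc, cA, cB)
      off_scale <- if (single_replica_rdm) 1 else 0.5
      accumulate_offdiagonal(acc, spawn_list[[1L]], cB, scale = off_scale)
      if (!single_replica_rdm)
        accumulate_offdiagonal(acc, spawn_list[[2L]], cA, scale = off_scale)
      if (eng$n_core > 0L) accumulate_core_exact(acc, cA, cB)
    }
    cref <- pops[[1L]][ref_proj]
    traj$iteration[it] <- it
    traj$shift[it] <- shifts[1L]
    traj$e_proj[it] <- if (cref != 0)
      sum(href * pops[[1L]]) / cref else NA_real_
    traj$n_walkers_a[it] <- sum(abs(pops[[1L]]))
    traj$n_walkers_b[it] <- if (n_rep > 1L) sum(abs(pops[[2L]])) else NA_real_
    traj$blooms[it] <- blooms_it
  }
  rdms <- if (rdm) finalize_rdms(acc, meta = list(
    window = c(burn_iter + 1L, n_iterations), seeds = seeds[seq_len(n_rep)],
    single_replica_diagonal = single_replica_rdm)) else NULL
  structure(
    list(trajectory = tibble::as_tibble(traj), rdms = rdms,
         reference = ref_proj, engine = eng, populations = pops,
         config = list(n_iterations = n_iterations, dtau = dtau,
                       target_walkers = target_walkers, seeds = seeds,
                       rdm = rdm, n_core = n_core, burnin = burnin,
                       kill_threshold = kill_threshold,
                       shift_damping = shift_damping,
                       shift_interval = shift_interval,
                       initial_walkers = initial_walkers,
                       rdm_floor = rdm_floor,
                       single_replica_rdm = single_replica_rdm),
         burn_iter = burn_iter),
    class = "fciqmc_run")
}

#' @export
print.fciqmc_run <- function(x, ...) {
  est <- fciqmc_energy(x)
  cat(sprintf(
    "<fciqmc_run> %d iterations, dim %d; E_proj = %.6f (se %.2g), mean shift = %.6f\n",
    x$config$n_iterations, x$engine$dim,
    est$estimate[est$estimator == "projected"],
    est$se[est$estimator == "projected"],
    est$estimate[est$estimator == "shift"]))
  invisible(x)
}

#' Energy estimates of an FCIQMC run
#'
#' Post-burn-in means of the projected energy and the shift, with blocked
#' standard errors (the blocking absorbs serial correlation).
#'
#' @param run An [run_fciqmc()] result.
#' @param n_blocks Number of blocks for the standard error.
#' @return A tibble with `estimator`, `estimate`, `se`, `n`.
#' @export
fciqmc_energy <- function(run, n_blocks = 32L) {
  tr <- run$trajectory
  keep <- tr$iteration > run$burn_iter
  out <- lapply(list(projected = tr$e_proj[keep], shift = tr$shift[keep]),
                function(x) {
    x <- x[is.finite(x)]
    nb <- max(2L, min(n_blocks, length(x) %/% 4L))
    bl <- split(x, cut(seq_along(x), nb, labels = FALSE))
    bm <- vapply(bl, mean, 1)
    c(mean(x), stats::sd(bm) / sqrt(length(bm)), length(x))
  })
  tibble::tibble(
    estimator = names(out),
    estimate = vapply(out, `[[`, 1, 1L),
    se = vapply(out, `[[`, 1, 2L),
    n = vapply(out, `[[`, 1, 3L))
}

#' @export
glance.fciqmc_run <- function(x, ...) {
  est <- fciqmc_energy(x)
  tibble::tibble(
    dim = x$engine$dim,
    n_iterations = x$config$n_iterations,
    e_projected = est$estimate[est$estimator == "projected"],
    se_projected = est$se[est$estimator == "projected"],
    e_shift = est$estimate[est$estimator == "shift"],
    se_shift = est$se[est$estimator == "shift"],
    blooms = sum(x$trajectory$blooms),
    rdm = x$config$rdm)
}

#' @export
tidy.fciqmc_run <- function(x, ...) x$trajectory

#' @export
autoplot.fciqmc_run <- function(object, ...) {
  tr <- object$trajectory
  dat <- dplyr::bind_rows(
    tibble::tibble(iteration = tr$iteration, value = tr$e_proj,
                   series = "projected energy"),
    tibble::tibble(iteration = tr$iteration, value = tr$shift,
                   series = "shift"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value,
                                    color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$burn_iter, linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = "energy (hartree)", color = NULL) +
    ggplot2::theme_minimal()
}
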