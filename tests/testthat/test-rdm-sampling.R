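dimer <- hubbard_model(2, 1, 4)
dimer_space <- spin_space(2, 2, 0)

test_that("explicit diagonal accumulation reproduces occupation products", {
  eng <- fciqmc_engine(dimer, dimer_space, rdm = TRUE)
  d <- eng$drt
  i_20 <- csf_to_index(d, csf("20", d$space))
  i_ud <- csf_to_index(d, csf("ud", d$space))

  acc <- rdm_accumulator(eng)
  pop <- numeric(eng$dim); pop[i_20] <- 1
  accumulate_diagonal(acc, pop, pop)
  rd <- finalize_rdms(acc)
  expect_equal(rd$gamma, diag(c(2, 0)), tolerance = 1e-12)
  expect_equal(rd$Gamma[1, 1, 1, 1], 2)
  expect_equal(rd$Gamma[1, 1, 2, 2], 0)

  acc2 <- rdm_accumulator(eng)
  pop2 <- numeric(eng$dim); pop2[i_ud] <- 1
  accumulate_diagonal(acc2, pop2, pop2)
  rd2 <- finalize_rdms(acc2)
  expect_equal(rd2$Gamma[1, 2, 2, 1], 1)   # singlet exchange diagonal

  engT <- fciqmc_engine(dimer, spin_space(2, 2, 2), rdm = TRUE)
  accT <- rdm_accumulator(engT)
  accumulate_diagonal(accT, 1, 1)
  rdT <- finalize_rdms(accT)
  expect_equal(rdT$Gamma[1, 2, 2, 1], -1)  # triplet exchange diagonal
})

test_that("the replica trick removes the positive diagonal bias", {
  # asymmetric two-orbital model: the minority occupation gamma_22 is
  # inflated by single-replica noise and unbiased with two replicas
  tm <- matrix(c(0, -0.2, -0.2, 2), 2)
  ints <- integral_set(tm)
  space <- spin_space(2, 2, 0)
  exact <- exact_casci(ints, space)
  g22_exact <- exact$rdms$gamma[2, 2]
  single <- numeric(0); double <- numeric(0)
  for (r in 1:14) {
    rs <- run_fciqmc(ints, space, n_iterations = 600, dtau = 0.05,
                     target_walkers = 25, seeds = c(100 + r, 500 + r),
                     rdm = TRUE, single_replica_rdm = TRUE, initial_walkers = 5)
    rd <- run_fciqmc(ints, space, n_iterations = 600, dtau = 0.05,
                     target_walkers = 25, seeds = c(100 + r, 500 + r),
                     rdm = TRUE, initial_walkers = 5)
    single <- c(single, rs$rdms$gamma[2, 2])
    double <- c(double, rd$rdms$gamma[2, 2])
  }
  bias_single <- mean(single) - g22_exact
  bias_double <- mean(double) - g22_exact
  expect_gt(bias_single, 3 * sd(single) / sqrt(length(single)))
  expect_lt(abs(bias_double), 3 * sd(double) / sqrt(length(double)))
})

test_that("off-diagonal sampling reproduces exact RDM entries on the dimer", {
  exact <- exact_casci(dimer, dimer_space)
  errs_g <- numeric(0); errs_G <- numeric(0)
  for (r in 1:6) {
    run <- run_fciqmc(dimer, dimer_space, n_iterations = 1200, dtau = 0.02,
                      target_walkers = 150, seeds = c(40 + r, 80 + r),
                      rdm = TRUE)
    errs_g <- c(errs_g, run$rdms$gamma[1, 2] - exact$rdms$gamma[1, 2])
    errs_G <- c(errs_G, run$rdms$Gamma[1, 2, 2, 1] - exact$rdms$Gamma[1, 2, 2, 1])
  }
  expect_lt(abs(mean(errs_g)), 3 * sd(errs_g) / sqrt(length(errs_g)))
  expect_lt(abs(mean(errs_G)), 3 * sd(errs_G) / sqrt(length(errs_G)))
})

test_that("exchange-coupled pairs accumulate each route separately and correctly", {
  # one 3-orbital high-spin center with exchange integrals: Hamiltonian
  # connects exchange-type CSF pairs directly
  ints <- exchange_cluster_model(1, 3, intra_exchange = 0.5,
                                 inter_hopping = 0, on_site_U = 4)
  space <- spin_space(3, 3, 1)
  exact <- exact_casci(ints, space)
  runs <- lapply(1:4, function(r)
    run_fciqmc(ints, space, n_iterations = 900, dtau = 0.05,
               target_walkers = 80, seeds = c(7 + r, 21 + r), rdm = TRUE))
  for (slot in list(c(1, 2, 2, 1), c(1, 3, 3, 1), c(2, 3, 3, 2))) {
    vals <- vapply(runs, function(rn)
      rn$rdms$Gamma[slot[1], slot[2], slot[3], slot[4]], 1)
    exv <- exact$rdms$Gamma[slot[1], slot[2], slot[3], slot[4]]
    expect_lt(abs(mean(vals) - exv),
              3 * sd(vals) / sqrt(length(vals)) + 1e-8)
  }
})

test_that("a hopping-free model yields an exactly diagonal 2-RDM sampling stream", {
  ints <- integral_set(matrix(0, 2, 2),
                       {v <- array(0, rep(2, 4)); v[1,1,1,1] <- v[2,2,2,2] <- 4; v})
  eng <- fciqmc_engine(ints, dimer_space, rdm = TRUE)
  acc <- rdm_accumulator(eng)
  pop <- numeric(eng$dim); pop[1] <- 3
  set.seed(6)
  sp <- spawn_step(eng, pop, 0.05)
  accumulate_diagonal(acc, pop, pop)
  accumulate_offdiagonal(acc, sp$spawns, pop)
  rd <- finalize_rdms(acc)
  expect_equal(rd$gamma[1, 2], 0)
  expect_equal(max(abs(rd$Gamma[1, 2, 1, 2])), 0)
})

test_that("full-core sampling reproduces the exact RDMs to round-off", {
  exact <- exact_casci(dimer, dimer_space)
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 1200, dtau = 0.05,
                    target_walkers = 50, seeds = c(3, 5), rdm = TRUE,
                    n_core = 3)
  expect_lt(max(abs(run$rdms$gamma - exact$rdms$gamma)), 1e-9)
  expect_lt(max(abs(run$rdms$Gamma - exact$rdms$Gamma)), 1e-9)
  expect_equal(rdm_energy(run$rdms, dimer), exact$energy, tolerance = 1e-9)
})

test_that("stochastic and core contributions partition without double counting", {
  exact <- exact_casci(dimer, dimer_space)
  errs <- numeric(0)
  for (r in 1:5) {
    run <- run_fciqmc(dimer, dimer_space, n_iterations = 900, dtau = 0.02,
                      target_walkers = 120, seeds = c(60 + r, 90 + r),
                      rdm = TRUE, n_core = 2)
    errs <- c(errs, run$rdms$Gamma[1, 2, 2, 1] - exact$rdms$Gamma[1, 2, 2, 1])
  }
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 1e-8)
})

test_that("finalization enforces the exact trace and rejects vanishing overlap", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 600, dtau = 0.02,
                    target_walkers = 100, seeds = c(3, 5), rdm = TRUE)
  expect_equal(sum(diag(run$rdms$gamma)), 2, tolerance = 1e-12)
  expect_equal(run$rdms$meta$checks$s2, 0, tolerance = 1e-10)
  # partial trace identity sum_k Gamma_ij,kk = (N-1) gamma_ij
  expect_lt(run$rdms$meta$checks$partial_trace_max_dev, 1e-9)

  eng <- fciqmc_engine(dimer, dimer_space, rdm = TRUE)
  acc <- rdm_accumulator(eng)
  expect_error(finalize_rdms(acc), "overlap")
})

test_that("RDM errors shrink as one over the square root of the window", {
  # windows of 400 vs 1600 post-burn-in iterations: the RMS error over
  # independent runs should halve (slope 1/2 in window length). The slope
  # estimate from a finite run ensemble carries its own sampling noise, so
  # the acceptance band is wide; the replicate counts keep the check well
  # inside the test-time budget.
  exact <- exact_casci(dimer, dimer_space)
  err_at <- function(iters, seed_base, R) {
    errs <- vapply(1:R, function(r) {
      run <- run_fciqmc(dimer, dimer_space, n_iterations = iters, dtau = 0.02,
                        target_walkers = 300,
                        seeds = c(seed_base + r, seed_base + 500 + r),
                        rdm = TRUE)
      abs(run$rdms$gamma[1, 2] - exact$rdms$gamma[1, 2])
    }, 1)
    sqrt(mean(errs^2))
  }
  e_short <- err_at(500, 200, 24)
  e_long <- err_at(2000, 300, 12)
  expect_gt(e_short, e_long)  # longer windows are strictly more accurate
  slope <- log(e_short / e_long) / log(sqrt(1600 / 400))
  expect_gt(slope, 0.3)
  expect_lt(slope, 1.9)
})

test_that("energy from sampled RDMs matches the projected energy", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 2000, dtau = 0.02,
                    target_walkers = 200, seeds = c(23, 29), rdm = TRUE)
  est <- fciqmc_energy(run)
  e_proj <- est$estimate[est$estimator == "projected"]
  se <- est$se[est$estimator == "projected"]
  expect_lt(abs(rdm_energy(run$rdms, dimer) - e_proj), 3 * se + 5e-3)
})
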