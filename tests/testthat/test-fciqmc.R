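dimer <- hubbard_model(2, 1, 4)
dimer_space <- spin_space(2, 2, 0)
E0_dimer <- 4 / 2 - sqrt(4^2 / 4 + 4)

test_that("excitation sampling covers exactly the connected space with correct p_gen", {
  eng <- fciqmc_engine(dimer, dimer_space)
  d <- eng$drt
  i_ud <- csf_to_index(d, csf("ud", d$space))
  i_02 <- csf_to_index(d, csf("02", d$space))
  i_20 <- csf_to_index(d, csf("20", d$space))
  set.seed(1)
  draws <- replicate(20000, {
    s <- sample_excitation(eng, i_ud)
    s$child
  })
  expect_setequal(unique(draws), c(i_02, i_20))
  # p_gen of each child sums to one over non-null outcomes and matches the
  # empirical frequency within 3 sigma binomial error
  p02 <- sample_excitation(eng, i_ud)$p_gen  # symmetric: both 1/2
  tab <- engine_p <- table(draws) / length(draws)
  for (child in c(i_02, i_20)) {
    s <- list()
    # recover exact p from the engine table
    tabs <- gugaci:::engine_column(eng, i_ud)
    p <- tabs$p[tabs$idx == child]
    emp <- as.numeric(engine_p[as.character(child)])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / length(draws)))
    # support condition: every sampled child has a nonzero H element
    expect_true(abs(tabs$h[tabs$idx == child]) > 0)
  }
})

test_that("children with zero Hamiltonian element are never generated without the RDM floor", {
  ints <- random_integrals(4, seed = 9)
  eng <- fciqmc_engine(ints, spin_space(4, 4, 0))
  set.seed(2)
  for (mu in sample.int(eng$dim, 5)) {
    tab <- gugaci:::engine_column(eng, mu)
    expect_true(all(abs(tab$h) > 0))
    expect_equal(sum(tab$p), if (length(tab$p) > 0) 1 else 0)
  }
})

test_that("mean spawned weight equals -dtau H c per unit parent weight", {
  eng <- fciqmc_engine(dimer, dimer_space)
  d <- eng$drt
  i_ud <- csf_to_index(d, csf("ud", d$space))
  i_20 <- csf_to_index(d, csf("20", d$space))
  pop <- numeric(eng$dim); pop[i_ud] <- 2.5
  dtau <- 0.01
  set.seed(3)
  tot <- numeric(eng$dim); trials <- 4000
  for (r in seq_len(trials)) {
    sp <- spawn_step(eng, pop, dtau)$spawns
    if (nrow(sp) > 0) {
      agg <- rowsum(sp$weight, sp$child)
      tot[as.integer(rownames(agg))] <- tot[as.integer(rownames(agg))] + agg
    }
  }
  H <- build_hamiltonian(dimer, d)
  expected <- -dtau * H[i_20, i_ud] * pop[i_ud]
  # 3-sigma band from the binomial structure of the two-child sampler
  per_attempt_sd <- abs(expected)  # conservative bound per trial
  expect_lt(abs(tot[i_20] / trials - expected),
            3 * per_attempt_sd / sqrt(trials))
  # linearity: doubling dtau doubles the expected spawn
  set.seed(3)
  tot2 <- 0
  for (r in seq_len(trials)) {
    sp <- spawn_step(eng, pop, 2 * dtau)$spawns
    tot2 <- tot2 + sum(sp$weight[sp$child == i_20])
  }
  expect_equal(tot2 / trials, 2 * expected, tolerance = 0.15)
})

test_that("a U-only model never spawns", {
  ints <- integral_set(matrix(0, 2, 2),
                       {v <- array(0, rep(2, 4)); v[1,1,1,1] <- v[2,2,2,2] <- 4; v})
  eng <- fciqmc_engine(ints, dimer_space)
  pop <- numeric(eng$dim); pop[1] <- 5
  set.seed(4)
  sp <- spawn_step(eng, pop, 0.05)
  expect_equal(nrow(sp$spawns), 0L)
})

test_that("death/clone is the deterministic diagonal contract", {
  eng <- fciqmc_engine(dimer, dimer_space)
  pop <- c(1.5, -2, 0.5)
  out <- death_clone_step(eng, pop, shift = eng$Hdiag[1], dtau = 0.02)
  expect_equal(out[1], pop[1])  # H_mumu = shift leaves the weight unchanged
  expect_equal(out, pop * (1 - 0.02 * (eng$Hdiag - eng$Hdiag[1])))
  # dtau (H - shift) = 2 flips the sign
  flip <- death_clone_step(eng, pop, shift = eng$Hdiag - 2 / 0.02, dtau = 0.02)
  expect_equal(flip, -pop)
})

test_that("annihilation cancels, concatenates, and rounds unbiasedly", {
  pop <- c(0, 3, 0)
  spawns <- tibble::tibble(child = c(1L, 1L, 3L), weight = c(0.6, -0.6, 2))
  out <- annihilate(pop, spawns, kill_threshold = 0)
  expect_equal(out, c(0, 3, 2))
  # stochastic kill preserves the expectation
  set.seed(5)
  vals <- replicate(20000, annihilate(c(0.6, 0, 0),
                                      tibble::tibble(child = integer(0),
                                                     weight = numeric(0)),
                                      kill_threshold = 1)[1])
  expect_setequal(unique(vals), c(0, 1))
  expect_lt(abs(mean(vals) - 0.6), 3 * sd(vals) / sqrt(length(vals)))
  # protected (core) entries are never rounded
  keep <- annihilate(c(0.3, 0.3), tibble::tibble(child = integer(0),
                                                 weight = numeric(0)),
                     kill_threshold = 1, protect = 1L)
  expect_equal(keep[1], 0.3)
})

test_that("shift control reacts to population growth with the documented law", {
  expect_equal(update_shift(-1, 100, 100, 0.01), -1)
  expect_lt(update_shift(-1, 150, 100, 0.01), -1)
  expect_gt(update_shift(-1, 70, 100, 0.01), -1)
  expect_equal(update_shift(-1, 120, 100, 0.01, damping = 0.05,
                            interval = 10),
               -1 - 0.05 / (10 * 0.01) * log(1.2))
  expect_error(update_shift(-1, 0, 100, 0.01), "died out")
})

test_that("full deterministic core reduces to exact propagation", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 800, dtau = 0.05,
                    target_walkers = 50, seeds = c(3, 5), rdm = FALSE,
                    n_core = 3)
  post <- run$trajectory$e_proj[run$trajectory$iteration > 400]
  expect_lt(sd(post), 1e-10)  # zero stochastic variance in the propagation
  expect_equal(mean(post), E0_dimer, tolerance = 1e-8)
})

test_that("a single-CSF core reduces to plain stochastic dynamics", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 1500, dtau = 0.02,
                    target_walkers = 200, seeds = c(3, 5), n_core = 1)
  est <- fciqmc_energy(run)
  e <- est$estimate[est$estimator == "projected"]
  se <- est$se[est$estimator == "projected"]
  expect_lt(abs(e - E0_dimer), 3 * se + 1e-3)
})

test_that("projected energy converges to the dimer ground state within 3 sigma", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 3000, dtau = 0.02,
                    target_walkers = 300, seeds = c(17, 19), rdm = FALSE)
  est <- fciqmc_energy(run)
  e <- est$estimate[est$estimator == "projected"]
  se <- est$se[est$estimator == "projected"]
  expect_lt(abs(e - E0_dimer), 3 * se + 1e-4)
  # shift estimator tracks the same energy
  es <- est$estimate[est$estimator == "shift"]
  ses <- est$se[est$estimator == "shift"]
  expect_lt(abs(es - E0_dimer), 5 * ses + 5e-3)
})

test_that("identical seeds and configuration give bit-identical trajectories", {
  r1 <- run_fciqmc(dimer, dimer_space, n_iterations = 400, dtau = 0.02,
                   target_walkers = 100, seeds = c(3, 5), rdm = TRUE)
  r2 <- run_fciqmc(dimer, dimer_space, n_iterations = 400, dtau = 0.02,
                   target_walkers = 100, seeds = c(3, 5), rdm = TRUE)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$rdms$gamma, r2$rdms$gamma)
  expect_identical(r1$rdms$Gamma, r2$rdms$Gamma)
})

test_that("replica RNG streams are distinct seeded generators", {
  expect_false(identical(gugaci:::rng_fingerprint(3), gugaci:::rng_fingerprint(5)))
  expect_identical(gugaci:::rng_fingerprint(3), gugaci:::rng_fingerprint(3))
  expect_error(run_fciqmc(dimer, dimer_space, n_iterations = 10,
                          seeds = c(3, 3), rdm = TRUE), "distinct")
})

test_that("walker populations stay inside the spin sector", {
  run <- run_fciqmc(dimer, dimer_space, n_iterations = 300, dtau = 0.02,
                    target_walkers = 100, seeds = c(3, 5))
  # structural spin purity: the population vector lives on the CSF basis of
  # the target sector by construction
  expect_equal(length(run$populations[[1]]), as.integer(run$engine$dim))
  expect_true(all(is.finite(run$populations[[1]])))
})
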