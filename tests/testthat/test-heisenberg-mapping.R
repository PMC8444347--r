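test_that("two-site model energies reproduce the Lande pattern", {
  me <- model_energies(0:5, J = 1)
  expect_equal(me$energy, (0:5) * (1:6) / 2, tolerance = 1e-12)
  expect_equal(me$energy[6], 15)   # E(5) - E(0) = 15 J
  flat <- model_energies(0:5, J = 0, J_biquadratic = 0)
  expect_equal(flat$energy, rep(0, 6))
  expect_error(model_energies(6, J = 1), "coupling range")
})

test_that("model energies equal exact two-site spin-model spectra", {
  set.seed(31)
  for (r in 1:100) {
    S_A <- sample(1:6, 1) / 2
    S_B <- sample(1:6, 1) / 2
    J <- rnorm(1)
    Jp <- rnorm(1, sd = 0.2)
    m <- spin_model(c(S_A, S_B), J = J, J_biquadratic = Jp)
    lad <- heisenberg_ladder(m)
    me <- model_energies(lad$S, J, Jp, S_A, S_B)
    expect_lt(max(abs((lad$energy - lad$energy[1]) - me$energy)), 1e-9)
  }
})

test_that("fits recover exact synthetic parameters with omega zero", {
  lad <- model_energies(0:5, J = 1.44e-3)
  fit <- fit_ladder(lad)
  expect_equal(fit$J, 1.44e-3, tolerance = 1e-12)
  expect_lt(fit$omega, 1e-10)
  expect_true(is.na(fit$J_biquadratic))

  lad2 <- model_energies(0:5, J = 1.2e-3, J_biquadratic = 4e-5)
  fit2 <- fit_ladder(lad2, model = "biquadratic")
  expect_equal(fit2$J, 1.2e-3, tolerance = 1e-10)
  expect_equal(fit2$J_biquadratic, 4e-5, tolerance = 1e-10)
  expect_lt(fit2$omega, 1e-9)
  # nested models: the bilinear fit cannot represent the biquadratic ladder
  fitb <- fit_ladder(lad2, model = "bilinear")
  expect_gt(fitb$omega, 0.1)
  expect_lte(fit2$omega, fitb$omega)
})

test_that("fits are invariant under row order and reference shifts", {
  lad <- model_energies(0:5, J = 2e-3, J_biquadratic = 1e-5)
  fit <- fit_ladder(lad, model = "biquadratic")
  perm <- lad[sample(nrow(lad)), ]
  fitp <- fit_ladder(perm, model = "biquadratic")
  expect_equal(fitp$J, fit$J, tolerance = 1e-12)
  shifted <- dplyr::mutate(lad, energy = energy + 0.37)
  fits <- fit_ladder(shifted, model = "biquadratic")
  expect_equal(fits$J, fit$J, tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_ladder(tibble::tibble(S = 0, energy = 0)), "at least")
  expect_error(fit_ladder(tibble::tibble(S = c(0, 0, 1),
                                         energy = c(0, 0, 1))),
               "one energy per")
  expect_error(fit_ladder(tibble::tibble(S = 0:2, energy = 0:2),
                          model = "biquadratic", S_A = 5, S_B = 5),
               NA)
})

test_that("omega follows its defining arithmetic", {
  ladc <- tibble::tibble(S = 0:5, energy = c(0, 1, 2, 3, 4, 10))
  ladm <- tibble::tibble(S = 0:5, energy = c(0, 1.1, 2.1, 3.1, 4.1, 10.1))
  expect_equal(omega_error(ladc, ladm), 1)        # N=5, |diff|=0.1, gap 10
  expect_equal(omega_error(ladc, ladc), 0)
  # scale invariance
  expect_equal(omega_error(dplyr::mutate(ladc, energy = energy * 7.3),
                           dplyr::mutate(ladm, energy = energy * 7.3)),
               1, tolerance = 1e-12)
  expect_error(omega_error(tibble::tibble(S = 0:1, energy = c(1, 1)),
                           tibble::tibble(S = 0:1, energy = c(1, 2))),
               "zero")
})

test_that("parameter recovery is unbiased under Gaussian noise", {
  set.seed(97)
  J_true <- 1.44e-3
  sigma <- 2e-4
  ests <- vapply(1:200, function(r) {
    lad <- model_energies(0:5, J = J_true)
    lad$energy <- lad$energy + rnorm(6, sd = sigma)
    fit_ladder(lad)$J
  }, 1)
  expect_lt(abs(mean(ests) - J_true), 3 * sd(ests) / sqrt(length(ests)))
  # and converges to truth as the noise vanishes
  small <- vapply(1:50, function(r) {
    lad <- model_energies(0:5, J = J_true)
    lad$energy <- lad$energy + rnorm(6, sd = sigma / 100)
    fit_ladder(lad)$J
  }, 1)
  expect_lt(sd(small), sd(ests) / 50)
})

test_that("biquadratic omega never exceeds bilinear omega on the same data", {
  set.seed(5)
  for (r in 1:20) {
    lad <- model_energies(0:5, J = 1e-3, J_biquadratic = rnorm(1, sd = 5e-5))
    lad$energy <- lad$energy + rnorm(6, sd = 1e-4)
    o_bil <- fit_ladder(lad, "bilinear")$omega
    o_biq <- fit_ladder(lad, "biquadratic")$omega
    expect_lte(o_biq, o_bil + 1e-12)
  }
})

test_that("complete-graph ladders match exact diagonalization and closed forms", {
  lad <- complete_graph_ladder(4, 5/2, J = 1)
  expect_equal(lad$S, 0:10)
  expect_equal(lad$energy[11] - lad$energy[1], 55)
  # exact cross-checks at reduced site spin
  for (s in c(1/2, 1)) {
    m <- spin_model(rep(s, 4), J = 0.9)
    expect_equal(heisenberg_ladder(m)$energy,
                 complete_graph_ladder(4, s, 0.9)$energy, tolerance = 1e-10)
  }
  # two sites reduce to the pair form
  two <- complete_graph_ladder(2, 5/2, J = 1.3)
  me <- model_energies(two$S, J = 1.3)
  expect_equal(two$energy - two$energy[1], me$energy, tolerance = 1e-12)
  # ferromagnetic coupling inverts the ladder
  expect_true(all(diff(complete_graph_ladder(4, 5/2, J = -1)$energy) < 0))
})

test_that("tidy and glance summarize fits in the broom idiom", {
  fit <- fit_ladder(model_energies(0:5, J = 1e-3, J_biquadratic = 1e-5),
                    model = "biquadratic")
  td <- tidy(fit)
  expect_equal(td$term, c("J", "J_biquadratic"))
  gl <- glance(fit)
  expect_equal(gl$n_states, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
})
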