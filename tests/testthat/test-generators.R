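test_that("one-body generator elements match hand-derived values", {
  s <- spin_space(2, 2, 0)
  d <- build_drt(s)
  # <u,d| E_12 |0,2> = sqrt(2): both CSFs expanded in determinants by hand
  expect_equal(coupling_coefficient(csf("ud", s), csf("02", s), 1, 2),
               sqrt(2))
  E12 <- generator_matrix(d, 1, 2)
  i_ud <- csf_to_index(d, csf("ud", s))
  i_02 <- csf_to_index(d, csf("02", s))
  i_20 <- csf_to_index(d, csf("20", s))
  expect_equal(E12[i_ud, i_02], sqrt(2))
  expect_equal(E12[i_20, i_ud], sqrt(2))
  # E_ii is the occupation-number operator
  E11 <- generator_matrix(d, 1, 1)
  expect_equal(E11[i_20, i_20], 2)
  expect_equal(generator_matrix(d, 2, 2)[i_20, i_20], 0)
  # transpose relation E_ji = E_ij^T
  expect_equal(as.matrix(generator_matrix(d, 2, 1)), t(as.matrix(E12)))
})

test_that("sum of E_ii is N times the identity on every sector", {
  for (sec in list(c(2, 2, 0), c(4, 4, 2), c(5, 3, 1))) {
    drt <- build_drt(spin_space(sec[1], sec[2], sec[3]))
    tot <- Reduce(`+`, lapply(seq_len(sec[1]), function(i)
      generator_matrix(drt, i, i)))
    expect_lt(max(abs(tot - Matrix::Diagonal(drt$dim, sec[2]))), 1e-12)
  }
})

test_that("two-body elements match spin-coupling derivations", {
  s0 <- spin_space(2, 2, 0); d0 <- build_drt(s0)
  s1 <- spin_space(2, 2, 2); d1 <- build_drt(s1)
  i_ud <- csf_to_index(d0, csf("ud", s0))
  i_20 <- csf_to_index(d0, csf("20", s0))
  # e_pq,qp = -1/2 e_pp,qq - 2 S_p.S_q with <S1.S2> = -3/4 (singlet), +1/4
  # (triplet), verified by determinant algebra
  expect_equal(two_body_matrix(d0, 1, 2, 2, 1)[i_ud, i_ud], 1)
  expect_equal(two_body_matrix(d1, 1, 2, 2, 1)[1, 1], -1)
  # e_ii,ii = n (n - 1)
  expect_equal(two_body_matrix(d0, 1, 1, 1, 1)[i_20, i_20], 2)
})

test_that("windowed coupling evaluation equals the sparse matrix route", {
  drt <- build_drt(spin_space(6, 6, 0))
  s <- drt$space
  set.seed(7)
  n_checked <- 0L
  for (rep in 1:400) {
    i <- sample(6, 1); j <- sample(6, 1)
    E <- generator_matrix(drt, i, j)
    mu <- sample.int(as.integer(drt$dim), 1)
    ket <- index_to_csf(drt, mu)
    # half the draws from the matrix support, half uniform
    col <- which(E[, mu] != 0)
    nu <- if (length(col) > 0 && rep %% 2 == 0) col[sample.int(length(col), 1)]
          else sample.int(as.integer(drt$dim), 1)
    bra <- index_to_csf(drt, nu)
    expect_equal(coupling_coefficient(bra, ket, i, j), E[nu, mu],
                 tolerance = 1e-11)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 400L)
})

test_that("coupling vanishes between CSFs differing by more than one move", {
  s <- spin_space(4, 4, 0)
  expect_equal(coupling_coefficient(csf("2200", s), csf("0022", s), 1, 3), 0)
})

test_that("generator commutation relations hold as matrix identities", {
  for (sec in list(c(4, 4, 0), c(4, 3, 1))) {
    drt <- build_drt(spin_space(sec[1], sec[2], sec[3]))
    n <- sec[1]
    set.seed(11)
    for (rep in 1:40) {
      idx <- sample(n, 4, replace = TRUE)
      i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
      lhs <- generator_matrix(drt, i, j) %*% generator_matrix(drt, k, l) -
        generator_matrix(drt, k, l) %*% generator_matrix(drt, i, j)
      rhs <- (if (j == k) generator_matrix(drt, i, l) else 0) -
        (if (l == i) generator_matrix(drt, k, j) else 0)
      expect_lt(max(abs(lhs - rhs)), 1e-11)
    }
  }
})

test_that("S^2 is S(S+1) times the identity on the CSF basis", {
  for (sec in list(c(4, 4, 0), c(5, 5, 1), c(6, 4, 2), c(5, 5, 5))) {
    drt <- build_drt(spin_space(sec[1], sec[2], sec[3]))
    S <- sec[3] / 2
    dev <- max(abs(s2_matrix(drt) - Matrix::Diagonal(drt$dim, S * (S + 1))))
    expect_lt(dev, 1e-11)
  }
})

test_that("excitation identification classifies and enumerates routes", {
  s <- spin_space(6, 4, 2)
  mu <- csf(c("u", "0", "u", "d", "u", "0"), s)
  mup <- csf(c("u", "0", "2", "u", "0", "0"), s)
  rec <- identify_excitation(mup, mu)
  expect_equal(rec$type, "single")
  ob <- rec$routes[rec$routes$kind == "one_body", ]
  expect_equal(nrow(ob), 1L)
  expect_equal(c(ob$i, ob$j), c(3L, 5L))
  expect_true(abs(ob$coefficient) > 0)

  # exchange pair: same occupations, different open-shell coupling
  s3 <- spin_space(3, 3, 1)
  bra <- csf("uud", s3); ket <- csf("udu", s3)
  rec2 <- identify_excitation(bra, ket)
  expect_equal(rec2$type, "exchange")
  expect_gt(nrow(rec2$routes), 1L)
  d3 <- build_drt(spin_space(3, 3, 1))
  ib <- csf_to_index(d3, bra); ik <- csf_to_index(d3, ket)
  for (r in seq_len(nrow(rec2$routes))) {
    rt <- rec2$routes[r, ]
    expect_equal(two_body_matrix(d3, rt$i, rt$j, rt$k, rt$l)[ib, ik],
                 rt$coefficient, tolerance = 1e-11)
  }

  # paired double excitation
  s2 <- spin_space(2, 2, 0)
  rec3 <- identify_excitation(csf("20", s2), csf("02", s2))
  expect_equal(rec3$type, "double")
  expect_true(all(rec3$routes$kind == "two_body"))

  rec4 <- identify_excitation(csf("ud", s2), csf("ud", s2))
  expect_equal(rec4$type, "diagonal")

  s4 <- spin_space(4, 4, 0)
  rec5 <- identify_excitation(csf("2020", s4), csf("0202", s4))
  expect_equal(rec5$type, "not_connected")
  expect_equal(nrow(rec5$routes), 0L)
})

test_that("route enumeration reproduces every nonzero operator slot", {
  # the windowed-evaluation route list and the sparse matrix route must
  # agree slot by slot for arbitrary connected pairs
  drt <- build_drt(spin_space(4, 4, 0))
  s <- drt$space
  n <- 4L
  set.seed(3)
  pairs <- cbind(sample.int(as.integer(drt$dim), 25, replace = TRUE),
                 sample.int(as.integer(drt$dim), 25, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    bra_i <- pairs[r, 1]; ket_i <- pairs[r, 2]
    if (bra_i == ket_i) next
    rec <- identify_excitation(index_to_csf(drt, bra_i),
                               index_to_csf(drt, ket_i))
    # collect matrix-route slots
    got <- new.env(parent = emptyenv())
    for (rr in seq_len(nrow(rec$routes))) {
      rt <- rec$routes[rr, ]
      key <- if (rt$kind == "one_body") paste("g", rt$i, rt$j)
             else paste("G", rt$i, rt$j, rt$k, rt$l)
      got[[key]] <- rt$coefficient
    }
    for (i in 1:n) for (j in 1:n) {
      mval <- generator_matrix(drt, i, j)[bra_i, ket_i]
      rval <- got[[paste("g", i, j)]]
      expect_equal(if (is.null(rval)) 0 else rval, mval, tolerance = 1e-11)
    }
    for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
      mval <- two_body_matrix(drt, i, j, k, l)[bra_i, ket_i]
      rval <- got[[paste("G", i, j, k, l)]]
      expect_equal(if (is.null(rval)) 0 else rval, mval, tolerance = 1e-11,
                   info = paste(bra_i, ket_i, i, j, k, l))
    }
  }
})

test_that("Hamiltonian assembly matches closed forms and stays symmetric", {
  ints <- hubbard_model(2, 1, 4)
  d <- build_drt(spin_space(2, 2, 0))
  H <- as.matrix(build_hamiltonian(ints, d))
  expect_equal(sort(diag(H)), c(0, 4, 4))
  i_ud <- csf_to_index(d, csf("ud", d$space))
  i_20 <- csf_to_index(d, csf("20", d$space))
  expect_equal(abs(H[i_ud, i_20]), sqrt(2))
  expect_equal(H, t(H))
  col <- hamiltonian_column(ints, d, csf("ud", d$space))
  expect_equal(as.numeric(col), H[, i_ud])
})

test_that("CSF- and determinant-basis Hamiltonians have identical spin-sector spectra", {
  for (case in list(list(n = 4, N = 4, seed = 1), list(n = 5, N = 4, seed = 2))) {
    ints <- random_integrals(case$n, case$seed)
    for (twos in seq(case$N %% 2, min(case$N, 4), by = 2)) {
      space <- spin_space(case$n, case$N, twos)
      drt <- build_drt(space)
      csf_vals <- sort(eigen(as.matrix(build_hamiltonian(ints, drt)),
                             symmetric = TRUE, only.values = TRUE)$values)
      det_vals <- sd_sector_eigenvalues(ints, case$N, twos)
      expect_equal(length(det_vals), length(csf_vals))
      expect_lt(max(abs(det_vals - csf_vals)), 1e-9)
    }
  }
})
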