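params_ref <- physical_params(phi = 0.01, omega = 24)

test_that("statistical weights are Boltzmann factors over omega", {
  expect_equal(statistical_weight(0, params_ref), 1 / 24)
  expect_equal(statistical_weight(-5.68, params_ref), exp(5.68) / 24)
  expect_equal(statistical_weight(20, params_ref), exp(-20) / 24)
  expect_error(statistical_weight(-700, params_ref), "floor")
})

test_that("transfer-matrix eigenvalues match a numeric eigensolver", {
  set.seed(21)
  for (i in 1:25) {
    w <- random_weights()
    ev <- transfer_eigenvalues(w)
    M <- matrix(c(w$a_AB, w$a_AA, w$a_BB, w$a_AB), 2, 2)
    ref <- sort(eigen(M, only.values = TRUE)$values)
    expect_equal(sort(c(ev$lambda_plus, ev$lambda_minus)), ref)
    expect_equal(ev$lambda_plus * ev$lambda_minus,
                 w$a_AB^2 - w$a_AA * w$a_BB)
  }
  w_eq <- list(a_AA = 2, a_BB = 2, a_AB = 2)
  ev <- transfer_eigenvalues(w_eq)
  expect_equal(ev$lambda_plus, 4)
  expect_equal(ev$lambda_minus, 0)
})

test_that("amplitudes satisfy A_plus - A_minus = 1 and force C_1 = c", {
  set.seed(22)
  for (i in 1:25) {
    w <- random_weights()
    am <- amplitudes(w)
    expect_equal(am$A_plus - am$A_minus, 1, tolerance = 1e-12)
    expect_gte(am$A_minus, 0)
    expect_equal(chain_concentration(1, 0.003, w, params_ref), 0.003)
  }
  am_eq <- amplitudes(list(a_AA = 3, a_BB = 3, a_AB = 1))
  expect_equal(am_eq$A_plus, 1)
  expect_equal(am_eq$A_minus, 0)
})

test_that("chain concentrations match explicit transfer-matrix powers", {
  set.seed(23)
  for (i in 1:10) {
    w <- random_weights()
    c_free <- runif(1, 1e-4, 0.5 / transfer_eigenvalues(w)$lambda_plus)
    ref <- oracle_chain_concentration(50, c_free, w)
    got <- chain_concentration(1:50, c_free, w, params_ref)
    expect_equal(got, ref, tolerance = 1e-12)
    # the dimer term spelled out: two isologous configurations plus the
    # two orientations of the heterologous dimer
    expect_equal(got[2], 0.5 * c_free^2 * (w$a_AA + 2 * w$a_AB + w$a_BB))
  }
})

test_that("monomer solve satisfies mass balance", {
  set.seed(24)
  for (i in 1:10) {
    w <- random_weights()
    phi <- 10^runif(1, -4, -1)
    c_free <- solve_monomer_concentration(phi, w)
    expect_gt(c_free, 0)
    expect_lt(c_free, phi)
    expect_lt(abs(oracle_total_concentration(c_free, w) - phi) / phi, 1e-8)
    # agrees with an independent uniroot solve of the mass balance
    upper <- min(phi, 1 / transfer_eigenvalues(w)$lambda_plus) * (1 - 1e-12)
    ref <- uniroot(function(x) {
      am <- amplitudes(w)
      ev <- transfer_eigenvalues(w)
      am$A_plus * x / (1 - ev$lambda_plus * x)^2 -
        am$A_minus * x / (1 - ev$lambda_minus * x)^2 - phi
    }, c(1e-300, upper), tol = 1e-15)$root
    expect_equal(c_free, ref, tolerance = 1e-9)
  }
})

test_that("weak interactions at low concentration leave monomers", {
  ph <- phenotype(interface_energies(0, 0, 0), physical_params(1e-6))
  expect_equal(ph$c, 1e-6, tolerance = 1e-4)
  expect_gt(ph$P1, 0.999)
  ph_rep <- phenotype(interface_energies(10, 10, 10), physical_params(1e-6))
  expect_gt(ph_rep$P1, 0.999)
})

test_that("phenotype fractions are normalized and ordered", {
  set.seed(25)
  for (i in 1:20) {
    e <- interface_energies(E_AA = runif(1, -14, 0), E_BB = 0,
                            E_AB = runif(1, -12, 0))
    ph <- phenotype(e, params_ref)
    expect_equal(ph$P1 + ph$P2 + ph$P_fib, 1, tolerance = 1e-9)
    expect_gte(ph$P2_star, 0)
    expect_lte(ph$P2_star, ph$P2)
    expect_gte(ph$P_ori, 0)
    expect_lte(ph$P_ori, ph$P_fib + 1e-12)
  }
  expect_error(phenotype(list(E_AA = 0, E_BB = -1, E_AB = 0), params_ref),
               "canonical")
})

test_that("closed-form oriented-fibril fraction matches the series", {
  set.seed(26)
  for (i in 1:20) {
    iso <- sort(runif(2, -12, 0))
    e <- interface_energies(iso[1], iso[2], runif(1, -10, 0))
    ph <- phenotype(e, params_ref)
    a_AB <- statistical_weight(e$E_AB, params_ref)
    expect_lt(ph$c * a_AB, 0.99)
    expect_equal(ph$P_ori,
                 oracle_p_ori(ph$c, a_AB, params_ref$phi, n_terms = 1e4),
                 tolerance = 1e-9)
  }
})

test_that("pure heterologous binding makes all fibrils oriented", {
  # a_AA = a_BB -> 0 relative to a_AB: every fibril interface is AB
  ph <- phenotype(interface_energies(5, 5, -9), params_ref)
  expect_gt(ph$P_fib, 0.5)
  expect_equal(ph$P_ori / ph$P_fib, 1, tolerance = 1e-3)
})

test_that("n-mer distribution sums to one with a nonnegative tail", {
  e <- interface_energies(-9.08, -8.67, -5.68)
  d <- nmer_distribution(e, params_ref, n_max = 30)
  expect_equal(sum(d$P_n), 1, tolerance = 1e-9)
  expect_true(all(d$P_n >= 0))
  ph <- phenotype(e, params_ref)
  expect_equal(d$P_n[1], ph$P1)
  expect_equal(d$P_n[2], ph$P2)
})

test_that("fibril fraction grows monotonically with concentration", {
  grid <- 10^seq(-6, 0, length.out = 25)
  for (row in c(2, 4, 6)) {
    e <- with(table1_energies()[row, ],
              interface_energies(E_AA, E_BB, E_AB))
    tr <- concentration_trajectory(e, grid, params_ref)
    expect_true(all(diff(tr$P_fib) >= -1e-12))
    expect_true(all(diff(tr$P1) <= 1e-12))
    # all sequences begin near the origin of the phase triangle
    expect_lt(tr$P_fib[1] + tr$P2_star[1], 0.05)
  }
  # strong dimer-former stays at the dimer corner even at 1 M
  e_c <- with(table1_energies()[3, ], interface_energies(E_AA, E_BB, E_AB))
  tr_c <- concentration_trajectory(e_c, grid, params_ref)
  high <- tr_c[tr_c$phi >= 1e-3, ]
  expect_true(all(high$P2_star > 0.85))
  expect_true(all(high$P2_star > high$P_fib))
})

test_that("vectorized phenotype table agrees with the scalar path", {
  set.seed(27)
  E <- ensemble_interface_energies(random_sequence_sample(50))
  pt <- phenotype_table(E, params_ref)
  expect_equal(pt$P1 + pt$P2 + pt$P_fib, rep(1, 50), tolerance = 1e-9)
  for (i in c(3, 31)) {
    ph <- phenotype(interface_energies(E$E_AA[i], E$E_BB[i], E$E_AB[i]),
                    params_ref)
    expect_equal(pt$P2_star[i], ph$P2_star)
    expect_equal(pt$P_fib[i], ph$P_fib)
    expect_equal(pt$P_ori[i], ph$P_ori)
  }
})
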