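test_that("mutation kernel changes sites at rate u * (1 - pi_i)", {
  model <- mutation_model(u = 0.05)
  set.seed(31)
  parent <- random_sequence()
  expect_identical(mutate_sequence(parent, mutation_model(u = 0)), parent)

  n_rep <- 2000
  changed <- 0L
  for (i in seq_len(n_rep)) {
    child <- mutate_sequence(parent, model)
    changed <- changed + sum(strsplit(child, "")[[1]] !=
                               strsplit(parent, "")[[1]])
  }
  p_hat <- changed / (n_rep * 32)
  p_true <- 0.05 * (1 - 0.05)
  se <- sqrt(p_true * (1 - p_true) / (n_rep * 32))
  expect_lt(abs(p_hat - p_true), 3 * se)

  # concentrated pi absorbs the composition
  conc <- mutation_model(u = 1, pi = c(1, rep(0, 19)))
  expect_identical(mutate_sequence(parent, conc), strrep("C", 32))
})

test_that("selection coefficients follow the scheme definitions", {
  ph <- phenotype(interface_energies(-9.08, -8.67, -5.68),
                  physical_params(0.01))
  expect_identical(selection_coefficient(ph, selection_scheme("neutral")), 0)
  expect_equal(selection_coefficient(ph, selection_scheme("dimer")),
               ph$P2_star)
  expect_equal(selection_coefficient(ph, selection_scheme("anti_fibril"),
                                     sigma = 2), -2 * ph$P_fib)
  expect_equal(selection_coefficient(ph, selection_scheme("fibril")),
               ph$P_fib)
  expect_equal(ph$P_fib, 0.61, tolerance = 0.03)
  expect_equal(selection_coefficient(ph, selection_scheme("oriented_fibril")),
               ph$P_ori)
  expect_error(selection_scheme("best"), "arg")
})

test_that("acceptance probability implements the fixation-weight ratio", {
  expect_equal(acceptance_probability(0.1, 25), 1)
  expect_equal(acceptance_probability(0, 0), 1)
  expect_equal(acceptance_probability(-log(2) / 50, 25), 0.5)
  # the up/down acceptance ratio is the fixation-probability ratio
  for (d in c(0.013, 0.08)) {
    expect_equal(acceptance_probability(d, 25) /
                   acceptance_probability(-d, 25), exp(2 * 25 * d))
  }
})

test_that("two-state chain reaches the SSWM stationary ratio", {
  # two phenotype scores; proposal flips state with probability q; the
  # acceptance rule must produce stationary odds exp(2 Ne sigma delta)
  set.seed(32)
  scores <- c(0.15, 0.40)
  ne_sigma <- 3
  q <- 0.5
  state <- 1L
  visits <- c(0L, 0L)
  for (i in 1:40000) {
    if (runif(1) < q) {
      prop <- 3L - state
      delta <- scores[prop] - scores[state]
      if (runif(1) < acceptance_probability(delta, ne_sigma)) state <- prop
    }
    visits[state] <- visits[state] + 1L
  }
  odds <- visits[2] / visits[1]
  expect_equal(odds, exp(2 * ne_sigma * (scores[2] - scores[1])),
               tolerance = 0.1)
})

test_that("compiled chain is exactly replayed by the R-level step", {
  B <- load_contact_matrix()
  scheme <- selection_scheme("dimer", Ne_sigma = 25)
  model <- mutation_model()
  params <- physical_params(0.01)
  ch <- run_mcmc(scheme, model, params, generations = 120, burn_in = 0,
                 seed = 42)
  set.seed(42)
  start <- decode_sequences(sample.int(20L, 32L, replace = TRUE,
                                       prob = model$pi))
  e0 <- protein_interface_energies(start, B)
  state <- list(sequence = start, energies = e0,
                phenotype = phenotype(e0, params))
  for (g in 1:120) {
    st <- metropolis_step(state, scheme, model, params, B)
    state <- st$state
    expect_identical(state$sequence, ch$samples$sequence[g])
    expect_identical(st$accepted, ch$samples$accepted[g])
  }
  # cached phenotype and energies in the chain match a fresh recomputation
  idx <- sample(nrow(ch$samples), 10)
  for (i in idx) {
    e <- protein_interface_energies(ch$samples$sequence[i], B)
    ph <- phenotype(e, params)
    expect_equal(ch$samples$E_AA[i], e$E_AA)
    expect_equal(ch$samples$relabelled[i], e$relabelled)
    expect_equal(ch$samples$P2_star[i], ph$P2_star)
    expect_equal(ch$samples$P_ori[i], ph$P_ori)
  }
})

test_that("chains are seed-deterministic and neutral at Ne_sigma = 0", {
  a <- run_mcmc(selection_scheme("neutral"), generations = 400,
                burn_in = 0, seed = 5)
  b <- run_mcmc(selection_scheme("neutral"), generations = 400,
                burn_in = 0, seed = 5)
  expect_identical(a$samples$sequence, b$samples$sequence)

  # with Ne_sigma = 0 every scheme degenerates to the neutral chain
  for (sc in c("dimer", "anti_fibril", "fibril", "oriented_fibril")) {
    z <- run_mcmc(selection_scheme(sc, Ne_sigma = 0), generations = 400,
                  burn_in = 0, seed = 5)
    expect_identical(z$samples$sequence, a$samples$sequence)
    expect_true(all(z$samples$accepted))
  }
})

test_that("neutral chain matches i.i.d. site frequencies", {
  ch <- run_mcmc(selection_scheme("neutral"), generations = 20000,
                 burn_in = 1000, seed = 8)
  s <- chain_samples(ch)
  expect_true(all(s$accepted))
  # thin to roughly independent samples before the chi-square sanity check
  thin <- s$sequence[seq(1, nrow(s), by = 400)]
  counts <- tabulate(encode_sequences(thin), nbins = 20)
  expect_gt(chisq.test(counts)$p.value, 1e-4)
  expect_equal(ch$burn_in, 1000)
  expect_equal(nrow(s), 19000)
})

test_that("chain summaries expose the selection response of energies", {
  neutral <- chain_summary(run_mcmc(selection_scheme("neutral"),
                                    generations = 30000, burn_in = 2000,
                                    seed = 9))
  expect_lt(neutral$mean_E_AA, neutral$mean_E_AB)
  # E_AB sits between the isologous means; the E_AB/E_BB gap is only
  # ~0.03 kT, so allow chain noise around it at this run length
  expect_lt(neutral$mean_E_AB, neutral$mean_E_BB + 0.1)

  dimer <- chain_summary(run_mcmc(selection_scheme("dimer"),
                                  generations = 30000, burn_in = 2000,
                                  seed = 9))
  expect_lt(dimer$mean_E_AA, neutral$mean_E_AA - 4)
  expect_gt(dimer$mean_E_BB, neutral$mean_E_BB)

  oriented <- chain_summary(run_mcmc(selection_scheme("oriented_fibril"),
                                     generations = 30000, burn_in = 2000,
                                     seed = 9))
  expect_lt(oriented$mean_E_AB, oriented$mean_E_AA - 3)
  expect_lt(oriented$mean_E_AB, oriented$mean_E_BB - 3)

  expect_error(chain_samples(structure(list(samples = data.frame(
    generation = 1:5), burn_in = 10), class = "evolution_chain")),
    "post-burn-in")
})
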