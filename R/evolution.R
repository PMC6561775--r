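#' Mutation model for surface sequences
#'
#' Sequences evolve by whole-sequence replication with independent per-site
#' mutation: site by site, residue i is replaced by residue j != i with
#' probability `u * pi[j]` and left unchanged otherwise, so the expected
#' per-site change probability is `u * (1 - pi[i])`. `pi` is the stationary
#' amino-acid frequency vector of the mutation process; `u` sets the
#' proposal step size and does not affect stationary frequencies.
#'
#' @param u Mutation rate constant in (0, 1]; 0.05 explores sequence space
#'   efficiently (about 1.5 sites change per proposal).
#' @param pi Length-20 frequency vector over [aa_alphabet()], summing to 1;
#'   default uniform (0.05 each).
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(u = 0.05, pi = rep(0.05, 20)) {
  stopifnot(u >= 0, u <= 1, length(pi) == 20L, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  structure(list(u = u, pi = pi / sum(pi)), class = "mutation_model")
}

#' Selection schemes over aggregation phenotypes
#'
#' Fitness is `w = 1 + s` with a selection coefficient that is a function
#' of the phenotype at concentration `phi_fitness`:
#' \describe{
#'   \item{neutral}{`s = 0` for every sequence;}
#'   \item{dimer}{`s = sigma * P2_star` (selection for closed AA dimers);}
#'   \item{anti_fibril}{`s = -sigma * P_fib`;}
#'   \item{fibril}{`s = sigma * P_fib` (fibrils of all kinds);}
#'   \item{oriented_fibril}{`s = sigma * P_ori` (all-heterologous fibrils).}
#' }
#' Only the compound strength `N_e * sigma` (effective population size times
#' sigma) enters the stationary distribution, so it is the user-facing
#' parameter; the factor 2 in the fixation weight `exp(2 Ne s)` is applied
#' internally.
#'
#' @param name One of `"neutral"`, `"dimer"`, `"anti_fibril"`, `"fibril"`,
#'   `"oriented_fibril"`.
#' @param Ne_sigma Compound selection strength `N_e * sigma` >= 0.
#' @param phi_fitness Concentration (mol/L) at which the phenotype enters
#'   the fitness function.
#' @return A `selection_scheme` list.
#' @export
selection_scheme <- function(name = c("neutral", "dimer", "anti_fibril",
                                      "fibril", "oriented_fibril"),
                             Ne_sigma = 25, phi_fitness = 0.01) {
  name <- match.arg(name)
  stopifnot(Ne_sigma >= 0, phi_fitness > 0)
  structure(list(name = name, Ne_sigma = Ne_sigma,
                 phi_fitness = phi_fitness),
            class = "selection_scheme")
}

scheme_code <- function(scheme) {
  match(scheme$name,
        c("neutral", "dimer", "anti_fibril", "fibril", "oriented_fibril")) - 1L
}

# the phenotype functional the scheme selects on (s = sigma * this)
scheme_score <- function(phenotype, scheme) {
  switch(scheme$name,
         neutral = 0,
         dimer = phenotype$P2_star,
         anti_fibril = -phenotype$P_fib,
         fibril = phenotype$P_fib,
         oriented_fibril = phenotype$P_ori)
}

#' Selection coefficient of a phenotype under a scheme
#'
#' @param phenotype An `aggregation_phenotype` (computed at the scheme's
#'   `phi_fitness`).
#' @param scheme A [selection_scheme()].
#' @param sigma Selection strength sigma; defaults to 1 so the value is the
#'   coefficient per unit sigma (only the product `N_e * sigma` matters for
#'   the sampler).
#' @return The selection coefficient `s` (dimensionless).
#' @export
selection_coefficient <- function(phenotype, scheme, sigma = 1) {
  sigma * scheme_score(phenotype, scheme)
}

#' Mutate a surface sequence
#'
#' Applies the replication-with-mutation kernel of [mutation_model()] to a
#' 32-residue sequence, using R's random number stream. Sites are visited
#' in position order 1..32; each site draws one uniform against `u`, and a
#' mutating site draws a replacement residue from `pi` (possibly the same
#' residue, so the realized change probability is `u * (1 - pi[i])`).
#'
#' @param parent A 32-letter sequence string.
#' @param model A [mutation_model()].
#' @return The descendant sequence (32-letter string).
#' @export
mutate_sequence <- function(parent, model = mutation_model()) {
  enc <- encode_sequences(parent)[1, ]
  for (x in 1:32) {
    if (runif(1) < model$u) {
      enc[x] <- findInterval(runif(1), cumsum(model$pi),
                             left.open = TRUE) + 1L
    }
  }
  decode_sequences(enc)
}

#' Metropolis acceptance probability of the evolutionary sampler
#'
#' `min(1, exp(2 * Ne_sigma * delta_score))`: an uphill move (or any move
#' under neutrality) is always accepted, and the ratio of acceptance of
#' moves that increase and decrease the score is `exp(2 Ne_sigma delta)`,
#' which is what makes the stationary sequence frequencies proportional to
#' `f_mut * exp(2 Ne s)`.
#'
#' @param delta_score Change in the scheme's phenotype functional.
#' @param Ne_sigma Compound selection strength.
#' @return Acceptance probability in (0, 1].
#' @export
acceptance_probability <- function(delta_score, Ne_sigma) {
  pmin(1, exp(2 * Ne_sigma * delta_score))
}

new_chain_state <- function(sequence, matrix, params) {
  e <- protein_interface_energies(sequence, matrix)
  ph <- phenotype(e, params)
  list(sequence = sequence, energies = e, phenotype = ph)
}

#' One Metropolis step of the evolutionary sampler
#'
#' Proposes a mutated descendant and accepts it with probability
#' `min(1, exp(2 Ne_sigma * delta_score))` where `delta_score` is the change
#' in the scheme's phenotype functional; a rejected proposal records a
#' second copy of the current sequence. This acceptance rule makes the
#' stationary sequence frequencies proportional to
#' `f_mut * exp(2 Ne sigma score)`, the strong-selection weak-mutation
#' stationary distribution.
#'
#' This R-level step mirrors the compiled chain driver in [run_mcmc()] and
#' is convenient for inspection and testing; for long chains use
#' [run_mcmc()].
#'
#' @param state A list from `new_chain_state()` / a previous step, holding
#'   `sequence`, `energies` and `phenotype`.
#' @param scheme A [selection_scheme()].
#' @param model A [mutation_model()].
#' @param params [physical_params()] at the scheme's fitness concentration.
#' @param matrix A `contact_matrix`.
#' @return List with `state` (the sampled state) and `accepted`.
#' @export
metropolis_step <- function(state, scheme, model, params,
                            matrix = load_contact_matrix()) {
  descendant <- mutate_sequence(state$sequence, model)
  if (identical(descendant, state$sequence)) {
    prop <- state
  } else {
    prop <- new_chain_state(descendant, matrix, params)
  }
  delta <- scheme_score(prop$phenotype, scheme) -
    scheme_score(state$phenotype, scheme)
  accepted <- 2 * scheme$Ne_sigma * delta >= 0 ||
    runif(1) < acceptance_probability(delta, scheme$Ne_sigma)
  list(state = if (accepted) prop else state, accepted = accepted)
}

#' Run the evolutionary Markov chain
#'
#' Samples 32-residue surface sequences from the strong-selection
#' weak-mutation stationary distribution by Metropolis MCMC. Every
#' generation contributes one sample (the accepted descendant or a
#' duplicate of the parent on rejection), and each sample carries its
#' canonical interface energies (E_AA <= E_BB) and full aggregation
#' phenotype at `scheme$phi_fitness`. The chain runs in compiled code using
#' R's seeded random number stream, so a fixed `seed` reproduces the chain
#' bit-for-bit.
#'
#' @param scheme A [selection_scheme()].
#' @param model A [mutation_model()].
#' @param params [physical_params()] whose `phi` must equal the scheme's
#'   `phi_fitness`; defaults to that.
#' @param generations Total proposals (default 300000, with the first 5000
#'   discarded by summaries for equilibration).
#' @param burn_in Number of initial generations summaries discard.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param start Optional 32-letter starting sequence; default a random
#'   sequence drawn from the mutation model's `pi`.
#' @param matrix A `contact_matrix`.
#' @return An `evolution_chain`: list with `samples` (data frame with one
#'   row per generation: `generation`, `sequence`, `E_AA`, `E_BB`, `E_AB`,
#'   `relabelled`, `c`, `P1`, `P2`, `P2_star`, `P_fib`, `P_ori`,
#'   `accepted`), plus `scheme`, `model`, `params`, `burn_in` and `seed`.
#' @export
#' @examples
#' ch <- run_mcmc(selection_scheme("neutral"), generations = 200,
#'                burn_in = 50, seed = 1)
#' chain_summary(ch)
run_mcmc <- function(scheme, model = mutation_model(),
                     params = physical_params(scheme$phi_fitness),
                     generations = 300000, burn_in = 5000, seed = NULL,
                     start = NULL, matrix = load_contact_matrix()) {
  stopifnot(generations > burn_in, burn_in >= 0)
  if (abs(params$phi - scheme$phi_fitness) > 1e-12) {
    stop("params$phi (", params$phi, ") must equal scheme$phi_fitness (",
         scheme$phi_fitness, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) {
    start_enc <- sample.int(20L, 32L, replace = TRUE, prob = model$pi)
  } else {
    start_enc <- encode_sequences(start)[1, ]
  }
  res <- cpp_run_mcmc(start_enc - 1L, as_contact_matrix(matrix),
                      scheme_code(scheme), scheme$Ne_sigma,
                      params$phi / params$c0, params$omega,
                      model$u, cumsum(model$pi), as.integer(generations))
  samples <- data.frame(
    generation = seq_len(generations),
    sequence = decode_sequences(res$sequences),
    E_AA = res$energies[, 1], E_BB = res$energies[, 2],
    E_AB = res$energies[, 3],
    relabelled = res$relabelled,
    c = res$phenotypes[, 1] * params$c0,
    P1 = res$phenotypes[, 2], P2 = res$phenotypes[, 3],
    P2_star = res$phenotypes[, 4], P_fib = res$phenotypes[, 5],
    P_ori = res$phenotypes[, 6],
    accepted = res$accepted
  )
  structure(list(samples = samples, scheme = scheme, model = model,
                 params = params, burn_in = burn_in, seed = seed),
            class = "evolution_chain")
}

#' Post-burn-in samples of a chain
#'
#' @param chain An `evolution_chain`.
#' @return The samples data frame with the burn-in prefix removed.
#' @export
chain_samples <- function(chain) {
  s <- chain$samples[chain$samples$generation > chain$burn_in, , drop = FALSE]
  if (nrow(s) == 0L) stop("no post-burn-in samples (burn_in = ",
                          chain$burn_in, ")")
  s
}

#' Summarize an evolutionary chain
#'
#' Simple means over the post-burn-in samples (rejected-step duplicates
#' included, as the sampling rule requires) of the phenotype fractions and
#' the three interface energies, plus the acceptance rate.
#'
#' @param chain An `evolution_chain`.
#' @return A one-row data frame with columns `scheme`, `Ne_sigma`,
#'   `generations`, `mean_P2_star`, `mean_P_fib`, `mean_P_ori`,
#'   `mean_E_AA`, `mean_E_BB`, `mean_E_AB`, `acceptance_rate`.
#' @export
chain_summary <- function(chain) {
  s <- chain_samples(chain)
  data.frame(scheme = chain$scheme$name,
             Ne_sigma = chain$scheme$Ne_sigma,
             generations = nrow(chain$samples),
             mean_P2_star = mean(s$P2_star),
             mean_P_fib = mean(s$P_fib),
             mean_P_ori = mean(s$P_ori),
             mean_E_AA = mean(s$E_AA),
             mean_E_BB = mean(s$E_BB),
             mean_E_AB = mean(s$E_AB),
             acceptance_rate = mean(s$accepted))
}

#' @export
print.evolution_chain <- function(x, ...) {
  cat(sprintf("Evolutionary chain: %s scheme, Ne*sigma = %g, phi = %g M\n",
              x$scheme$name, x$scheme$Ne_sigma, x$scheme$phi_fitness))
  cat(sprintf("  %d generations (%d burn-in)\n", nrow(x$samples), x$burn_in))
  print(chain_summary(x))
  invisible(x)
}
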