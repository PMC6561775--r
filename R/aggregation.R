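#' Physical parameters of the aggregation equilibrium
#'
#' @param phi Total protein subunit concentration in mol/L.
#' @param omega Number of orientational configurations of one subunit
#'   relative to its neighbour; 24 for a cubic object on a cubic lattice
#'   (the model's default). Larger omega means a larger rotational-entropy
#'   penalty per interface, hence less aggregation.
#' @param c0 Reference concentration, 1 mol/L.
#' @param beta Inverse temperature in 1/kT. Interface energies are supplied
#'   in kT units, so `beta = 1` and the Boltzmann exponent is dimensionless;
#'   the parameter is kept explicit for clarity.
#' @return A `physical_params` list.
#' @export
physical_params <- function(phi, omega = 24, c0 = 1, beta = 1) {
  stopifnot(phi > 0, omega >= 1, c0 > 0, beta > 0)
  structure(list(phi = phi, omega = omega, c0 = c0, beta = beta),
            class = "physical_params")
}

#' Statistical weight of one interface
#'
#' The dimensionless Boltzmann weight of an interface of energy `E` (kT),
#' penalized by the rotational-entropy factor omega:
#' `a = exp(-beta * E) / omega`. An interface of type ij in a chain
#' contributes a factor `a_ij * c / c0` to the chain's statistical weight.
#'
#' @param E Interface energy in kT (may be a vector).
#' @param params A [physical_params()] object.
#' @param floor Lower energy bound guarding against overflow; no physical
#'   16-contact surface comes near it.
#' @return Dimensionless weight(s), strictly positive.
#' @export
#' @examples
#' statistical_weight(0, physical_params(0.01)) # 1/24
statistical_weight <- function(E, params, floor = -600) {
  stopifnot(all(is.finite(E)))
  if (any(E < floor)) {
    stop("interface energy ", min(E), " kT is below the overflow floor (",
         floor, " kT)")
  }
  exp(-params$beta * E) / params$omega
}

interface_weights <- function(energies, params) {
  list(a_AA = statistical_weight(energies$E_AA, params),
       a_BB = statistical_weight(energies$E_BB, params),
       a_AB = statistical_weight(energies$E_AB, params))
}

#' Eigenvalues of the 2x2 aggregation transfer matrix
#'
#' The transfer matrix `[[a_AB, a_BB], [a_AA, a_AB]]` propagates the
#' concentrations of growing chains classified by which face (A or B) is
#' exposed at the growing end. Its eigenvalues
#' `lambda_pm = a_AB +- sqrt(a_AA * a_BB)` control the geometric decay of
#' the chain-length distribution: chains proliferate while
#' `lambda_plus * c / c0 < 1`.
#'
#' @param weights List with positive `a_AA`, `a_BB`, `a_AB` (vectors allowed).
#' @return List with `lambda_plus` and `lambda_minus`.
#' @export
transfer_eigenvalues <- function(weights) {
  s <- sqrt(weights$a_AA * weights$a_BB)
  list(lambda_plus = weights$a_AB + s, lambda_minus = weights$a_AB - s)
}

#' Amplitudes of the chain-concentration closed form
#'
#' `A_pm = (a_AA + a_BB +- 2 sqrt(a_AA a_BB)) / (4 sqrt(a_AA a_BB))`.
#' Both are nonnegative and `A_plus - A_minus = 1` identically, which forces
#' the n = 1 chain concentration to equal the free monomer concentration.
#'
#' @inheritParams transfer_eigenvalues
#' @return List with `A_plus` and `A_minus`.
#' @export
amplitudes <- function(weights) {
  s <- sqrt(weights$a_AA * weights$a_BB)
  list(A_plus = (weights$a_AA + weights$a_BB + 2 * s) / (4 * s),
       A_minus = (weights$a_AA + weights$a_BB - 2 * s) / (4 * s))
}

#' Equilibrium concentration of n-chains
#'
#' Closed form for the total concentration of linear aggregates of n
#' subunits at free monomer concentration `c`:
#' `C_n / c0 = (c/c0)^n (A_plus lambda_plus^(n-1) - A_minus lambda_minus^(n-1))`,
#' summed over the two exposed-end states and all interface type sequences.
#'
#' @param n Aggregate size(s), integer >= 1.
#' @param c Free monomer concentration, mol/L.
#' @param weights Interface statistical weights.
#' @param params A [physical_params()] object.
#' @return Concentration(s) `C_n` in mol/L.
#' @export
chain_concentration <- function(n, c, weights, params) {
  stopifnot(all(n >= 1), c > 0)
  ev <- transfer_eigenvalues(weights)
  am <- amplitudes(weights)
  x <- c / params$c0
  params$c0 * x^n * (am$A_plus * ev$lambda_plus^(n - 1) -
                     am$A_minus * ev$lambda_minus^(n - 1))
}

# right-hand side of the mass-balance equation: total subunit concentration
# sum_n n C_n as a function of the monomer concentration (both in units of c0)
mass_balance_rhs <- function(x, weights) {
  ev <- transfer_eigenvalues(weights)
  am <- amplitudes(weights)
  am$A_plus * x / (1 - ev$lambda_plus * x)^2 -
    am$A_minus * x / (1 - ev$lambda_minus * x)^2
}

#' Solve for the free monomer concentration
#'
#' Finds the unique root c of the mass-balance equation
#' `phi/c0 = A+ (c/c0)/(1 - lambda+ c/c0)^2 - A- (c/c0)/(1 - lambda- c/c0)^2`
#' on the physical interval `0 < c < min(phi, c0/lambda_plus)`, where the
#' right-hand side is monotone increasing. Solved by bisection in compiled
#' code to machine precision; all statistical-weight arguments may be
#' vectors of equal length.
#'
#' @param phi Total subunit concentration, mol/L.
#' @param weights Interface statistical weights.
#' @param params A [physical_params()] object (its `phi` is ignored in
#'   favour of the explicit argument).
#' @return Free monomer concentration(s) c in mol/L.
#' @export
solve_monomer_concentration <- function(phi, weights,
                                        params = physical_params(phi)) {
  stopifnot(phi > 0)
  c0 <- params$c0
  cpp_solve_monomer(as.numeric(weights$a_AA),
                    as.numeric(weights$a_BB),
                    as.numeric(weights$a_AB), phi / c0) * c0
}

phenotype_columns <- c("c", "P1", "P2", "P2_star", "P_fib", "P_ori")

#' Aggregation phenotype of a protein at equilibrium
#'
#' From the three canonical interface energies and the physical parameters,
#' computes the free monomer concentration and the partition of subunits
#' over aggregate classes:
#' \describe{
#'   \item{P1, P2}{fractions of subunits free and in dimers;}
#'   \item{P2_star}{fraction in closed dimers bound through the strong
#'     isologous AA interface, `P2 * a_AA / (a_AA + a_BB + 2 a_AB)`;}
#'   \item{P_fib}{fraction in fibrils (aggregates of 3 or more), computed
#'     exactly as `1 - P1 - P2`;}
#'   \item{P_ori}{fraction in oriented fibrils, whose interfaces are all
#'     heterologous AB so every subunit points the same way; closed form
#'     `P_ori = x^3 (3 - 2x) / ((1 - x)^2 a_AB phi/c0)` with
#'     `x = a_AB c/c0`.}
#' }
#' `P1 + P2 + P_fib = 1` by construction and `P_ori <= P_fib` always.
#'
#' @param energies An `interface_energies` object (or list with `E_AA`,
#'   `E_BB`, `E_AB` in kT, satisfying `E_AA <= E_BB`).
#' @param params A [physical_params()] object.
#' @return An `aggregation_phenotype`: list with `c`, `P1`, `P2`, `P2_star`,
#'   `P_fib`, `P_ori` and the inputs `energies` and `params`.
#' @export
#' @examples
#' # a fibril-forming energy triple at cellular-like concentration
#' ph <- phenotype(interface_energies(-9.08, -8.67, -5.68),
#'                 physical_params(phi = 0.01))
#' round(ph$P_fib, 2)
phenotype <- function(energies, params) {
  if (energies$E_AA > energies$E_BB) {
    stop("energies must be canonical (E_AA <= E_BB); call ",
         "protein_interface_energies() or interface_energies() first")
  }
  statistical_weight(min(energies$E_AA, energies$E_BB, energies$E_AB), params)
  E <- matrix(c(energies$E_AA, energies$E_BB, energies$E_AB) * params$beta,
              nrow = 1)
  out <- cpp_phenotypes(E, params$phi / params$c0, params$omega)
  ph <- as.list(out[1, ])
  names(ph) <- phenotype_columns
  ph$c <- ph$c * params$c0
  ph$energies <- energies
  ph$params <- params
  class(ph) <- "aggregation_phenotype"
  ph
}

#' @export
print.aggregation_phenotype <- function(x, ...) {
  cat(sprintf("Aggregation phenotype at phi = %g M (omega = %g)\n",
              x$params$phi, x$params$omega))
  cat(sprintf("  free monomer c = %.4g M\n", x$c))
  cat(sprintf("  P1 = %.4f  P2 = %.4f  P2* = %.4f  P_fib = %.4f  P_ori = %.4f\n",
              x$P1, x$P2, x$P2_star, x$P_fib, x$P_ori))
  invisible(x)
}

#' Phenotypes for many energy triples at once
#'
#' Vectorized companion of [phenotype()] for ensemble and chain analyses.
#'
#' @param energies Data frame with columns `E_AA`, `E_BB`, `E_AB` (kT,
#'   canonical labelling), e.g. from [ensemble_interface_energies()].
#' @param params A [physical_params()] object.
#' @return A data frame with columns `c`, `P1`, `P2`, `P2_star`, `P_fib`,
#'   `P_ori`, one row per input row.
#' @export
phenotype_table <- function(energies, params) {
  stopifnot(all(c("E_AA", "E_BB", "E_AB") %in% names(energies)))
  if (any(energies$E_AA > energies$E_BB)) {
    stop("energies must be canonical (E_AA <= E_BB) in every row")
  }
  E <- cbind(energies$E_AA, energies$E_BB, energies$E_AB) * params$beta
  out <- cpp_phenotypes(E, params$phi / params$c0, params$omega)
  colnames(out) <- phenotype_columns
  df <- as.data.frame(out)
  df$c <- df$c * params$c0
  df
}

#' Distribution of subunits over n-mer sizes
#'
#' The probability that a subunit is part of an n-mer,
#' `P_n = n C_n / phi`, reported up to `n_max` together with the mass in
#' the tail `n > n_max` (computed as the exact complement).
#'
#' @inheritParams phenotype
#' @param n_max Largest aggregate size reported individually.
#' @return Data frame with columns `n` and `P_n`; the final row with
#'   `n = NA` holds the tail mass beyond `n_max`.
#' @export
nmer_distribution <- function(energies, params, n_max = 20) {
  ph <- phenotype(energies, params)
  w <- interface_weights(energies, params)
  n <- seq_len(n_max)
  P_n <- n * chain_concentration(n, ph$c, w, params) / params$phi
  rbind(data.frame(n = n, P_n = P_n),
        data.frame(n = NA_integer_, P_n = max(0, 1 - sum(P_n))))
}

#' Phenotype trajectory across concentrations
#'
#' Recomputes the aggregation phenotype on a grid of total concentrations,
#' tracing the path of a sequence through the (P2*, P_fib) phase triangle:
#' all sequences start near the origin (all monomers) at low concentration
#' and move toward the fibril corner as concentration grows.
#'
#' @param energies An `interface_energies` object.
#' @param phi_grid Increasing vector of total concentrations, mol/L.
#' @param params A [physical_params()] object supplying `omega`, `c0`,
#'   `beta`; its `phi` is ignored.
#' @return Data frame with columns `phi`, `c`, `P1`, `P2`, `P2_star`,
#'   `P_fib`, `P_ori`, one row per grid point.
#' @export
#' @examples
#' tr <- concentration_trajectory(interface_energies(-9.08, -8.67, -5.68),
#'                                10^seq(-6, 0, by = 1))
#' tr[, c("phi", "P2_star", "P_fib")]
concentration_trajectory <- function(energies, phi_grid,
                                     params = physical_params(phi_grid[1])) {
  stopifnot(all(phi_grid > 0), !is.unsorted(phi_grid))
  rows <- lapply(phi_grid, function(phi) {
    p <- physical_params(phi, omega = params$omega, c0 = params$c0,
                         beta = params$beta)
    ph <- phenotype(energies, p)
    data.frame(phi = phi, c = ph$c, P1 = ph$P1, P2 = ph$P2,
               P2_star = ph$P2_star, P_fib = ph$P_fib, P_ori = ph$P_ori)
  })
  do.call(rbind, rows)
}
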