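# Independent oracles, written directly from the model definitions and kept
# free of the package's computational paths.

# mirror-contact maps written out literally, per rotation
oracle_partner <- function(r, c, rotation) {
  switch(as.character(rotation),
         "0"   = c(5 - r, c),
         "90"  = c(c, r),
         "180" = c(r, 5 - c),
         "270" = c(5 - c, 5 - r))
}

# plain double-loop contact sum over the 4x4 grid
oracle_energy_at_rotation <- function(face1, face2, rotation, B) {
  total <- 0
  for (r in 1:4) {
    for (cc in 1:4) {
      p <- oracle_partner(r, cc, rotation)
      total <- total + B[face1[r, cc], face2[p[1], p[2]]]
    }
  }
  total
}

oracle_interface_energy <- function(face1, face2, B) {
  min(sapply(c(0, 90, 180, 270), function(rot) {
    oracle_energy_at_rotation(face1, face2, rot, B)
  }))
}

# chain concentration by explicit transfer-matrix powers:
# (C_n(A); C_n(B)) = (c/c0) [[a_AB, a_BB], [a_AA, a_AB]] (C_{n-1}(A); C_{n-1}(B))
oracle_chain_concentration <- function(n_max, c, w, c0 = 1) {
  M <- matrix(c(w$a_AB, w$a_AA, w$a_BB, w$a_AB), 2, 2)
  state <- c(c / 2, c / 2)
  out <- numeric(n_max)
  out[1] <- sum(state)
  for (n in 2:n_max) {
    state <- (c / c0) * (M %*% state)
    out[n] <- sum(state)
  }
  out
}

# mass balance by truncated direct summation of n * C_n; the geometric
# factors are grouped as (x lambda)^n to stay inside floating-point range
oracle_total_concentration <- function(c, w, n_terms = 1e5, c0 = 1) {
  s <- sqrt(w$a_AA * w$a_BB)
  lp <- w$a_AB + s
  lm <- w$a_AB - s
  Ap <- (w$a_AA + w$a_BB + 2 * s) / (4 * s)
  Am <- (w$a_AA + w$a_BB - 2 * s) / (4 * s)
  n <- seq_len(n_terms)
  x <- c / c0
  plus <- sum(n * (x * lp)^n) * Ap / lp
  minus <- if (abs(lm) > 0) sum(n * (x * lm)^n) * Am / lm else Am * x
  (plus - minus) * c0
}

# oriented-fibril fraction by truncated summation of the series,
# n c^n a_AB^(n-1)/c0^(n-1) = n (c a_AB/c0)^n c0/a_AB, summed stably
oracle_p_ori <- function(c, a_AB, phi, n_terms = 1e4, c0 = 1) {
  n <- 3:n_terms
  x <- c * a_AB / c0
  sum(n * x^n) * c0 / a_AB / phi
}

# random statistical weights with lambda_plus * c / c0 comfortably below 1
random_weights <- function() {
  list(a_AA = exp(runif(1, -2, 4)),
       a_BB = exp(runif(1, -2, 4)),
       a_AB = exp(runif(1, -2, 4)))
}

random_face <- function() {
  surface_face(sample(aa_alphabet(), 16, replace = TRUE))
}

random_sequence <- function() {
  paste(sample(aa_alphabet(), 32, replace = TRUE), collapse = "")
}

# textbook Pearson r and two-sided t-test p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}
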