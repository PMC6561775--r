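#' Draw i.i.d. random surface sequences
#'
#' Samples `n` 32-residue sequences with independent sites distributed
#' according to the mutation model's stationary frequencies `pi`. This is
#' the neutral sequence ensemble: under neutral evolution every sequence
#' has stationary frequency proportional to its mutational frequency, so
#' an i.i.d. sample is equivalent to (and much cheaper than) a neutral
#' Markov chain.
#'
#' @param n Number of sequences.
#' @param model A [mutation_model()] supplying `pi`.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An integer matrix (`n` x 32) of residue indices into
#'   [aa_alphabet()]; convert with [decode_sequences()] if letters are
#'   needed.
#' @export
random_sequence_sample <- function(n, model = mutation_model(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(sample.int(20L, n * 32L, replace = TRUE, prob = model$pi),
         nrow = n, ncol = 32L)
}

#' Relative amino-acid frequencies on the A and B surfaces
#'
#' Counts residues on the strong (A) and weak (B) faces over a sample of
#' sequences, after canonical relabelling (E_AA <= E_BB), and reports them
#' relative to the mutational expectation:
#' `p_X(i) = (count of i on face X / residues on face X) / pi[i]`.
#' Residues are pooled over all sequences (16 per face per sequence). For
#' an `evolution_chain` the post-burn-in samples are used, including
#' rejection duplicates, matching the chain's estimator.
#'
#' The counting identity `sum_i pi[i] * p_X(i) = 1` holds exactly per face,
#' and for the neutral ensemble `(p_A + p_B)/2 = 1` for every amino acid up
#' to sampling error, since relabelling only moves residues between faces.
#'
#' @param sample An integer matrix from [random_sequence_sample()], a
#'   character vector of 32-letter sequences, or an `evolution_chain`.
#' @param model The [mutation_model()] defining `pi`.
#' @param matrix A `contact_matrix` (used to relabel raw sequences; chains
#'   are already canonical).
#' @return A `propensity_table` data frame: columns `aa`, `p_A`, `p_B`;
#'   attribute `sample_size` holds the number of sequences.
#' @export
surface_frequencies <- function(sample, model = mutation_model(),
                                matrix = load_contact_matrix()) {
  if (inherits(sample, "evolution_chain")) {
    s <- chain_samples(sample)
    enc <- encode_sequences(s$sequence)
    relabelled <- s$relabelled
  } else {
    enc <- if (is.character(sample)) encode_sequences(sample) else sample
    stopifnot(is.matrix(enc), ncol(enc) == 32L)
    relabelled <- ensemble_interface_energies(enc, matrix)$relabelled
  }
  n <- nrow(enc)
  if (n == 0L) stop("empty sample")
  face1 <- enc[, 1:16, drop = FALSE]
  face2 <- enc[, 17:32, drop = FALSE]
  a_res <- rbind(face1[!relabelled, , drop = FALSE],
                 face2[relabelled, , drop = FALSE])
  b_res <- rbind(face2[!relabelled, , drop = FALSE],
                 face1[relabelled, , drop = FALSE])
  count_a <- tabulate(a_res, nbins = 20L)
  count_b <- tabulate(b_res, nbins = 20L)
  out <- data.frame(aa = aa_alphabet(),
                    p_A = (count_a / (16 * n)) / model$pi,
                    p_B = (count_b / (16 * n)) / model$pi)
  attr(out, "sample_size") <- n
  class(out) <- c("propensity_table", "data.frame")
  out
}

#' Interface propensity score
#'
#' `S_int(i) = ln(p_A(i) / p_B(i))`: positive for amino acids enriched on
#' the strong (A) surface relative to the weak (B) surface, negative for
#' the depleted ones. Computed from a [surface_frequencies()] table.
#'
#' @param table A `propensity_table` with positive `p_A` and `p_B`.
#' @return Named numeric vector of per-amino-acid scores.
#' @export
s_int <- function(table) {
  zero <- table$p_A <= 0 | table$p_B <= 0
  if (any(zero)) {
    stop("zero surface count for: ", paste(table$aa[zero], collapse = ", "),
         "; use a larger sample")
  }
  setNames(log(table$p_A / table$p_B), table$aa)
}

#' Isologous-versus-heterologous interface propensity
#'
#' `S_iso(i) = ln(p_A(i, dimers) / p_A(i, oriented fibrils))`: contrasts the
#' strong-face composition selected by isologous (closed-dimer) binding
#' against that selected by heterologous (oriented-fibril) binding. An
#' amino acid that binds a copy of itself well (self-energy below its row
#' average, like Cys) is favoured at isologous interfaces and scores
#' positive; like-charge repulsion gives charged residues negative scores.
#'
#' @param dimer_table `propensity_table` from a dimer-selection chain.
#' @param oriented_table `propensity_table` from an oriented-fibril chain.
#' @return Named numeric vector of per-amino-acid scores.
#' @export
s_iso <- function(dimer_table, oriented_table) {
  zero <- dimer_table$p_A <= 0 | oriented_table$p_A <= 0
  if (any(zero)) {
    stop("zero A-surface count for: ",
         paste(dimer_table$aa[zero], collapse = ", "),
         "; use longer chains")
  }
  setNames(log(dimer_table$p_A / oriented_table$p_A), dimer_table$aa)
}

#' Per-amino-acid predictors from the contact matrix
#'
#' `B_self(i)` is the diagonal element B_ii (the energy of an amino acid
#' contacting a copy of itself), `B_ave(i)` the mean of its interactions
#' with the 20 possible partners, and `delta_B = B_ave - B_self`. More
#' negative B_self/B_ave predict higher interface propensity; positive
#' delta_B predicts enrichment at isologous interfaces, where self-contacts
#' are guaranteed at the rotation map's fixed points.
#'
#' @param matrix A `contact_matrix`.
#' @return Data frame with columns `aa`, `B_self`, `B_ave`, `delta_B` (kT).
#' @export
matrix_predictors <- function(matrix = load_contact_matrix()) {
  m <- as_contact_matrix(matrix)
  data.frame(aa = aa_alphabet(),
             B_self = diag(m),
             B_ave = rowMeans(m),
             delta_B = rowMeans(m) - diag(m),
             row.names = NULL)
}

#' Pearson correlation with t-test significance
#'
#' Standard Pearson r between two per-amino-acid score vectors, with the
#' two-sided p-value from `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `correlation_result` list: `r`, `p_value`, `n`.
#' @export
pearson_with_pvalue <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.2g (n = %d)\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Correlations of model propensities with external scales
#'
#' Correlates per-amino-acid model scores (e.g. S_int or S_iso) against
#' externally measured propensity scales such as ln(RIP) (relative
#' interface propensity), stickiness, or ln(REI) (relative enrichment at
#' isologous interfaces). Scales are user-supplied two-column tables
#' (amino acid, value); none are bundled with the package.
#'
#' @param scores Named numeric vector over the 20 amino acids (names from
#'   [aa_alphabet()]), e.g. from [s_int()].
#' @param scales Named list of data frames, each with columns `aa` and
#'   `value` covering all 20 amino acids.
#' @return Named list of `correlation_result` objects, one per scale.
#' @export
external_scale_correlations <- function(scores, scales) {
  stopifnot(is.list(scales), !is.null(names(scales)))
  lapply(scales, function(sc) {
    stopifnot(all(c("aa", "value") %in% names(sc)))
    missing <- setdiff(aa_alphabet(), sc$aa)
    if (length(missing)) {
      stop("scale is missing amino acid(s): ",
           paste(missing, collapse = ", "))
    }
    v <- sc$value[match(names(scores), sc$aa)]
    pearson_with_pvalue(scores, v)
  })
}
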