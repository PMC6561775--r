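#' The amino-acid alphabet used throughout the package
#'
#' One-letter codes for the 20 standard amino acids in the fixed order used
#' by the packaged contact-energy matrix, by all sequence encodings and by
#' every table the package writes. The order runs from hydrophobic to polar
#' (Cys, Met, Phe, Ile, Leu, Val, Trp, Tyr, Ala, Gly, Thr, Ser, Asn, Gln,
#' Asp, Glu, His, Arg, Lys, Pro), the customary ordering for statistical
#' contact potentials.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("C", "M", "F", "I", "L", "V", "W", "Y", "A", "G",
    "T", "S", "N", "Q", "D", "E", "H", "R", "K", "P")
}

#' Load a 20x20 amino-acid contact-energy matrix
#'
#' Reads a whitespace-delimited 20x20 table of pairwise contact energies in
#' kT units, with one-letter amino-acid row and column headers. With
#' `path = NULL` the packaged default is loaded: the Betancourt-Thirumalai
#' statistical potential, i.e. the Miyazawa-Jernigan contact energies shifted
#' relative to threonine so that solvent-mediated interactions are accounted
#' for and both attractive (negative) and repulsive (positive) entries occur.
#'
#' The loader validates that all 20 standard amino acids are present, every
#' cell is numeric and the matrix is symmetric to within `1e-9`; rows and
#' columns are reordered to [aa_alphabet()].
#'
#' @param path Path to a matrix file, or `NULL` for the packaged default.
#' @return A `contact_matrix`: a named 20x20 numeric matrix (kT units).
#' @export
#' @examples
#' B <- load_contact_matrix()
#' mean(B) # slightly negative on average
#' B["C", "C"] # strong cysteine self-interaction
load_contact_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bt_contact_energies.tsv",
                        package = "multimerevo", mustWork = TRUE)
  }
  raw <- read.table(path, header = TRUE, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  aa <- aa_alphabet()
  missing_row <- setdiff(aa, rownames(raw))
  missing_col <- setdiff(aa, colnames(raw))
  if (length(missing_row) || length(missing_col)) {
    stop("contact matrix is missing amino acid(s): ",
         paste(union(missing_row, missing_col), collapse = ", "))
  }
  if (nrow(raw) != 20L || ncol(raw) != 20L) {
    stop("contact matrix must be exactly 20x20, got ",
         nrow(raw), "x", ncol(raw))
  }
  bad <- !vapply(raw, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric contact energies in column(s): ",
         paste(colnames(raw)[bad], collapse = ", "))
  }
  m <- as.matrix(raw)[aa, aa]
  asym <- abs(m - t(m))
  if (any(asym > 1e-9)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("contact matrix is not symmetric: [%s,%s] = %g but [%s,%s] = %g",
                 aa[w[1]], aa[w[2]], m[w[1], w[2]],
                 aa[w[2]], aa[w[1]], m[w[2], w[1]]))
  }
  structure(m, class = c("contact_matrix", "matrix", "array"))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Amino-acid contact-energy matrix (kT units)\n")
  cat(sprintf("  mean over all 400 ordered pairs: %.4f kT\n", mean(x)))
  cat(sprintf("  range: [%.2f, %.2f] kT\n", min(x), max(x)))
  invisible(x)
}

# cached packaged default
bt_matrix <- function() {
  if (is.null(the_env$bt)) the_env$bt <- load_contact_matrix()
  the_env$bt
}

as_contact_matrix <- function(matrix) {
  if (inherits(matrix, "contact_matrix")) return(matrix)
  stopifnot(is.matrix(matrix), nrow(matrix) == 20L, ncol(matrix) == 20L)
  matrix
}
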