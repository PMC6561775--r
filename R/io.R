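#' Read 32-residue surface sequences from FASTA
#'
#' Each record must contain exactly 32 valid amino-acid letters: positions
#' 1-16 are face A row-major, 17-32 face B (see [encode_sequences()]).
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id` and `sequence`.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- names(set)
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != 32L) {
      stop("record '", ids[i], "' has ", nchar(seqs[i]),
           " residues; exactly 32 are required")
    }
  }
  bad <- !vapply(strsplit(seqs, "", fixed = TRUE),
                 function(x) all(x %in% aa_alphabet()), logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- which(!(strsplit(seqs[i], "", fixed = TRUE)[[1]] %in%
                     aa_alphabet()))[1]
    stop("record '", ids[i], "' has an invalid letter at position ", pos)
  }
  data.frame(id = unname(ids), sequence = unname(seqs))
}

#' Write surface sequences to FASTA
#'
#' @param records Data frame with columns `id` and `sequence` (32 letters).
#' @param path Output path.
#' @export
write_sequences <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  encode_sequences(records$sequence) # validates length and alphabet
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a result table as TSV or JSON
#'
#' Deterministic column order, floats at 12 significant digits, gzip
#' compression when the path ends in `.gz`.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_result_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 12)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(jsonlite::toJSON(rows, dataframe = "rows", digits = NA,
                                na = "null", pretty = TRUE), con)
  }
  invisible(path)
}

#' Interface energies of the six worked example sequences
#'
#' The six (E_AA, E_BB, E_AB) triples, in kT, of the example phenotypes
#' used throughout the package documentation: a monomer (A), a dimer-former
#' (B), a strong dimer-former (C), a fibril former (D), a strong
#' fibril-former (E) and an oriented fibril-former (F).
#'
#' @return Data frame with columns `sequence`, `description`, `E_AA`,
#'   `E_BB`, `E_AB`.
#' @export
#' @examples
#' phenotype(with(table1_energies()[4, ], interface_energies(E_AA, E_BB, E_AB)),
#'           physical_params(0.01))
table1_energies <- function() {
  data.frame(
    sequence = c("A", "B", "C", "D", "E", "F"),
    description = c("Monomer", "Dimer-former", "Strong dimer-former",
                    "Fibril former", "Strong fibril-former",
                    "Oriented fibril-former"),
    E_AA = c(-2.68, -12.06, -15.82, -9.08, -12.28, -4.53),
    E_BB = c(-2.32, -3.14, -0.60, -8.67, -12.06, -4.52),
    E_AB = c(-2.80, -5.25, -2.80, -5.68, -12.01, -8.18)
  )
}

#' Generate small fixture files
#'
#' Writes plain-text fixtures used by tests and examples: `toy_matrix`
#' (a 20x20 matrix that is zero except for a hand-set block, for
#' brute-force oracle checks), `random_sequences` (a seeded FASTA of
#' 32-mers) and `table1_energies` (the six example energy triples as TSV).
#'
#' @param kind One of `"toy_matrix"`, `"random_sequences"`,
#'   `"table1_energies"`.
#' @param dir Output directory.
#' @param n Number of sequences for `random_sequences`.
#' @param seed Seed for `random_sequences`.
#' @return The path written, invisibly.
#' @export
make_fixtures <- function(kind = c("toy_matrix", "random_sequences",
                                   "table1_energies"),
                          dir = tempdir(), n = 10, seed = 1) {
  kind <- match.arg(kind)
  path <- file.path(dir, paste0(kind, switch(kind,
                                             toy_matrix = ".tsv",
                                             random_sequences = ".fasta",
                                             table1_energies = ".tsv")))
  if (kind == "toy_matrix") {
    aa <- aa_alphabet()
    m <- matrix(0, 20, 20, dimnames = list(aa, aa))
    m["C", "C"] <- -2
    m["C", "S"] <- m["S", "C"] <- -1
    m["S", "S"] <- 1
    write.table(data.frame(m, check.names = FALSE), path, sep = "\t",
                quote = FALSE, col.names = NA)
  } else if (kind == "random_sequences") {
    enc <- random_sequence_sample(n, seed = seed)
    write_sequences(data.frame(id = sprintf("seq%03d", seq_len(n)),
                               sequence = decode_sequences(enc)), path)
  } else {
    write.table(table1_energies(), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
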