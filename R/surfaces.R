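#' Encode and decode surface sequences
#'
#' A protein in this model carries two opposing 4x4 binding surfaces, A and
#' B, written as a single 32-letter sequence: positions 1-16 fill face A
#' row-major (rows top to bottom, columns left to right) and positions 17-32
#' fill face B in the same convention. Position numbering within a face is
#' row-major 1..16, so the main diagonal is positions 1, 6, 11, 16.
#'
#' `encode_sequences()` converts sequences (32-character strings) to an
#' integer matrix of indices into [aa_alphabet()]; `decode_sequences()`
#' inverts it.
#'
#' @param sequences Character vector of 32-letter sequences.
#' @return `encode_sequences()`: an integer matrix with one row per sequence
#'   and 32 columns; `decode_sequences()`: a character vector.
#' @export
encode_sequences <- function(sequences) {
  stopifnot(is.character(sequences))
  n <- length(sequences)
  if (any(nchar(sequences) != 32L)) {
    bad <- which(nchar(sequences) != 32L)[1]
    stop("sequence ", bad, " has ", nchar(sequences[bad]),
         " residues; exactly 32 are required")
  }
  letters32 <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                      nrow = n, ncol = 32L, byrow = TRUE)
  idx <- match(letters32, aa_alphabet())
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1, ]
    stop("invalid amino-acid letter '", letters32[bad[1], bad[2]],
         "' in sequence ", bad[1], " position ", bad[2])
  }
  matrix(idx, nrow = n, ncol = 32L)
}

#' @rdname encode_sequences
#' @param encoded Integer matrix of residue indices (one row per sequence).
#' @export
decode_sequences <- function(encoded) {
  if (is.vector(encoded)) encoded <- matrix(encoded, nrow = 1)
  apply(encoded, 1, function(row) paste(aa_alphabet()[row], collapse = ""))
}

#' Build a 4x4 surface face from residues
#'
#' @param residues 16 one-letter amino-acid codes (character vector or a
#'   single 16-character string), filled row-major.
#' @return A `surface_face`: a 4x4 character matrix.
#' @export
#' @examples
#' surface_face("CCCCMMMMFFFFIIII")
surface_face <- function(residues) {
  if (is.character(residues) && length(residues) == 1L && nchar(residues) == 16L) {
    residues <- strsplit(residues, "", fixed = TRUE)[[1]]
  }
  if (length(residues) != 16L) {
    stop("a surface face has exactly 16 residues, got ", length(residues))
  }
  bad <- !(residues %in% aa_alphabet())
  if (any(bad)) {
    stop("invalid amino-acid letter(s): ",
         paste(unique(residues[bad]), collapse = ", "))
  }
  structure(matrix(residues, 4, 4, byrow = TRUE),
            class = c("surface_face", "matrix", "array"))
}

#' Opposing-face position contacted at a given rotation
#'
#' When two 4x4 faces are brought together, position (r, c) of one face
#' touches one position of the other face, depending on the relative
#' rotation. The pairing map is an involution at every rotation: at 0 and
#' 180 degrees it has no fixed points, at 90 degrees its fixed points are
#' exactly the main-diagonal positions 1, 6, 11, 16, and at 270 degrees the
#' anti-diagonal. Fixed points are the positions at which a residue in an
#' isologous interface contacts a copy of itself.
#'
#' @param position Integer pair `c(row, col)`, each in 1..4.
#' @param rotation One of 0, 90, 180, 270 (degrees).
#' @return Integer pair `c(row, col)` on the opposing face.
#' @export
#' @examples
#' contact_partner(c(2, 2), 90) # a self-contact position
contact_partner <- function(position, rotation) {
  stopifnot(length(position) == 2L, all(position %in% 1:4))
  r <- position[1]
  c <- position[2]
  switch(as.character(rotation),
    "0"   = c(5L - r, c),
    "90"  = c(c, r),
    "180" = c(r, 5L - c),
    "270" = c(5L - c, 5L - r),
    stop("rotation must be one of 0, 90, 180, 270; got ", rotation)
  )
}

#' Interface energy between two faces at one rotation
#'
#' Sum of the 16 pairwise contact energies formed when `face2`, rotated by
#' `rotation`, is brought against `face1`. For an isologous interface
#' (`face1` identical to `face2`) each amino-acid pair interaction off the
#' rotation's fixed points is counted twice, which doubles the variance of
#' isologous interface energies relative to heterologous ones.
#'
#' @param face1,face2 `surface_face` objects (4x4 character matrices).
#' @param rotation One of 0, 90, 180, 270.
#' @param matrix A `contact_matrix`; default the packaged potential.
#' @return Energy in kT.
#' @export
interface_energy_at_rotation <- function(face1, face2, rotation,
                                         matrix = load_contact_matrix()) {
  e <- 0
  for (r in 1:4) {
    for (c in 1:4) {
      p <- contact_partner(c(r, c), rotation)
      e <- e + matrix[face1[r, c], face2[p[1], p[2]]]
    }
  }
  e
}

#' Interface energy between two faces
#'
#' The energy of an interface is the lowest of the four energies arising
#' from the four possible 90-degree rotations of one face against the other.
#' Taking the minimum is what makes isologous interfaces stronger on
#' average: their energy distribution at fixed rotation has twice the
#' variance, so its minimum over rotations reaches lower.
#'
#' @inheritParams interface_energy_at_rotation
#' @return Energy in kT.
#' @export
#' @examples
#' B <- load_contact_matrix()
#' f <- surface_face(strrep("C", 16))
#' interface_energy(f, f, B) # 16 * B["C","C"]
interface_energy <- function(face1, face2, matrix = load_contact_matrix()) {
  min(vapply(c(0, 90, 180, 270), function(rot) {
    interface_energy_at_rotation(face1, face2, rot, matrix)
  }, numeric(1)))
}

#' The three interface energies of a protein, canonically labelled
#'
#' Computes the two isologous energies E_AA and E_BB and the heterologous
#' energy E_AB for a 32-residue surface sequence, then relabels the faces if
#' necessary so that A is the stronger self-interacting face, i.e.
#' E_AA <= E_BB. On an exact tie the input labelling is kept.
#'
#' @param protein A `protein_surfaces` object, a 32-letter sequence string,
#'   or a list with elements `face_A` and `face_B`.
#' @param matrix A `contact_matrix`.
#' @return An `interface_energies` object: list with `E_AA`, `E_BB`, `E_AB`
#'   (kT) and `relabelled` (TRUE if the faces were swapped).
#' @export
#' @examples
#' protein_interface_energies(strrep("C", 16) |> paste0(strrep("S", 16)))
protein_interface_energies <- function(protein,
                                       matrix = load_contact_matrix()) {
  if (is.character(protein)) protein <- protein_surfaces(protein, matrix,
                                                         canonicalize = FALSE)
  e_11 <- interface_energy(protein$face_A, protein$face_A, matrix)
  e_22 <- interface_energy(protein$face_B, protein$face_B, matrix)
  e_12 <- interface_energy(protein$face_A, protein$face_B, matrix)
  swap <- e_11 > e_22
  interface_energies(E_AA = if (swap) e_22 else e_11,
                     E_BB = if (swap) e_11 else e_22,
                     E_AB = e_12,
                     relabelled = swap)
}

#' Construct an interface-energy triple
#'
#' @param E_AA,E_BB,E_AB Interface energies in kT; `E_AA <= E_BB` is
#'   required (A is by convention the stronger self-interacting face).
#' @param relabelled Whether the A/B labels were swapped to achieve that.
#' @return An `interface_energies` object.
#' @export
interface_energies <- function(E_AA, E_BB, E_AB, relabelled = FALSE) {
  stopifnot(is.finite(E_AA), is.finite(E_BB), is.finite(E_AB))
  if (E_AA > E_BB) {
    stop("E_AA must not exceed E_BB (relabel the faces): E_AA = ", E_AA,
         ", E_BB = ", E_BB)
  }
  structure(list(E_AA = E_AA, E_BB = E_BB, E_AB = E_AB,
                 relabelled = relabelled),
            class = "interface_energies")
}

#' @export
print.interface_energies <- function(x, ...) {
  cat(sprintf("Interface energies (kT): E_AA = %.2f, E_BB = %.2f, E_AB = %.2f%s\n",
              x$E_AA, x$E_BB, x$E_AB,
              if (isTRUE(x$relabelled)) "  [faces relabelled]" else ""))
  invisible(x)
}

#' A protein as a pair of binding surfaces
#'
#' Splits a 32-letter sequence into the two 4x4 faces and, by default,
#' relabels them so that the A face forms the stronger isologous interface
#' (E_AA <= E_BB) under the given contact matrix.
#'
#' @param sequence A 32-letter amino-acid string.
#' @param matrix A `contact_matrix` used for canonical labelling.
#' @param canonicalize If `TRUE` (default), enforce E_AA <= E_BB by swapping
#'   the faces when needed.
#' @return A `protein_surfaces` object: list with `face_A`, `face_B`
#'   (`surface_face` matrices), `sequence` (possibly face-swapped), and
#'   `relabelled`.
#' @export
#' @examples
#' p <- protein_surfaces(paste0(strrep("S", 16), strrep("C", 16)))
#' p$relabelled # TRUE: the all-Cys face is the stronger one
protein_surfaces <- function(sequence, matrix = load_contact_matrix(),
                             canonicalize = TRUE) {
  enc <- encode_sequences(sequence)
  letters <- aa_alphabet()[enc[1, ]]
  p <- list(face_A = surface_face(letters[1:16]),
            face_B = surface_face(letters[17:32]),
            sequence = sequence,
            relabelled = FALSE)
  class(p) <- "protein_surfaces"
  if (canonicalize) {
    e <- protein_interface_energies(p, matrix)
    if (e$relabelled) {
      p <- list(face_A = p$face_B, face_B = p$face_A,
                sequence = paste0(substr(sequence, 17, 32),
                                  substr(sequence, 1, 16)),
                relabelled = TRUE)
      class(p) <- "protein_surfaces"
    }
  }
  p
}

#' @export
print.protein_surfaces <- function(x, ...) {
  cat("Protein surfaces (4x4 faces, row-major)\n")
  cat("  face A:", paste(t(x$face_A), collapse = ""), "\n")
  cat("  face B:", paste(t(x$face_B), collapse = ""), "\n")
  if (isTRUE(x$relabelled)) cat("  (faces relabelled so that E_AA <= E_BB)\n")
  invisible(x)
}

#' Canonical interface energies for many sequences at once
#'
#' Vectorized equivalent of [protein_interface_energies()] running in
#' compiled code, for ensemble and chain analyses.
#'
#' @param sequences Character vector of 32-letter sequences, or an integer
#'   matrix from [encode_sequences()].
#' @param matrix A `contact_matrix`.
#' @return A data frame with columns `E_AA`, `E_BB`, `E_AB` (kT, canonical
#'   labelling) and `relabelled` (logical).
#' @export
ensemble_interface_energies <- function(sequences,
                                        matrix = load_contact_matrix()) {
  enc <- if (is.character(sequences)) encode_sequences(sequences) else sequences
  stopifnot(is.matrix(enc), ncol(enc) == 32L)
  storage.mode(enc) <- "integer"
  out <- cpp_ensemble_energies(enc - 1L, as_contact_matrix(matrix))
  data.frame(E_AA = out[, 1], E_BB = out[, 2], E_AB = out[, 3],
             relabelled = out[, 4] > 0)
}
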