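# Sequence I/O, residue bookkeeping and average molecular weight.

# Average (isotope-weighted) residue masses in Da, as used by the Expasy
# Compute pI/MW tool; a peptide mass is the sum of residue masses plus one
# water (18.01524 Da).
AA_AVERAGE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_DA <- 18.01524
CANONICAL_AA <- names(AA_AVERAGE_MASS)

# Validate a sequence for physicochemical computations: non-empty, canonical
# residues only. Errors name the first offending residue and its position.
check_canonical <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  if (nchar(sequence) == 0L) {
    stop("`sequence` is empty", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% CANONICAL_AA))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d; only the 20 canonical amino acids are admitted",
      chars[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  invisible(chars)
}

# Counts of each canonical residue (errors on non-canonical input).
residue_counts <- function(sequence) {
  chars <- check_canonical(sequence)
  as.list(table(factor(chars, levels = CANONICAL_AA)))
}

#' Construct a protein record
#'
#' @param id Accession-like identifier.
#' @param sequence Amino-acid string; uppercased, trailing `*` stop symbols
#'   stripped. Non-canonical letters are accepted here and rejected later by
#'   the molecular-weight and pI computations.
#' @param description Free-text description (default `""`).
#' @return An object of class `protein_record` with fields `id`,
#'   `description`, `sequence`.
#' @export
protein_record <- function(id, sequence, description = "") {
  sequence <- toupper(sequence)
  sequence <- sub("\\*+$", "", sequence)
  if (nchar(sequence) == 0L) {
    stop(sprintf("record '%s' has an empty sequence", id), call. = FALSE)
  }
  structure(
    list(id = as.character(id), description = as.character(description),
         sequence = sequence),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. Sequences are
#' uppercased and trailing `*` stop symbols stripped. Non-canonical residue
#' letters (B, Z, X, U, O, ...) are accepted at parse time; they raise errors
#' later in the molecular-weight/pI computations, so that profiles are never
#' silently imputed.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects, one per header, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  desc <- sub("^\\S+\\s*", "", headers)
  mapply(function(id, d, seq) protein_record(id, seq, d),
         ids, desc, as.character(set),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Average molecular weight of a protein in kDa
#'
#' Sum of average residue masses plus one water mass (18.01524 Da), divided
#' by 1000. Matches the Expasy Compute pI/MW convention; summaries report it
#' to one decimal.
#'
#' @param sequence Amino-acid string (canonical residues only; anything else
#'   is an error naming the residue and position).
#' @return Molecular weight in kDa.
#' @export
#' @examples
#' compute_mw("G") # glycine residue + water = 0.07507 kDa
compute_mw <- function(sequence) {
  chars <- check_canonical(sequence)
  (sum(AA_AVERAGE_MASS[chars]) + WATER_MASS_DA) / 1000
}
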