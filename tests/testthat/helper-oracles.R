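# Independent oracles used to validate the package's computations. These are
# written from scratch (own constants, own control flow) so they never share
# code with the implementation paths they check.

# Henderson-Hasselbalch net charge, written independently of net_charge():
# explicit per-group arithmetic over a vector of pH values, generic
# N-terminal pKa 7.5 (Bjellqvist constants).
oracle_charge <- function(sequence, pH) {
  aa <- strsplit(sequence, "")[[1]]
  nD <- sum(aa == "D"); nE <- sum(aa == "E"); nC <- sum(aa == "C")
  nY <- sum(aa == "Y"); nH <- sum(aa == "H"); nK <- sum(aa == "K")
  nR <- sum(aa == "R")
  pos <- 1 / (1 + 10^(pH - 7.5)) +
    nH / (1 + 10^(pH - 5.98)) +
    nK / (1 + 10^(pH - 10.0)) +
    nR / (1 + 10^(pH - 12.0))
  neg <- 1 / (1 + 10^(3.55 - pH)) +
    nD / (1 + 10^(4.05 - pH)) +
    nE / (1 + 10^(4.45 - pH)) +
    nC / (1 + 10^(9.0 - pH)) +
    nY / (1 + 10^(10.0 - pH))
  pos - neg
}

# Dense-grid pI: the pH on a 1e-4-step grid over [0, 14] whose net charge is
# closest to zero.
oracle_pi_grid <- function(sequence, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(oracle_charge(sequence, grid)))]
}

# Brute-force sliding-window substring counter (overlaps allowed).
oracle_count_substring <- function(s, pattern) {
  n <- nchar(s); m <- nchar(pattern)
  if (n < m) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == pattern) hits <- hits + 1L
  }
  hits
}

# Random canonical-alphabet peptide.
random_peptide <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Write protein records to a temporary FASTA file, optionally wrapped.
write_temp_fasta <- function(records, width = NA) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(records, function(r) {
    header <- paste0(">", r$id,
                     if (nzchar(r$description)) paste0(" ", r$description) else "")
    seq <- r$sequence
    body <- if (is.na(width)) seq else {
      starts <- seq(1, nchar(seq), by = width)
      substring(seq, starts, pmin(starts + width - 1, nchar(seq)))
    }
    c(header, body)
  }))
  writeLines(lines, path)
  path
}
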