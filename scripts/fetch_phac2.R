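#!/usr/bin/env Rscript
# Optional helper (requires network access): downloads the Cobetia sp. MC34
# PhaC_2 protein sequence (accession WP_213113863) from NCBI into
# inst/extdata/ so the accession-based checks and report fields can run.
# Reinstall the package afterwards.

url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
              "?db=protein&id=WP_213113863.1&rettype=fasta&retmode=text")
dest <- file.path("inst", "extdata", "WP_213113863.fasta")
dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
download.file(url, dest, quiet = TRUE)

lines <- readLines(dest, warn = FALSE)
if (length(lines) < 2L || !startsWith(lines[[1L]], ">")) {
  unlink(dest)
  stop("download did not return a FASTA record")
}
cat("wrote", dest, "(", sum(nchar(lines[-1L])), "aa )\n")
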