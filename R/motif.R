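# Motif scans: the PhaC catalytic box and the AAKP tetrapeptide.

#' Scan a sequence for PhaC-box motifs
#'
#' The PhaC box is the conserved catalytic motif `(G/S)XCX(G/A)G` surrounding
#' the active-site cysteine, related to the lipase box. Reported PhaC boxes in
#' the Halomonadaceae are often written as 5-residue motifs (GYCLG, SYCIG,
#' SYCVG), so both patterns are scanned:
#'
#' * `phac_box_6`: `[GS] x C x [GA] G` (6 positions)
#' * `phac_box_5`: `[GS] x C x G` (5 positions)
#'
#' Overlapping matches are allowed. A 6-mer match suppresses the 5-mer match
#' starting at the same position (the 5-mer is its prefix). The catalytic
#' cysteine is always at `start + 2`.
#'
#' @param sequence Non-empty amino-acid string.
#' @return A data frame of class `motif_hits` with columns `motif_name`
#'   (`"phac_box_6"` or `"phac_box_5"`), `start` (1-based), `matched_seq` and
#'   `catalytic_cys_index` (`start + 2`). Zero rows when no motif is present.
#' @export
#' @examples
#' scan_phac_box("AASYCIGAA")  # one 5-mer hit at position 3
scan_phac_box <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]

  match_at <- function(start, len) {
    if (start + len - 1L > n) return(FALSE)
    w <- chars[start:(start + len - 1L)]
    ok <- w[1L] %in% c("G", "S") && w[3L] == "C"
    if (!ok) return(FALSE)
    if (len == 5L) return(w[5L] == "G")
    w[5L] %in% c("G", "A") && w[6L] == "G"
  }

  starts6 <- if (n >= 6L) which(vapply(seq_len(n - 5L), match_at, logical(1), len = 6L)) else integer(0)
  starts5 <- if (n >= 5L) which(vapply(seq_len(n - 4L), match_at, logical(1), len = 5L)) else integer(0)
  starts5 <- setdiff(starts5, starts6)  # 6-mer suppresses 5-mer at same start

  hits <- rbind(
    if (length(starts6)) data.frame(
      motif_name = "phac_box_6", start = starts6,
      matched_seq = substring(sequence, starts6, starts6 + 5L),
      catalytic_cys_index = starts6 + 2L, stringsAsFactors = FALSE
    ),
    if (length(starts5)) data.frame(
      motif_name = "phac_box_5", start = starts5,
      matched_seq = substring(sequence, starts5, starts5 + 4L),
      catalytic_cys_index = starts5 + 2L, stringsAsFactors = FALSE
    )
  )
  if (is.null(hits)) {
    hits <- data.frame(motif_name = character(0), start = integer(0),
                       matched_seq = character(0),
                       catalytic_cys_index = integer(0),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$start, hits$motif_name), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Count AAKP motifs in a sequence region
#'
#' Counts exact occurrences of the tetrapeptide `AAKP`, a motif prevalent in
#' histone-like DNA-binding domains (e.g. the phasin PhaF). Overlapping
#' occurrences are counted (the conservative superset; `AAKP` cannot in fact
#' overlap itself, but the sliding window makes no assumption).
#'
#' @param region Amino-acid string, a contiguous slice of a record.
#' @return Integer count (`>= 0`).
#' @export
#' @examples
#' count_aakp("AAKPAAKP") # 2
count_aakp <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  region <- toupper(region)
  n <- nchar(region)
  if (n < 4L) return(0L)
  starts <- seq_len(n - 3L)
  sum(substring(region, starts, starts + 3L) == "AAKP")
}
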