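# Segmented physicochemical profiling of PhaC candidates.

#' Segmented physicochemical profile of a PhaC candidate
#'
#' Computes the characterization used for PhaC polymerase variants: average
#' molecular weight of the full sequence, isoelectric points of the full
#' sequence and of the N-terminal segment (residues `1..boundary`) and the
#' C-terminal extension (residues `boundary+1..end`), PhaC-box hits, AAKP
#' motif count in the C-terminal extension, and a variant call. The default
#' boundary of 613 residues separates the class I catalytic region from the
#' extended C-terminus of the Cobetia-type PhaC_2 variant. Sequences no longer
#' than the boundary yield a catalytic-only profile (`pi_c_segment = NA`,
#' `cterm_length_aa = 0`) rather than an error. Coordinates are 1-based
#' inclusive.
#'
#' @param record A [protein_record()] (or a bare sequence string, in which
#'   case the id is `"unnamed"`).
#' @param boundary 1-based residue count of the N-terminal segment
#'   (default 613; must be `>= 1`).
#' @param pka pKa set for the pI computations, see [pka_set()].
#' @param mw_thresholds Passed on to [classify_phac()].
#' @return An object of class `phac_profile`: a list with fields `record_id`,
#'   `length_aa`, `boundary`, `mw_kda`, `pi_full`, `pi_n_segment`,
#'   `pi_c_segment` (`NA` when there is no C-terminal extension),
#'   `cterm_length_aa`, `phac_box_hits` (a `motif_hits` data frame),
#'   `aakp_count_cterm` and `variant_call`.
#' @export
#' @examples
#' p <- gen_protein(seed = 1)
#' segment_profile(p$record)
segment_profile <- function(record, boundary = 613L, pka = pka_set(),
                            mw_thresholds = NULL) {
  if (is.character(record)) record <- protein_record("unnamed", record)
  stopifnot(inherits(record, "protein_record"))
  boundary <- as.integer(boundary)
  if (is.na(boundary) || boundary < 1L) {
    stop("`boundary` must be a positive integer", call. = FALSE)
  }
  seq_full <- record$sequence
  len <- nchar(seq_full)

  n_seg <- substr(seq_full, 1L, min(boundary, len))
  c_seg <- if (len > boundary) substr(seq_full, boundary + 1L, len) else ""
  cterm_len <- max(0L, len - boundary)

  prof <- structure(list(
    record_id = record$id,
    length_aa = len,
    boundary = boundary,
    mw_kda = compute_mw(seq_full),
    pi_full = compute_pi(seq_full, pka = pka),
    pi_n_segment = compute_pi(n_seg, pka = pka),
    pi_c_segment = if (cterm_len > 0L) compute_pi(c_seg, pka = pka) else NA_real_,
    cterm_length_aa = cterm_len,
    phac_box_hits = scan_phac_box(seq_full),
    aakp_count_cterm = if (cterm_len > 0L) count_aakp(c_seg) else 0L,
    variant_call = NA_character_
  ), class = "phac_profile")

  prof$variant_call <- if (is.null(mw_thresholds)) {
    classify_phac(prof)
  } else {
    do.call(classify_phac, c(list(prof), mw_thresholds))
  }
  prof
}

#' Classify a PhaC profile as a polymerase variant
#'
#' Class I PhaC polymerases run around 60-73 kDa; the Cobetia-type PhaC_2
#' variant carries an extended C-terminus taking the whole protein to roughly
#' 93-106 kDa. A profile is called `"phac2_extended"` when a PhaC box is
#' present and the molecular weight is at least `phac2_min_kda`;
#' `"phac1_like"` when a PhaC box is present and the weight falls inside
#' `phac1_range_kda`; otherwise `"unclassified"`.
#'
#' @param profile A `phac_profile` from [segment_profile()].
#' @param phac2_min_kda Lower weight bound for the extended variant
#'   (default 90).
#' @param phac1_range_kda Two-element weight range for class-I-sized
#'   polymerases (default `c(55, 80)`).
#' @return One of `"phac2_extended"`, `"phac1_like"`, `"unclassified"`.
#' @export
classify_phac <- function(profile, phac2_min_kda = 90,
                          phac1_range_kda = c(55, 80)) {
  stopifnot(inherits(profile, "phac_profile"))
  has_box <- nrow(profile$phac_box_hits) > 0L
  mw <- profile$mw_kda
  if (has_box && mw >= phac2_min_kda) return("phac2_extended")
  if (has_box && mw >= phac1_range_kda[1L] && mw <= phac1_range_kda[2L]) {
    return("phac1_like")
  }
  "unclassified"
}

# Partition of the 20 canonical residues into composition groups. "Small
# non-polar" and "polar" follow the grouping used in secondary-structure
# composition charts; charged groups are K+R and D+E.
AA_GROUPS <- list(
  small_nonpolar = c("G", "A", "S", "T"),
  hydrophobic    = c("C", "V", "L", "I", "M", "P", "F", "W"),
  polar          = c("N", "Q", "Y", "H"),
  positive_kr    = c("K", "R"),
  negative_de    = c("D", "E")
)

#' Amino-acid composition of a sequence region
#'
#' Per-residue counts and fractions over a sequence or segment, plus grouped
#' fractions: small non-polar (G, A, S, T), hydrophobic (C, V, L, I, M, P, F,
#' W), polar (N, Q, Y, H), positively charged (K + R) and negatively charged
#' (D + E). The groups partition the canonical alphabet, so both the residue
#' fractions and the group fractions sum to 1.
#'
#' @param region Non-empty amino-acid string (canonical residues only).
#' @return An object of class `aa_composition`: list with `n` (region
#'   length), `counts`, `fractions` (named over the 20 residues),
#'   `group_counts` and `group_fractions`.
#' @export
#' @examples
#' aa_composition("KKRR")$group_fractions[["positive_kr"]]
aa_composition <- function(region) {
  counts <- unlist(residue_counts(region))
  n <- sum(counts)
  group_counts <- vapply(AA_GROUPS, function(g) sum(counts[g]), numeric(1))
  structure(list(
    n = n,
    counts = counts,
    fractions = counts / n,
    group_counts = group_counts,
    group_fractions = group_counts / n
  ), class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, digits = 3, ...) {
  cat(sprintf("<aa_composition> %d residues\n", x$n))
  gf <- round(x$group_fractions, digits)
  cat(paste(sprintf("  %-15s %s", names(gf), format(gf)), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.phac_profile <- function(x, ...) {
  cat(sprintf("<phac_profile> %s\n", x$record_id))
  cat(sprintf("  length        %d aa (N-segment %d, C-terminus %d)\n",
              x$length_aa, min(x$boundary, x$length_aa), x$cterm_length_aa))
  cat(sprintf("  MW            %.1f kDa\n", x$mw_kda))
  cat(sprintf("  pI            full %.2f | N-segment %.2f | C-terminus %s\n",
              x$pi_full, x$pi_n_segment,
              if (is.na(x$pi_c_segment)) "-" else sprintf("%.2f", x$pi_c_segment)))
  boxes <- x$phac_box_hits
  cat(sprintf("  PhaC box      %s\n",
              if (nrow(boxes) == 0L) "none" else
                paste(sprintf("%s@%d", boxes$matched_seq, boxes$start), collapse = ", ")))
  cat(sprintf("  AAKP (C-term) %d\n", x$aakp_count_cterm))
  cat(sprintf("  variant       %s\n", x$variant_call))
  invisible(x)
}

# One Table-shaped row per profile (used by run_profile and as a user-facing
# summary). `phac_box` concatenates the matched motifs in sequence order.
profile_row <- function(p) {
  boxes <- p$phac_box_hits
  data.frame(
    record_id = p$record_id,
    length_aa = p$length_aa,
    mw_kda = round(p$mw_kda, 1),
    pi_full = round(p$pi_full, 2),
    pi_n613 = round(p$pi_n_segment, 2),
    pi_cterm = if (is.na(p$pi_c_segment)) NA_real_ else round(p$pi_c_segment, 2),
    cterm_len = p$cterm_length_aa,
    phac_box = if (nrow(boxes) == 0L) "" else paste(boxes$matched_seq, collapse = ";"),
    aakp_cterm = p$aakp_count_cterm,
    variant_call = p$variant_call,
    stringsAsFactors = FALSE
  )
}
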