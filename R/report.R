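# Table-shaped reports over whole inputs: a PhaC characterization table (one
# row per FASTA record) and a productivity table (titer recomputation with
# consistency flags and per-group dispersion).

#' Profile every record of a FASTA file into a characterization table
#'
#' Runs [segment_profile()] on each record of a FASTA file (or a list of
#' [protein_record()]s) and assembles the Table-shaped report: one row per
#' record, in input order, with columns `record_id`, `length_aa`, `mw_kda`,
#' `pi_full`, `pi_n613`, `pi_cterm`, `cterm_len`, `phac_box`, `aakp_cterm`,
#' `variant_call`. Optionally writes the table as TSV plus a JSON sidecar
#' with full motif-hit detail.
#'
#' @param input Path to a FASTA file, or a list of [protein_record()]s.
#' @param boundary Segment boundary passed to [segment_profile()].
#' @param pka pKa set, see [pka_set()].
#' @param out_tsv,out_json Optional output paths.
#' @return The report data frame (invisibly the same object that is
#'   written); zero rows with the full header for empty input lists.
#' @export
run_profile <- function(input, boundary = 613L, pka = pka_set(),
                        out_tsv = NULL, out_json = NULL) {
  records <- if (is.character(input)) read_fasta(input) else input
  stopifnot(is.list(records))
  profiles <- lapply(records, segment_profile, boundary = boundary, pka = pka)

  if (length(profiles) == 0L) {
    report <- profile_row(segment_profile(protein_record("x", "M")))[0L, ]
  } else {
    report <- do.call(rbind, lapply(profiles, profile_row))
  }

  if (!is.null(out_tsv)) {
    utils::write.table(report, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  if (!is.null(out_json)) {
    detail <- lapply(profiles, function(p) {
      c(unclass(p)[setdiff(names(unclass(p)), "phac_box_hits")],
        list(phac_box_hits = as.data.frame(p$phac_box_hits)))
    })
    jsonlite::write_json(detail, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  report
}

#' Recompute and check a PHA productivity table
#'
#' Applies [pha_titer()] to every row of a productivity table (CDW plus
#' monomer fractions as % of CDW) and, when a printed titer column is
#' present, flags rows whose printed value disagrees with the value
#' recomputed from the printed (rounded) inputs. Rows with negative CDW or
#' fractions are marked with an error message and the run continues.
#'
#' @param table A data frame with columns `cdw`, `frac_3hb` and optionally
#'   `frac_3hv`, `pha_printed`, `strain`, `substrate` (e.g.
#'   [cobetia_productivity()]), or a path to a TSV file with those columns.
#' @param out_tsv Optional TSV output path.
#' @return The input table with added columns `pha_computed` (rounded, 1
#'   decimal), `pha_exact` (unrounded), `consistent` (`NA` when no printed
#'   titer), `row_error`.
#' @export
#' @examples
#' rep <- run_productivity(cobetia_productivity())
#' subset(rep, !consistent)[, c("strain", "substrate", "pha_printed", "pha_computed")]
run_productivity <- function(table, out_tsv = NULL) {
  if (is.character(table)) {
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  if (nrow(table) > 0L && !all(c("cdw", "frac_3hb") %in% names(table))) {
    stop("productivity table needs columns `cdw` and `frac_3hb`", call. = FALSE)
  }
  n <- nrow(table)
  pha_computed <- rep(NA_real_, n)
  pha_exact <- rep(NA_real_, n)
  row_error <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fr <- c(table$frac_3hb[i],
            if ("frac_3hv" %in% names(table)) table$frac_3hv[i])
    fr <- fr[!is.na(fr)]
    res <- tryCatch(pha_titer(table$cdw[i], fr), error = function(e) e)
    if (inherits(res, "error")) {
      row_error[i] <- conditionMessage(res)
    } else {
      pha_computed[i] <- as.numeric(res)
      pha_exact[i] <- attr(res, "exact")
    }
  }
  table$pha_computed <- pha_computed
  table$pha_exact <- pha_exact
  table$consistent <- if ("pha_printed" %in% names(table)) {
    abs(table$pha_printed - pha_computed) < 1e-9
  } else {
    rep(NA, n)
  }
  table$row_error <- row_error

  if (!is.null(out_tsv)) {
    utils::write.table(table, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  table
}
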