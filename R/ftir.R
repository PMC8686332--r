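# FT-IR spectra: I/O, baseline correction, region integration and the
# C:A 1 ratio (carbonyl-ester / amide band I), a semi-quantitative PHA proxy.

#' Default FT-IR integration regions
#'
#' Carbonyl-ester 1705-1763 cm-1 and amide band I 1580-1705 cm-1. The shared
#' boundary at 1705 cm-1 belongs to both (closed, touching intervals).
#'
#' @param lo,hi Region bounds in cm-1 (`lo < hi`).
#' @param name Region label.
#' @return A list of class `ftir_region` with fields `lo`, `hi`, `name`.
#' @export
ftir_region <- function(lo, hi, name = "") {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  structure(list(lo = lo, hi = hi, name = name), class = "ftir_region")
}

#' @rdname ftir_region
#' @export
region_carbonyl <- function() ftir_region(1705, 1763, "carbonyl_ester")

#' @rdname ftir_region
#' @export
region_amide1 <- function() ftir_region(1580, 1705, "amide_I")

#' Construct an FT-IR spectrum
#'
#' @param wavenumbers Strictly monotone numeric vector (cm-1); descending
#'   input is accepted and stored ascending.
#' @param absorbance Numeric vector of the same length (unitless).
#' @param label Sample label.
#' @param time_h Optional culture time point in hours.
#' @return Object of class `ftir_spectrum`: list with `wavenumbers`
#'   (ascending), `absorbance`, `meta` (list with `label`, `time_h`).
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, label = "", time_h = NA_real_) {
  stopifnot(is.numeric(wavenumbers), is.numeric(absorbance))
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumber and absorbance vectors differ in length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumbers) || anyNA(absorbance)) {
    stop("spectrum contains non-numeric (NA) values", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (any(d <= 0)) {
    stop("wavenumbers must be strictly monotone (duplicates present?)", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = list(label = label, time_h = time_h)),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %.1f-%.1f cm-1%s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              if (nzchar(x$meta$label)) paste0(" [", x$meta$label, "]") else ""))
  invisible(x)
}

#' Read a two-column FT-IR spectrum file
#'
#' Reads delimited text (CSV/TSV/whitespace autodetected) with columns
#' wavenumber (cm-1) and absorbance; `#` starts a comment line. Descending
#' files are reversed so spectra are always stored ascending.
#'
#' @param path Path to the file.
#' @param label Sample label (defaults to the file name).
#' @param time_h Optional time point in hours.
#' @return An [ftir_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path), time_h = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  sep <- if (length(first) && grepl(",", first[[1L]], fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, comment.char = "#",
                           header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected two columns: wavenumber, absorbance", call. = FALSE)
  wn <- suppressWarnings(as.numeric(tab[[1L]]))
  ab <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(wn) || anyNA(ab)) {
    # a non-numeric header row is tolerated; anything else is an error
    if (!anyNA(wn[-1L]) && !anyNA(ab[-1L]) && is.na(wn[1L])) {
      wn <- wn[-1L]; ab <- ab[-1L]
    } else {
      stop(sprintf("non-numeric rows in %s", path), call. = FALSE)
    }
  }
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in spectrum", call. = FALSE)
  ftir_spectrum(wn, ab, label = label, time_h = time_h)
}

#' Baseline-correct a spectrum
#'
#' Removes negative absorbance values around the analysis window:
#'
#' * `method = "offset"` subtracts the minimum absorbance inside `window` so
#'   the window minimum becomes exactly 0;
#' * `method = "linear"` subtracts the straight line through the absorbances
#'   at the two window endpoints, then clips in-window negatives to 0.
#'
#' The input spectrum is not modified.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param window Length-2 numeric, cm-1 (default `c(1500, 1800)`); must lie
#'   inside the spectrum range.
#' @param method `"offset"` or `"linear"`.
#' @return A corrected [ftir_spectrum()].
#' @export
baseline_correct <- function(spectrum, window = c(1500, 1800),
                             method = c("offset", "linear")) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  method <- match.arg(method)
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  window <- sort(window)
  if (window[1L] < min(wn) || window[2L] > max(wn)) {
    stop("baseline window lies outside the spectrum range", call. = FALSE)
  }
  inside <- wn >= window[1L] & wn <= window[2L]
  if (!any(inside)) stop("no points inside the baseline window", call. = FALSE)

  if (method == "offset") {
    ab <- ab - min(ab[inside])
  } else {
    y1 <- stats::approx(wn, ab, xout = window[1L])$y
    y2 <- stats::approx(wn, ab, xout = window[2L])$y
    line <- y1 + (y2 - y1) * (wn - window[1L]) / (window[2L] - window[1L])
    ab <- ab - line
    ab[inside & ab < 0] <- 0
  }
  out <- spectrum
  out$absorbance <- ab
  out
}

#' Integrate absorbance over a spectral region
#'
#' Trapezoidal integral of absorbance over wavenumber between `region$lo` and
#' `region$hi`, with linear interpolation at boundaries that fall between
#' grid points. Units: absorbance x cm-1.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param region An [ftir_region()] (or a length-2 numeric `c(lo, hi)`).
#' @return The area (numeric scalar).
#' @export
#' @examples
#' s <- ftir_spectrum(seq(650, 4000, 1), rep(1, 3351))
#' integrate_region(s, region_carbonyl()) # 58 = width of a unit rectangle
integrate_region <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (is.numeric(region) && length(region) == 2L) {
    region <- ftir_region(min(region), max(region))
  }
  stopifnot(inherits(region, "ftir_region"))
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  lo <- max(region$lo, min(wn))
  hi <- min(region$hi, max(wn))
  if (!(lo < hi)) {
    stop(sprintf("region [%g, %g] does not overlap the spectrum range [%g, %g]",
                 region$lo, region$hi, min(wn), max(wn)), call. = FALSE)
  }
  inner <- wn > lo & wn < hi
  x <- c(lo, wn[inner], hi)
  y <- c(stats::approx(wn, ab, xout = lo)$y, ab[inner],
         stats::approx(wn, ab, xout = hi)$y)
  pracma::trapz(x, y)
}

#' C:A 1 ratio of an FT-IR spectrum
#'
#' The semi-quantitative PHA statistic: area of the carbonyl-ester region
#' (default 1705-1763 cm-1) divided by the area of the amide band I region
#' (default 1580-1705 cm-1). Also locates the carbonyl peak (wavenumber of
#' maximum absorbance inside the carbonyl window) and calls the spectrum
#' PHA-positive when that peak sits at 1724 +/- 2 cm-1 with height above the
#' window baseline exceeding `prominence`.
#'
#' Ratios are computed from raw spectra by default (`baseline = "none"`);
#' offset or linear correction over `baseline_window` can be requested, e.g.
#' for agar-plate spectra with negative absorbances.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param carbonyl,amide [ftir_region()] definitions.
#' @param baseline `"none"` (default), `"offset"` or `"linear"`.
#' @param baseline_window Window passed to [baseline_correct()].
#' @param peak_window Acceptance window for the carbonyl peak position
#'   (default `c(1722, 1726)` cm-1).
#' @param prominence Minimum peak height above the carbonyl-window minimum
#'   for a PHA-positive call (default 0.01 absorbance; a reporting
#'   convention, not an instrument constant).
#' @return Object of class `ca1_result`: list with `carbonyl_area`,
#'   `amide_area`, `ratio`, `carbonyl_peak_cm1`, `carbonyl_peak_height`
#'   (above window minimum), `pha_positive`, `baseline`.
#' @export
ca1_ratio <- function(spectrum,
                      carbonyl = region_carbonyl(), amide = region_amide1(),
                      baseline = c("none", "offset", "linear"),
                      baseline_window = c(1500, 1800),
                      peak_window = c(1722, 1726), prominence = 0.01) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  baseline <- match.arg(baseline)
  if (baseline != "none") {
    spectrum <- baseline_correct(spectrum, window = baseline_window,
                                 method = baseline)
  }
  carbonyl_area <- integrate_region(spectrum, carbonyl)
  amide_area <- integrate_region(spectrum, amide)
  if (amide_area <= 0) {
    stop("amide band I area is not positive; C:A 1 ratio undefined", call. = FALSE)
  }
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  inwin <- wn >= carbonyl$lo & wn <= carbonyl$hi
  peak_idx <- which(inwin)[which.max(ab[inwin])]
  peak_cm1 <- wn[peak_idx]
  peak_height <- ab[peak_idx] - min(ab[inwin])
  structure(list(
    carbonyl_area = carbonyl_area,
    amide_area = amide_area,
    ratio = carbonyl_area / amide_area,
    carbonyl_peak_cm1 = peak_cm1,
    carbonyl_peak_height = peak_height,
    pha_positive = peak_cm1 >= peak_window[1L] && peak_cm1 <= peak_window[2L] &&
      peak_height > prominence,
    baseline = baseline
  ), class = "ca1_result")
}

#' @export
print.ca1_result <- function(x, ...) {
  cat(sprintf("<ca1_result> C:A 1 ratio %.4f (carbonyl %.4f / amide %.4f)\n",
              x$ratio, x$carbonyl_area, x$amide_area))
  cat(sprintf("  carbonyl peak %.1f cm-1 (height %.4f) -> PHA %s\n",
              x$carbonyl_peak_cm1, x$carbonyl_peak_height,
              if (x$pha_positive) "positive" else "negative"))
  invisible(x)
}

#' Per-hour C:A 1 ratio after stationary onset
#'
#' PHA production proxies are normalized to production per hour after the
#' culture reaches stationary phase. Two readings are computed:
#'
#' * `rate` (primary): the C:A 1 ratio at the first time point at or after
#'   `stationary_onset`, divided by that elapsed time;
#' * `rate_slope` (alternative): the slope `delta ratio / delta t` over the
#'   last two points of the series.
#'
#' @param times Strictly increasing time points (h).
#' @param ratios C:A 1 ratios at those times.
#' @param stationary_onset Stationary-phase onset (h); there must be a
#'   measurement at or after it.
#' @return List of class `ca1_rate`: `rate`, `rate_slope`,
#'   `stationary_onset`, `t_used`, `ratio_used` (per-hour units).
#' @export
#' @examples
#' ratio_rate(c(4, 10), c(0.2, 0.5), stationary_onset = 10) # 0.05 /h
ratio_rate <- function(times, ratios, stationary_onset) {
  stopifnot(is.numeric(times), is.numeric(ratios),
            length(times) == length(ratios), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  idx <- which(times >= stationary_onset)
  if (length(idx) == 0L) {
    stop("no measurement at or after the stationary onset", call. = FALSE)
  }
  i <- idx[1L]
  n <- length(times)
  slope <- if (n >= 2L) {
    (ratios[n] - ratios[n - 1L]) / (times[n] - times[n - 1L])
  } else NA_real_
  structure(list(
    rate = ratios[i] / times[i],
    rate_slope = slope,
    stationary_onset = stationary_onset,
    t_used = times[i],
    ratio_used = ratios[i]
  ), class = "ca1_rate")
}

#' Convert a C:A 1 ratio into % PHA of CDW with a user calibration
#'
#' The area-ratio model is linear in PHA content only below 44% of the cell
#' dry weight, so results above that bound are returned with
#' `valid = FALSE`. No default calibration coefficients are provided: without
#' `slope`/`intercept` the result is explicitly `"uncalibrated"`.
#'
#' @param ratio C:A 1 ratio (numeric).
#' @param slope,intercept Linear calibration, `%PHA = slope * ratio +
#'   intercept`.
#' @param validity_max Upper validity bound in % of CDW (default 44).
#' @return List with `pha_pct_cdw` (or `NA` when uncalibrated), `valid`,
#'   `calibrated`.
#' @export
calibrate_ratio_to_pha <- function(ratio, slope = NULL, intercept = NULL,
                                   validity_max = 44) {
  if (is.null(slope) || is.null(intercept)) {
    return(list(pha_pct_cdw = NA_real_, valid = FALSE, calibrated = FALSE))
  }
  val <- slope * ratio + intercept
  list(pha_pct_cdw = val, valid = val <= validity_max, calibrated = TRUE)
}
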