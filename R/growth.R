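# Growth kinetics: specific growth rate from OD600 ln-ratios, exponential
# phase rate estimation, stationary onset and dispersion statistics.

#' Construct a growth curve
#'
#' @param times Strictly increasing sampling times (h).
#' @param od600 Optical densities at 600 nm (`>= 0`, finite), same length.
#' @param label Culture label.
#' @return Object of class `growth_curve`: list with `times`, `od600`,
#'   `label`.
#' @export
growth_curve <- function(times, od600, label = "") {
  stopifnot(is.numeric(times), is.numeric(od600))
  if (length(times) != length(od600)) {
    stop("`times` and `od600` differ in length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a growth curve needs at least 2 points", call. = FALSE)
  if (any(!is.finite(od600)) || any(!is.finite(times))) {
    stop("times and OD600 must be finite", call. = FALSE)
  }
  if (any(od600 < 0)) stop("OD600 values must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, od600 = od600, label = label),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d points over %.1f-%.1f h, OD600 max %.2f%s\n",
              length(x$times), min(x$times), max(x$times), max(x$od600),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Specific growth rate between two OD600 readings
#'
#' `k = ln(OD2 / OD1) / (t2 - t1)`, the per-hour exponential rate over one
#' sampling interval. Invariant to rescaling of the OD values.
#'
#' @param od1,od2 Optical densities (`> 0`) at times `t1`, `t2`.
#' @param t1,t2 Times in hours, `t2 > t1`.
#' @return The specific growth rate `k` (per h).
#' @export
#' @examples
#' specific_growth_rate(0.1, 0.2, 0, 2) # ln(2)/2
specific_growth_rate <- function(od1, od2, t1, t2) {
  if (any(c(od1, od2) <= 0)) stop("OD values must be positive", call. = FALSE)
  if (!(t2 > t1)) stop("`t2` must be greater than `t1`", call. = FALSE)
  log(od2 / od1) / (t2 - t1)
}

#' Maximum specific growth rate of a growth curve
#'
#' Two estimators of the exponential-phase rate:
#'
#' * `"pairwise_max"` applies the ln-ratio formula to every consecutive pair
#'   of positive-OD points and returns the maximum;
#' * `"regression"` fits `ln(OD) ~ t` in a sliding window (default 4 points,
#'   mirroring 2-h sampling of the exponential phase) and returns the
#'   maximum slope together with that window's r-squared.
#'
#' @param curve A [growth_curve()].
#' @param method `"pairwise_max"` (default) or `"regression"`.
#' @param window_pts Points per regression window (default 4; the pairwise
#'   method always uses 2).
#' @return Object of class `rate_estimate`: list with `k` (per h), `window`
#'   (`c(t_start, t_end)`), `method`, `r2` (`NA` for pairwise).
#' @export
max_growth_rate <- function(curve, method = c("pairwise_max", "regression"),
                            window_pts = 4L) {
  stopifnot(inherits(curve, "growth_curve"))
  method <- match.arg(method)
  pos <- curve$od600 > 0
  if (!any(pos)) stop("all OD600 values are non-positive", call. = FALSE)
  t <- curve$times[pos]
  od <- curve$od600[pos]

  if (method == "pairwise_max") {
    if (length(t) < 2L) stop("need at least 2 positive-OD points", call. = FALSE)
    ks <- vapply(seq_len(length(t) - 1L), function(i) {
      specific_growth_rate(od[i], od[i + 1L], t[i], t[i + 1L])
    }, numeric(1))
    best <- which.max(ks)
    est <- list(k = ks[best], window = c(t[best], t[best + 1L]),
                method = method, r2 = NA_real_)
  } else {
    window_pts <- max(2L, as.integer(window_pts))
    if (length(t) < window_pts) {
      stop(sprintf("need at least %d positive-OD points for the regression window",
                   window_pts), call. = FALSE)
    }
    lnod <- log(od)
    fits <- lapply(seq_len(length(t) - window_pts + 1L), function(i) {
      idx <- i:(i + window_pts - 1L)
      fit <- stats::lm(lnod[idx] ~ t[idx])
      list(k = unname(stats::coef(fit)[2L]),
           r2 = summary(fit)$r.squared,
           window = c(t[idx[1L]], t[idx[window_pts]]))
    })
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "k"))]]
    est <- list(k = best$k, window = best$window, method = method, r2 = best$r2)
  }
  structure(est, class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> k = %.4f /h (%s, window %.1f-%.1f h%s)\n",
              x$k, x$method, x$window[1L], x$window[2L],
              if (is.na(x$r2)) "" else sprintf(", r2 = %.3f", x$r2)))
  invisible(x)
}

#' Stationary-phase onset of a growth curve
#'
#' First sampling time at which the OD600 reaches `frac` of the curve
#' maximum (default 95%). A simple threshold convention; the fraction is
#' configurable.
#'
#' @param curve A [growth_curve()].
#' @param frac Fraction of the maximum OD (default 0.95).
#' @return Onset time in hours.
#' @export
stationary_onset <- function(curve, frac = 0.95) {
  stopifnot(inherits(curve, "growth_curve"))
  curve$times[which(curve$od600 >= frac * max(curve$od600))[1L]]
}

#' Population dispersion statistics
#'
#' Mean, population standard deviation (divide-by-n, the spreadsheet
#' `STDEV.P` convention) and coefficient of variation `sd / mean`.
#'
#' @param values Numeric vector with at least one value.
#' @return Object of class `dispersion_stat`: list with `mean`,
#'   `population_sd`, `cv` (`NA` when the mean is 0) and `n`.
#' @export
#' @examples
#' dispersion(c(2, 4)) # population sd 1, mean 3
dispersion <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize", call. = FALSE)
  m <- mean(values)
  psd <- sqrt(mean((values - m)^2))
  structure(list(
    mean = m,
    population_sd = psd,
    cv = if (m != 0) psd / m else NA_real_,
    n = length(values)
  ), class = "dispersion_stat")
}

#' @export
print.dispersion_stat <- function(x, ...) {
  cat(sprintf("<dispersion_stat> mean %.4g, population sd %.4g, cv %s (n = %d)\n",
              x$mean, x$population_sd,
              if (is.na(x$cv)) "-" else sprintf("%.4g", x$cv), x$n))
  invisible(x)
}
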