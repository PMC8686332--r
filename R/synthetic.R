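# Seeded generators for ground-truth-known proteins, FT-IR spectra and
# growth curves. Every generator is deterministic for a fixed seed and
# returns the planted truth alongside the object, so each analysis stage can
# be validated without external data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Background alphabet for synthetic proteins: the canonical residues minus
# cysteine and proline. A PhaC box requires a central C and an AAKP motif a
# P, so excluding both from the background guarantees that the only motif
# matches in a generated sequence are the planted ones (exact recovery).
SYNTH_BACKGROUND_AA <- setdiff(CANONICAL_AA, c("C", "P"))

#' Generate a synthetic PhaC-like protein with planted features
#'
#' Emulates the two-segment architecture of the extended PhaC_2 variant: a
#' catalytic N-terminal segment carrying one planted PhaC-box motif, followed
#' by a low-complexity C-terminal extension enriched in lysine/arginine with
#' a planted number of AAKP motifs. Background residues are drawn uniformly
#' from the canonical alphabet minus C and P so that the planted motifs are
#' provably the only matches; the residue following a planted 5-residue box
#' is forced to be non-G so the hit is not promoted to a 6-mer match.
#'
#' @param seed Integer seed; the same seed always yields the same record.
#' @param catalytic_len N-terminal segment length (default 613).
#' @param cterm_len C-terminal extension length (default 380); 0 gives a
#'   catalytic-only protein.
#' @param box_motif PhaC-box motif to plant (default `"SYCIG"`).
#' @param box_pos 1-based position of the box in the catalytic segment
#'   (default 310).
#' @param n_aakp Number of non-overlapping AAKP motifs planted in the
#'   C-terminus (default 5).
#' @param cterm_kr_fraction Target K+R background fraction in the C-terminus
#'   (default 0.20; the realized fraction is recorded exactly in the truth).
#' @param nterm_de_fraction Target D+E background fraction in the catalytic
#'   segment (default 0.15), giving it the acidic isoelectric point
#'   characteristic of real PhaC catalytic domains.
#' @param id Record id.
#' @return List with `record` (a [protein_record()]) and `truth` (list:
#'   `box_motif`, `box_start`, `catalytic_cys_index`, `aakp_starts_cterm`,
#'   `n_aakp`, `kr_fraction_cterm` (exact, over the final C-terminus),
#'   `catalytic_len`, `cterm_len`).
#' @export
#' @examples
#' g <- gen_protein(seed = 42)
#' count_aakp(substr(g$record$sequence, 614, nchar(g$record$sequence)))
gen_protein <- function(seed, catalytic_len = 613L, cterm_len = 380L,
                        box_motif = "SYCIG", box_pos = 310L, n_aakp = 5L,
                        cterm_kr_fraction = 0.20, nterm_de_fraction = 0.15,
                        id = sprintf("synthetic_phac_%d", seed)) {
  catalytic_len <- as.integer(catalytic_len)
  cterm_len <- as.integer(cterm_len)
  box_len <- nchar(box_motif)
  if (box_pos < 1L || box_pos + box_len - 1L > catalytic_len) {
    stop("planted PhaC box does not fit inside the catalytic segment", call. = FALSE)
  }
  if (n_aakp > 0L && cterm_len < 4L * n_aakp) {
    stop("planted AAKP motifs do not fit inside the C-terminus", call. = FALSE)
  }
  if (cterm_kr_fraction < 0 || cterm_kr_fraction > 1) {
    stop("`cterm_kr_fraction` must be in [0, 1]", call. = FALSE)
  }

  if (nterm_de_fraction < 0 || nterm_de_fraction > 1) {
    stop("`nterm_de_fraction` must be in [0, 1]", call. = FALSE)
  }

  with_seed(seed, {
    de <- nterm_de_fraction
    non_de <- setdiff(SYNTH_BACKGROUND_AA, c("D", "E"))
    nprobs <- c(rep(de / 2, 2L), rep((1 - de) / length(non_de), length(non_de)))
    ncat <- sample(c("D", "E", non_de), catalytic_len, replace = TRUE,
                   prob = nprobs)
    ncat[box_pos:(box_pos + box_len - 1L)] <- strsplit(box_motif, "")[[1L]]
    after <- box_pos + box_len
    if (box_len == 5L && after <= catalytic_len && ncat[after] %in% c("G")) {
      ncat[after] <- "L"
    }

    aakp_starts <- integer(0)
    cterm <- character(0)
    if (cterm_len > 0L) {
      kr <- cterm_kr_fraction
      others <- setdiff(SYNTH_BACKGROUND_AA, c("K", "R"))
      probs <- c(rep(kr / 2, 2L), rep((1 - kr) / length(others), length(others)))
      cterm <- sample(c("K", "R", others), cterm_len, replace = TRUE, prob = probs)
      if (n_aakp > 0L) {
        slots <- seq_len(cterm_len - 3L)
        while (length(aakp_starts) < n_aakp) {
          cand <- sample(slots, 1L)
          if (all(abs(cand - aakp_starts) >= 4L) || length(aakp_starts) == 0L) {
            aakp_starts <- c(aakp_starts, cand)
          }
        }
        aakp_starts <- sort(aakp_starts)
        for (s in aakp_starts) cterm[s:(s + 3L)] <- c("A", "A", "K", "P")
      }
    }

    seq_full <- paste(c(ncat, cterm), collapse = "")
    kr_exact <- if (cterm_len > 0L) {
      sum(cterm %in% c("K", "R")) / cterm_len
    } else NA_real_

    list(
      record = protein_record(id, seq_full,
                              description = "synthetic PhaC-like protein"),
      truth = list(
        box_motif = box_motif,
        box_start = box_pos,
        catalytic_cys_index = box_pos + 2L,
        aakp_starts_cterm = aakp_starts,
        n_aakp = as.integer(n_aakp),
        kr_fraction_cterm = kr_exact,
        catalytic_len = catalytic_len,
        cterm_len = cterm_len
      )
    )
  })
}

#' Generate a synthetic FT-IR spectrum with known band areas
#'
#' Absorbance is a sum of Gaussian bands plus a linear baseline and iid
#' Gaussian noise on the default instrument-like grid (650-4000 cm-1, step
#' 1.9). The default band set emulates a bacterial pellet: a carbonyl-ester
#' band at 1724 cm-1 whose amplitude scales linearly with the simulated PHA
#' fraction (`amplitude = 2.5 * pha_fraction`; the slope is an arbitrary,
#' recorded convention — only monotonicity is meaningful), amide I at
#' 1650 cm-1, amide II at 1540 cm-1 and minor CH-stretch bands at
#' 2850-2960 cm-1.
#'
#' @param seed Integer seed.
#' @param pha_fraction Simulated PHA content as a fraction of CDW in
#'   `[0, 0.6]` (default 0.2).
#' @param wn_min,wn_max,step Wavenumber grid (cm-1).
#' @param bands Optional data frame with columns `center`, `sigma`,
#'   `amplitude` replacing the non-carbonyl default bands.
#' @param pha_amp_slope Linear map from `pha_fraction` to carbonyl amplitude
#'   (default 2.5).
#' @param baseline_offset,baseline_slope Linear baseline (absorbance and
#'   absorbance per cm-1).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.002 absorbance).
#' @param label Spectrum label.
#' @param time_h Optional time point (h).
#' @return List with `spectrum` (an [ftir_spectrum()]) and `truth` (list:
#'   `pha_fraction`, `carbonyl_amplitude`, `bands` data frame with analytic
#'   full-line areas `amplitude * sigma * sqrt(2*pi)`, `baseline_offset`,
#'   `baseline_slope`, `noise_sd`, `clean_absorbance`).
#' @export
gen_spectrum <- function(seed, pha_fraction = 0.2,
                         wn_min = 650, wn_max = 4000, step = 1.9,
                         bands = NULL, pha_amp_slope = 2.5,
                         baseline_offset = 0.02, baseline_slope = 2e-5,
                         noise_sd = 0.002,
                         label = sprintf("synthetic_spectrum_%d", seed),
                         time_h = NA_real_) {
  if (pha_fraction < 0 || pha_fraction > 0.6) {
    stop("`pha_fraction` must be in [0, 0.6]", call. = FALSE)
  }
  wn <- seq(wn_min, wn_max, by = step)
  if (is.null(bands)) {
    bands <- data.frame(
      name = c("amide_I", "amide_II", "ch2_sym", "ch3_sym", "ch2_asym", "ch3_asym"),
      center = c(1650, 1540, 2852, 2874, 2922, 2958),
      sigma = c(18, 15, 10, 8, 12, 10),
      amplitude = c(1.0, 0.6, 0.10, 0.06, 0.16, 0.10),
      stringsAsFactors = FALSE
    )
  }
  a_pha <- pha_amp_slope * pha_fraction
  bands <- rbind(
    data.frame(name = "carbonyl_ester", center = 1724, sigma = 10,
               amplitude = a_pha, stringsAsFactors = FALSE),
    bands
  )
  bands$area_analytic <- bands$amplitude * bands$sigma * sqrt(2 * pi)

  clean <- baseline_offset + baseline_slope * (wn - wn_min)
  for (i in seq_len(nrow(bands))) {
    clean <- clean + bands$amplitude[i] *
      exp(-(wn - bands$center[i])^2 / (2 * bands$sigma[i]^2))
  }
  ab <- with_seed(seed, clean + stats::rnorm(length(wn), sd = noise_sd))

  list(
    spectrum = ftir_spectrum(wn, ab, label = label, time_h = time_h),
    truth = list(
      pha_fraction = pha_fraction,
      carbonyl_amplitude = a_pha,
      bands = bands,
      baseline_offset = baseline_offset,
      baseline_slope = baseline_slope,
      noise_sd = noise_sd,
      clean_absorbance = clean
    )
  )
}

#' Generate a synthetic logistic growth curve with known rate
#'
#' OD600 follows a logistic curve with an initial lag: constant at
#' `start_od` until `lag`, then
#' `OD(t) = K * N0 / (N0 + (K - N0) * exp(-k * (t - lag)))`, sampled at a
#' fixed interval and perturbed by multiplicative log-normal noise
#' (`OD * exp(rnorm(0, noise_sd))`). Defaults emulate shake-flask
#' cultivation: start OD 0.05, intrinsic rate 0.4 per h, carrying capacity
#' OD 15, 2-h sampling over 32 h.
#'
#' @param seed Integer seed.
#' @param k True intrinsic exponential rate (per h, `> 0`).
#' @param lag Lag phase duration (h).
#' @param capacity Carrying capacity (maximum OD600, `>= start_od`).
#' @param start_od Inoculation OD600 (`> 0`).
#' @param interval Sampling interval (h, default 2).
#' @param horizon Total duration (h, default 32).
#' @param noise_sd Log-scale noise standard deviation (default 0.02).
#' @param label Curve label.
#' @return List with `curve` (a [growth_curve()]) and `truth` (list: `k`,
#'   `lag`, `capacity`, `start_od`, `t_stationary` (analytic time at which
#'   the noise-free curve reaches 95% of capacity; `lag` for a flat curve),
#'   `od_true` (noise-free ODs)).
#' @export
gen_growth_curve <- function(seed, k = 0.4, lag = 2, capacity = 15,
                             start_od = 0.05, interval = 2, horizon = 32,
                             noise_sd = 0.02,
                             label = sprintf("synthetic_growth_%d", seed)) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (start_od <= 0) stop("`start_od` must be positive", call. = FALSE)
  if (capacity < start_od) stop("`capacity` must be >= `start_od`", call. = FALSE)
  times <- seq(0, horizon, by = interval)
  grow <- pmax(0, times - lag)
  od_true <- capacity * start_od /
    (start_od + (capacity - start_od) * exp(-k * grow))
  od <- with_seed(seed, od_true * exp(stats::rnorm(length(times), sd = noise_sd)))

  t_stat <- if (capacity > start_od / 0.95) {
    lag + log(0.95 * (capacity - start_od) / (0.05 * start_od)) / k
  } else {
    lag
  }

  list(
    curve = growth_curve(times, od, label = label),
    truth = list(k = k, lag = lag, capacity = capacity, start_od = start_od,
                 t_stationary = t_stat, od_true = od_true)
  )
}
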