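# Synthetic triple-quadrupole instrument.  The forward model is deliberately
# simple: a linear mass axis (DAC = omega * mass + zeta), peak width driven
# monotonically by the per-mass OFFSET deviation, and a separable Gaussian
# ion-source/lens response surface (optionally with a lower decoy mode) that
# scales peak intensity.  Spectra are Gaussian peaks on a uniform m/z grid
# with multiplicative intensity noise, mass-reading jitter and a flat
# baseline noise floor.

#' Synthetic instrument ground truth
#'
#' @param omega,zeta True mass-axis slope (DAC units per m/z) and intercept.
#' @param anchors Anchor masses (m/z), strictly increasing.
#' @param fwhm_at_target Peak FWHM (m/z) obtained at the true offsets, one
#'   per anchor.
#' @param offset_true True OFFSET value per anchor (the resolution optimum).
#' @param offset_sens FWHM change (m/z) per OFFSET unit; positive, so the
#'   width grows monotonically with the offset deviation.
#' @param fwhm_floor Smallest achievable FWHM (m/z).
#' @param source_opt Named optimum of the (CUR, GS1, DP, EP) response.
#' @param source_sigma Per-axis Gaussian widths of the response surface
#'   (defaults are roughly a quarter of each axis box, as source responses
#'   are broad on real instruments).
#' @param source_floor Residual relative transmission far from the optimum
#'   (the instrument always passes some ions).
#' @param i_max Peak apex intensity (counts) at the response optimum.
#' @param decoy Optional local intensity mode: `list(location =, height =,
#'   sigma =)` with `height < 1` relative to `i_max`.
#' @param noise_cv Relative (multiplicative) intensity noise.
#' @param mass_jitter_sd Mass-reading jitter SD (m/z).
#' @param baseline_sd Flat additive baseline noise SD (counts).
#' @param detection_floor Apex counts below which a peak is not detected.
#' @param dac_box,offset_box Control boxes for DAC and OFFSET values.
#' @param source_lower,source_upper Box for (CUR, GS1, DP, EP).
#' @param grid_step,half_window Acquisition grid step and half-width (m/z).
#' @return An object of class `"instrument_truth"`.
#' @export
instrument_ground_truth <- function(omega = 50, zeta = 120,
                                    anchors = c(59.05, 616.46, 906.67),
                                    fwhm_at_target = c(0.6, 0.7, 0.725),
                                    offset_true = c(-4, 3, 5),
                                    offset_sens = 0.08, fwhm_floor = 0.2,
                                    source_opt = c(CUR = 20, GS1 = 40, DP = 80, EP = 10),
                                    source_sigma = c(12, 22, 45, 3.2),
                                    source_floor = 0.02, i_max = 1e6,
                                    decoy = NULL, noise_cv = 0.03,
                                    mass_jitter_sd = 0.005, baseline_sd = 50,
                                    detection_floor = 1e3,
                                    dac_box = c(0, 65535), offset_box = c(-8, 8),
                                    source_lower = c(0, 0, 0, 2),
                                    source_upper = c(50, 90, 180, 15),
                                    grid_step = 0.01, half_window = 3) {
  if (omega <= 0) stop("omega must be positive")
  if (i_max <= 0) stop("i_max must be positive")
  if (any(source_sigma <= 0)) stop("source_sigma must be positive")
  if (is.unsorted(anchors, strictly = TRUE)) stop("anchors must be strictly increasing")
  stopifnot(length(fwhm_at_target) == length(anchors),
            length(offset_true) == length(anchors))
  if (!is.null(decoy)) {
    if (is.null(decoy$height) || decoy$height >= 1 || decoy$height <= 0)
      stop("decoy height must lie strictly in (0, 1)")
    if (length(decoy$location) != 4L) stop("decoy location must have 4 components")
    if (is.null(decoy$sigma)) decoy$sigma <- 0.7 * source_sigma
  }
  structure(list(omega = omega, zeta = zeta, anchors = anchors,
                 fwhm_at_target = fwhm_at_target, offset_true = offset_true,
                 offset_sens = offset_sens, fwhm_floor = fwhm_floor,
                 source_opt = source_opt, source_sigma = source_sigma,
                 source_floor = source_floor, i_max = i_max, decoy = decoy,
                 noise_cv = noise_cv, mass_jitter_sd = mass_jitter_sd,
                 baseline_sd = baseline_sd, detection_floor = detection_floor,
                 dac_box = dac_box, offset_box = offset_box,
                 source_lower = source_lower, source_upper = source_upper,
                 grid_step = grid_step, half_window = half_window,
                 grid_offsets = grid_step * seq.int(-round(half_window / grid_step),
                                                    round(half_window / grid_step))),
            class = "instrument_truth")
}

#' Relative ion-source response
#'
#' Separable Gaussian response around the optimum, plus the optional decoy
#' mode, floored at the residual transmission and capped at 1.
#'
#' @param truth An [instrument_ground_truth()].
#' @param x Length-4 vector (CUR, GS1, DP, EP), or a `4 x k` matrix.
#' @return Relative response in `(0, 1]`, one value per candidate.
#' @export
source_response <- function(truth, x) {
  x <- as.matrix(x)
  if (nrow(x) != 4L) stop("source settings must have 4 components")
  resp <- exp(-0.5 * colSums(((x - truth$source_opt) / truth$source_sigma)^2))
  if (!is.null(truth$decoy)) {
    resp <- resp + truth$decoy$height *
      exp(-0.5 * colSums(((x - truth$decoy$location) / truth$decoy$sigma)^2))
  }
  truth$source_floor + (1 - truth$source_floor) * pmin(resp, 1)
}

# scalar fast path used by acquire_spectrum
source_response_fast <- function(truth, x) {
  resp <- exp(-0.5 * sum(((x - truth$source_opt) / truth$source_sigma)^2))
  if (!is.null(truth$decoy)) {
    resp <- resp + truth$decoy$height *
      exp(-0.5 * sum(((x - truth$decoy$location) / truth$decoy$sigma)^2))
  }
  truth$source_floor + (1 - truth$source_floor) * min(resp, 1)
}

#' Instrument control settings
#'
#' @param anchors Anchor masses (m/z).
#' @param dac DAC value at each anchor.
#' @param offset OFFSET value at each anchor.
#' @param source Length-4 (CUR, GS1, DP, EP) vector.
#' @return An object of class `"control_settings"`.
#' @export
control_settings <- function(anchors, dac, offset, source) {
  stopifnot(length(dac) == length(anchors), length(offset) == length(anchors),
            length(source) == 4L)
  structure(list(anchors = as.numeric(anchors), dac = as.numeric(dac),
                 offset = as.numeric(offset), source = as.numeric(source)),
            class = "control_settings")
}

#' Settings exactly at the instrument ground truth
#'
#' @param truth An [instrument_ground_truth()].
#' @return A [control_settings()] at the hidden optimum.
#' @export
true_settings <- function(truth) {
  control_settings(truth$anchors,
                   dac = truth$omega * truth$anchors + truth$zeta,
                   offset = truth$offset_true,
                   source = truth$source_opt)
}

#' Randomly detuned settings
#'
#' Draws a detuned starting state: anchor DACs perturbed uniformly by up to
#' `dac_error` DAC units around the true line, offsets uniform over the
#' offset box and source parameters uniform over the source box.  Consumes
#' the global RNG.
#'
#' @param truth An [instrument_ground_truth()].
#' @param dac_error Maximum absolute DAC perturbation (default 100 units,
#'   i.e. a 2 m/z shift at the default slope).
#' @return A [control_settings()].
#' @export
detuned_settings <- function(truth, dac_error = 100) {
  k <- length(truth$anchors)
  dac <- truth$omega * truth$anchors + truth$zeta +
    stats::runif(k, -dac_error, dac_error)
  offset <- stats::runif(k, truth$offset_box[1], truth$offset_box[2])
  source <- stats::runif(4L, truth$source_lower, truth$source_upper)
  control_settings(truth$anchors, clamp(dac, truth$dac_box[1], truth$dac_box[2]),
                   offset, source)
}

#' Piecewise-linear interpolation of a control curve
#'
#' Interpolates between neighbouring anchors; queries outside the anchor
#' range extrapolate linearly along the nearest segment.
#'
#' @param masses Strictly increasing anchor masses (at least 2).
#' @param values Control value at each anchor.
#' @param query Query mass (vectorised).
#' @return Interpolated control value(s).
#' @export
interpolate_control <- function(masses, values, query) {
  n <- length(masses)
  if (n < 2L) stop("need at least 2 anchors")
  if (is.unsorted(masses, strictly = TRUE)) stop("anchor masses must be strictly increasing")
  if (length(values) != n) stop("values must match masses in length")
  seg <- clamp(findInterval(query, masses), 1L, n - 1L)
  values[seg] + (query - masses[seg]) *
    (values[seg + 1L] - values[seg]) / (masses[seg + 1L] - masses[seg])
}

# unchecked scalar interpolation for the acquisition hot path
interp1 <- function(masses, values, q) {
  n <- length(masses)
  seg <- findInterval(q, masses)
  if (seg < 1L) seg <- 1L else if (seg > n - 1L) seg <- n - 1L
  values[seg] + (q - masses[seg]) *
    (values[seg + 1L] - values[seg]) / (masses[seg + 1L] - masses[seg])
}

#' Acquire a spectrum from the synthetic instrument
#'
#' Generates a Gaussian peak whose centroid reflects the DAC deviation from
#' the true mass-axis line, whose FWHM follows the OFFSET deviation from the
#' per-mass resolution optimum (floored at the instrument minimum), and
#' whose apex scales with the source response; noise adds mass jitter,
#' multiplicative intensity error and a flat baseline.
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings A [control_settings()].
#' @param mass Target mass (m/z) at the centre of the acquisition window.
#' @param noise Set `FALSE` for the noiseless forward model.
#' @return An object of class `"spectrum"`: list with `mz` and `intensity`.
#' @export
acquire_spectrum <- function(truth, settings, mass, noise = TRUE) {
  dac_at <- interp1(settings$anchors, settings$dac, mass)
  off_at <- interp1(settings$anchors, settings$offset, mass)
  centroid <- mass + (dac_at - (truth$omega * mass + truth$zeta)) / truth$omega
  if (noise) centroid <- centroid + stats::rnorm(1L, 0, truth$mass_jitter_sd)
  fw0 <- interp1(truth$anchors, truth$fwhm_at_target, mass)
  off0 <- interp1(truth$anchors, truth$offset_true, mass)
  fw <- max(truth$fwhm_floor, fw0 + truth$offset_sens * (off_at - off0))
  amp <- truth$i_max * source_response_fast(truth, settings$source)
  if (noise) amp <- max(0, amp * (1 + stats::rnorm(1L, 0, truth$noise_cv)))
  mz <- mass + truth$grid_offsets
  sig <- fw / (2 * sqrt(2 * log(2)))
  dev <- mz - centroid
  intensity <- amp * exp(dev * dev / (-2 * sig * sig))
  if (noise) {
    intensity <- intensity + stats::rnorm(length(mz), 0, truth$baseline_sd)
    intensity[intensity < 0] <- 0
  }
  out <- list(mz = mz, intensity = intensity)
  class(out) <- "spectrum"
  out
}

#' Measure centroid, FWHM and apex of a spectrum
#'
#' The apex is the maximum sample; the centroid is the intensity-weighted
#' mean over the contiguous run of samples at or above half maximum around
#' the apex; the FWHM is the distance between the two half-maximum crossings
#' located by linear interpolation on each flank.  A flank that never drops
#' below half maximum inside the window yields `fwhm = NA` (truncated peak).
#'
#' @param spectrum A [acquire_spectrum()] result.
#' @param floor Detection floor (counts); an apex at or below it raises a
#'   no-peak error (condition class `ipsotune_no_peak`).
#' @return An object of class `"peak_measurement"`: `mass`, `fwhm`,
#'   `intensity`.
#' @export
measure_peak <- function(spectrum, floor = 0) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  len <- length(y)
  if (len == 0L) stop("empty spectrum")
  i0 <- which.max(y)
  apex <- y[i0]
  if (apex <= floor) {
    stop(structure(class = c("ipsotune_no_peak", "error", "condition"),
                   list(message = "no peak above the detection floor",
                        call = sys.call())))
  }
  half <- apex / 2
  l <- i0
  while (l > 1L && y[l - 1L] >= half) l <- l - 1L
  r <- i0
  while (r < len && y[r + 1L] >= half) r <- r + 1L
  centroid <- sum(mz[l:r] * y[l:r]) / sum(y[l:r])
  left <- if (l > 1L) {
    mz[l - 1L] + (half - y[l - 1L]) * (mz[l] - mz[l - 1L]) / (y[l] - y[l - 1L])
  } else NA_real_
  right <- if (r < len) {
    mz[r] + (y[r] - half) * (mz[r + 1L] - mz[r]) / (y[r] - y[r + 1L])
  } else NA_real_
  fw <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  out <- list(mass = centroid, fwhm = fw, intensity = apex)
  class(out) <- "peak_measurement"
  out
}

#' Averaged peak measurement at given settings
#'
#' Acquires `n_acq` spectra at the target mass and averages the per-spectrum
#' measurements (the package default of 3 acquisitions tames noise).
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings A [control_settings()].
#' @param mass Target mass (m/z).
#' @param n_acq Number of averaged acquisitions.
#' @param noise Use the noisy forward model.
#' @param floor Detection floor; defaults to the instrument's.
#' @return A `"peak_measurement"` of the averaged quantities.
#' @export
measure_settings <- function(truth, settings, mass, n_acq = 3, noise = TRUE,
                             floor = truth$detection_floor) {
  ms <- numeric(n_acq)
  fw <- numeric(n_acq)
  it <- numeric(n_acq)
  for (i in seq_len(n_acq)) {
    pk <- measure_peak(acquire_spectrum(truth, settings, mass, noise = noise),
                       floor = floor)
    ms[i] <- pk$mass
    fw[i] <- pk$fwhm
    it[i] <- pk$intensity
  }
  out <- list(mass = mean(ms), fwhm = mean(fw), intensity = mean(it))
  class(out) <- "peak_measurement"
  out
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat("<peak_measurement> mass =", format(x$mass), " FWHM =", format(x$fwhm),
      " apex =", format(x$intensity), "\n")
  invisible(x)
}

#' @export
print.instrument_truth <- function(x, ...) {
  cat("<instrument_truth> omega =", x$omega, " zeta =", x$zeta, "\n")
  cat("  anchors:", paste(x$anchors, collapse = ", "), "m/z\n")
  cat("  decoy mode:", if (is.null(x$decoy)) "off" else "on", "\n")
  invisible(x)
}

#' Write / read instrument ground truth as JSON
#'
#' @param truth An [instrument_ground_truth()].
#' @param path File path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the reconstructed `"instrument_truth"`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$grid_offsets <- NULL  # derived field, rebuilt by the constructor
  if (!is.null(x$decoy)) x$decoy <- as.list(x$decoy)
  x$source_opt <- unlist(x$source_opt)
  do.call(instrument_ground_truth, x)
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum A `"spectrum"` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
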