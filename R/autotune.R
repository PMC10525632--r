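# Staged auto-tuning: alternate iterative mass-axis correction with
# swarm-based resolution (OFFSET) calibration until the stage-I weighted
# squared-error condition holds at every anchor, then maximise peak
# intensity over the 4-D (CUR, GS1, DP, EP) box until it reaches the pass
# threshold.

#' Tuning configuration
#'
#' @param anchors Anchor masses (m/z) for the low/mid/high segments.
#' @param tfw Target FWHM per anchor (defaults to the midpoints of the
#'   acceptance windows).
#' @param fwhm_windows Acceptance FWHM windows (m/z) per anchor.
#' @param mass_tol Mass-accuracy pass bound (m/z).
#' @param mass_axis_target Internal convergence target of the iterative
#'   mass-axis correction (m/z); tighter than `mass_tol` so the joint
#'   stage-I condition stays attainable for the resolution stage.
#' @param lambda2,lambda3 Stage-I objective weights on the squared FWHM and
#'   mass deviations (non-negative).
#' @param eps_i Stage-I termination threshold per anchor; default
#'   `lambda2 * (0.8 * halfwidth)^2` of each FWHM window, so meeting the
#'   condition implies the window and the mass bound with a 20% margin
#'   against measurement noise.
#' @param it Intensity pass threshold (counts) for stage II.
#' @param m Swarm size for the calibration/optimization stages.
#' @param n_iter Iteration cap per swarm stage.
#' @param alpha,beta Dynamic-boundary coefficients.
#' @param wmin,wmax Inertia-weight bounds.
#' @param t0,eta Annealing temperature and cooling factor.
#' @param eps Annealing threshold mode (`NULL` = fresh uniform draw).
#' @param offset_v,dac_v Velocity bounds for the OFFSET and DAC components.
#' @param source_v Per-axis velocity bound for (CUR, GS1, DP, EP).
#' @param n_acq Acquisitions averaged per measurement.
#' @param max_outer Cap on mass-axis/resolution alternation passes.
#' @param penalty Objective value substituted for failed measurements.
#' @param ref_anchor Anchor index whose intensity drives stage II.
#' @return An object of class `"tune_config"`.
#' @export
tune_config <- function(anchors = c(59.05, 616.46, 906.67),
                        tfw = c(0.6, 0.7, 0.725),
                        fwhm_windows = list(c(0.5, 0.7), c(0.6, 0.8), c(0.6, 0.85)),
                        mass_tol = 0.2, mass_axis_target = 0.05,
                        lambda2 = 1, lambda3 = 1, eps_i = NULL, it = 7e5,
                        m = 30, n_iter = 50, alpha = 0.1, beta = 0.05,
                        wmin = 0.4, wmax = 0.9, t0 = 80, eta = 0.9, eps = NULL,
                        offset_v = 0.5, dac_v = 60, source_v = c(5, 5, 1, 1),
                        n_acq = 3, max_outer = 6, penalty = 1e6,
                        ref_anchor = 1) {
  if (lambda2 < 0 || lambda3 < 0) stop("lambda weights must be non-negative")
  if (it <= 0) stop("intensity threshold must be positive")
  half <- vapply(fwhm_windows, function(w) diff(w) / 2, numeric(1))
  if (any(half <= 0)) stop("FWHM windows must be well-ordered")
  if (is.null(eps_i)) eps_i <- lambda2 * (0.8 * half)^2
  structure(list(anchors = anchors, tfw = tfw, fwhm_windows = fwhm_windows,
                 mass_tol = mass_tol, mass_axis_target = mass_axis_target,
                 lambda2 = lambda2, lambda3 = lambda3, eps_i = eps_i, it = it,
                 m = as.integer(m), n_iter = as.integer(n_iter),
                 alpha = alpha, beta = beta, wmin = wmin, wmax = wmax,
                 t0 = t0, eta = eta, eps = eps,
                 offset_v = offset_v, dac_v = dac_v, source_v = source_v,
                 n_acq = as.integer(n_acq), max_outer = as.integer(max_outer),
                 penalty = penalty, ref_anchor = as.integer(ref_anchor)),
            class = "tune_config")
}

tune_annealing <- function(config) {
  annealing_config(t0 = config$t0, eta = config$eta, eps = config$eps)
}

tune_swarm <- function(config, m = config$m) {
  swarm_config(m = m, n_iter = config$n_iter, wmin = config$wmin,
               wmax = config$wmax, alpha = config$alpha, beta = config$beta)
}

#' Stage-wise tuning objective
#'
#' Stage I (calibration): `lambda2*(FW - TFW)^2 + lambda3*(MASS - TMASS)^2`,
#' to be minimised; termination when it drops to `eps_i`.  Stage II
#' (parameter optimization): the peak intensity, to be maximised;
#' termination when it reaches the pass threshold `it`.
#'
#' @param measurement A `"peak_measurement"`.
#' @param config A [tune_config()].
#' @param stage `"I"` or `"II"`.
#' @param anchor Anchor index selecting `tfw`/target mass.
#' @return The objective value (penalty value for unmeasurable peaks in
#'   stage I).
#' @export
evaluate_tune_objective <- function(measurement, config, stage = c("I", "II"),
                                    anchor = 1) {
  stage <- match.arg(stage)
  if (config$lambda2 < 0 || config$lambda3 < 0)
    stop("lambda weights must be non-negative")
  if (stage == "II") return(measurement$intensity)
  if (is.na(measurement$fwhm)) return(config$penalty)
  config$lambda2 * (measurement$fwhm - config$tfw[anchor])^2 +
    config$lambda3 * (measurement$mass - config$anchors[anchor])^2
}

try_measure <- function(truth, settings, mass, config, noise = TRUE) {
  tryCatch(measure_settings(truth, settings, mass, n_acq = config$n_acq,
                            noise = noise),
           ipsotune_no_peak = function(e) NULL)
}

# Fresh stage-I objective per anchor at the given settings.
anchor_objectives <- function(truth, settings, config, noise = TRUE) {
  vapply(seq_along(config$anchors), function(ai) {
    mm <- try_measure(truth, settings, config$anchors[ai], config, noise)
    if (is.null(mm)) config$penalty
    else evaluate_tune_objective(mm, config, "I", ai)
  }, numeric(1))
}

#' Iterative mass-axis calibration
#'
#' For each anchor, measures the peak centroid and applies the linear
#' correction `DAC(n) = DAC(n-1) + omega * (MASS_target - MASS(n))` until
#' the absolute shift falls to the internal target or the iteration cap is
#' reached; an anchor already within the target is left untouched (zero
#' corrections).  Afterwards the mass-axis line is refit over all anchors.
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings Current [control_settings()].
#' @param config A [tune_config()].
#' @param omega Slope estimate; default is a least-squares fit of the
#'   current anchor DACs against mass.
#' @param max_iter Correction cap per anchor.
#' @param noise Use the noisy forward model.
#' @return List with updated `settings`, the refit `model`
#'   (`omega`, `zeta`, `r2`), a per-anchor `iterations` count and a `trace`
#'   data frame.
#' @export
calibrate_mass_axis <- function(truth, settings, config = tune_config(),
                                omega = NULL, max_iter = config$n_iter,
                                noise = TRUE) {
  anchors <- settings$anchors
  if (is.null(omega)) {
    omega <- stats::coef(stats::lm(settings$dac ~ anchors))[[2]]
  }
  trace <- list()
  iters <- integer(length(anchors))
  for (ai in seq_along(anchors)) {
    target <- anchors[ai]
    for (k in seq_len(max_iter + 1L)) {
      mm <- try_measure(truth, settings, target, config, noise)
      if (is.null(mm)) {
        stop("mass-axis calibration aborted: no peak detected at anchor ",
             format(target), " m/z")
      }
      shift <- mm$mass - target
      trace[[length(trace) + 1L]] <-
        data.frame(anchor = target, iteration = k - 1L, mass = mm$mass,
                   shift = shift, dac = settings$dac[ai])
      if (abs(shift) <= config$mass_axis_target || k > max_iter) break
      settings$dac[ai] <- clamp(settings$dac[ai] + omega * (target - mm$mass),
                                truth$dac_box[1], truth$dac_box[2])
      iters[ai] <- iters[ai] + 1L
    }
  }
  fit <- stats::lm(settings$dac ~ anchors)
  ss_tot <- sum((settings$dac - mean(settings$dac))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  model <- list(omega = stats::coef(fit)[[2]], zeta = stats::coef(fit)[[1]],
                r2 = r2)
  list(settings = settings, model = model, iterations = iters,
       trace = do.call(rbind, trace))
}

#' Resolution (OFFSET) calibration with the improved swarm
#'
#' Optimises the OFFSET values of the selected anchors jointly with the
#' improved optimizer under the stage-I objective (summed over the selected
#' anchors), terminating once every selected anchor's own objective falls
#' to its `eps_i` threshold or at the iteration cap.  One particle is
#' warm-started at the current offsets so progress accumulates across
#' alternation passes.
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings Current [control_settings()].
#' @param config A [tune_config()].
#' @param anchors Indices of the anchors to calibrate (default: all).
#' @param warm_start Seed one particle at the current offsets.
#' @param noise Use the noisy forward model.
#' @return List with updated `settings`, `fwhm` and `objective` finals per
#'   selected anchor, `converged` flag, `iterations` and the optimizer
#'   `result`.
#' @export
calibrate_resolution <- function(truth, settings, config = tune_config(),
                                 anchors = seq_along(settings$anchors),
                                 warm_start = TRUE, noise = TRUE) {
  k <- length(anchors)
  masses <- settings$anchors[anchors]
  fit_fn <- function(X) {
    X <- as.matrix(X)
    vapply(seq_len(ncol(X)), function(ci) {
      s2 <- settings
      s2$offset[anchors] <- X[, ci]
      tot <- 0
      for (i in seq_len(k)) {
        mm <- try_measure(truth, s2, masses[i], config, noise)
        obj <- if (is.null(mm)) config$penalty
               else evaluate_tune_objective(mm, config, "I", anchors[i])
        tot <- tot + obj
      }
      -tot
    }, numeric(1))
  }
  prob <- objective_problem(fit_fn,
                            lower = rep(truth$offset_box[1], k),
                            upper = rep(truth$offset_box[2], k),
                            vlower = rep(-config$offset_v, k),
                            vupper = rep(config$offset_v, k),
                            vectorized = TRUE, name = "resolution")
  cfg <- tune_swarm(config)
  init <- matrix(stats::runif(k * cfg$m, truth$offset_box[1], truth$offset_box[2]),
                 nrow = k)
  if (warm_start) init[, 1] <- settings$offset[anchors]
  check <- function(off) {
    s2 <- settings
    s2$offset[anchors] <- off
    obj <- vapply(seq_len(k), function(i) {
      mm <- try_measure(truth, s2, masses[i], config, noise)
      if (is.null(mm)) config$penalty
      else evaluate_tune_objective(mm, config, "I", anchors[i])
    }, numeric(1))
    all(obj <= config$eps_i[anchors])
  }
  res <- run_optimizer(prob, cfg, annealing = tune_annealing(config),
                       mode = "ipso",
                       termination = function(state) check(state$gh),
                       init = init)
  settings$offset[anchors] <- res$g
  fw <- numeric(k)
  obj <- numeric(k)
  for (i in seq_len(k)) {
    mm <- try_measure(truth, settings, masses[i], config, noise)
    fw[i] <- if (is.null(mm)) NA_real_ else mm$fwhm
    obj[i] <- if (is.null(mm)) config$penalty
              else evaluate_tune_objective(mm, config, "I", anchors[i])
  }
  list(settings = settings, fwhm = fw, objective = obj,
       converged = all(obj <= config$eps_i[anchors]),
       iterations = res$iterations, result = res)
}

#' Ion-source and lens parameter optimization
#'
#' Maximises the measured peak intensity over the 4-D (CUR, GS1, DP, EP)
#' box with the improved optimizer, stopping once the intensity at the best
#' settings reaches the pass threshold `it` or at the iteration cap.
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings Current [control_settings()].
#' @param config A [tune_config()].
#' @param warm_start Seed one particle at the current source settings.
#' @param noise Use the noisy forward model.
#' @return List with updated `settings`, final `intensity`, `converged`
#'   flag, `iterations` and the optimizer `result`.
#' @export
optimize_source_params <- function(truth, settings, config = tune_config(),
                                   warm_start = TRUE, noise = TRUE) {
  ref_mass <- settings$anchors[config$ref_anchor]
  fit_fn <- function(X) {
    X <- as.matrix(X)
    vapply(seq_len(ncol(X)), function(ci) {
      s2 <- settings
      s2$source <- X[, ci]
      mm <- try_measure(truth, s2, ref_mass, config, noise)
      if (is.null(mm)) 0 else mm$intensity
    }, numeric(1))
  }
  prob <- objective_problem(fit_fn, lower = truth$source_lower,
                            upper = truth$source_upper,
                            vlower = -config$source_v, vupper = config$source_v,
                            vectorized = TRUE, name = "source")
  cfg <- tune_swarm(config)
  init <- matrix(stats::runif(4L * cfg$m, rep(truth$source_lower, cfg$m),
                              rep(truth$source_upper, cfg$m)), nrow = 4L)
  if (warm_start) init[, 1] <- settings$source
  check <- function(src) {
    s2 <- settings
    s2$source <- src
    mm <- try_measure(truth, s2, ref_mass, config, noise)
    !is.null(mm) && mm$intensity >= config$it
  }
  res <- run_optimizer(prob, cfg, annealing = tune_annealing(config),
                       mode = "ipso",
                       termination = function(state) check(state$gh),
                       init = init)
  settings$source <- res$g
  mm <- try_measure(truth, settings, ref_mass, config, noise)
  final <- if (is.null(mm)) 0 else mm$intensity
  list(settings = settings, intensity = final,
       converged = final >= config$it,
       iterations = res$iterations, result = res)
}

#' Run the full staged auto-tune
#'
#' Alternates mass-axis correction and resolution calibration until the
#' stage-I condition holds at every anchor (or the alternation cap is
#' reached), then optimises the ion-source and lens parameters until the
#' intensity pass threshold is met.  Fully reproducible given `seed`.
#'
#' @param truth An [instrument_ground_truth()].
#' @param settings Starting [control_settings()] (e.g. from
#'   [detuned_settings()]).
#' @param config A [tune_config()].
#' @param seed Optional integer seed applied before the run.
#' @param noise Use the noisy forward model.
#' @return An object of class `"tune_report"`: per-anchor finals (`fwhm`,
#'   `mass_shift`, `intensity`), pass flags against the FWHM windows, mass
#'   bound and intensity threshold, per-stage iteration counts, stage
#'   traces, the final settings, the configuration echo and the seed.
#' @export
run_autotune <- function(truth, settings, config = tune_config(), seed = NULL,
                         noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ma_iters <- list()
  res_iters <- integer(0)
  traces <- list()
  cond1 <- FALSE
  outer <- 0L
  model <- NULL
  todo <- seq_along(config$anchors)  # later passes revisit only failing anchors
  for (pass in seq_len(config$max_outer)) {
    outer <- pass
    ma <- calibrate_mass_axis(truth, settings, config, noise = noise)
    settings <- ma$settings
    model <- ma$model
    ma_iters[[pass]] <- ma$iterations
    traces[[paste0("mass_axis_pass", pass)]] <- ma$trace
    rs <- calibrate_resolution(truth, settings, config, anchors = todo,
                               noise = noise)
    settings <- rs$settings
    res_iters[pass] <- rs$iterations
    traces[[paste0("resolution_pass", pass)]] <- rs$result$records
    q <- anchor_objectives(truth, settings, config, noise = noise)
    if (all(q <= config$eps_i)) {
      cond1 <- TRUE
      break
    }
    todo <- which(q > config$eps_i)
  }
  sp <- optimize_source_params(truth, settings, config, noise = noise)
  settings <- sp$settings
  traces$source <- sp$result$records

  k <- length(config$anchors)
  fwhm <- numeric(k)
  shift <- numeric(k)
  inten <- numeric(k)
  for (ai in seq_len(k)) {
    mm <- try_measure(truth, settings, config$anchors[ai], config, noise)
    fwhm[ai] <- if (is.null(mm)) NA_real_ else mm$fwhm
    shift[ai] <- if (is.null(mm)) NA_real_ else mm$mass - config$anchors[ai]
    inten[ai] <- if (is.null(mm)) 0 else mm$intensity
  }
  pass_fwhm <- vapply(seq_len(k), function(ai) {
    !is.na(fwhm[ai]) && fwhm[ai] >= config$fwhm_windows[[ai]][1] &&
      fwhm[ai] <= config$fwhm_windows[[ai]][2]
  }, logical(1))
  pass_mass <- !is.na(shift) & abs(shift) <= config$mass_tol
  pass_int <- inten >= config$it

  structure(list(anchors = config$anchors, fwhm = fwhm, mass_shift = shift,
                 intensity = inten, pass_fwhm = pass_fwhm,
                 pass_mass = pass_mass, pass_intensity = pass_int,
                 passed = all(pass_fwhm) && all(pass_mass) && all(pass_int),
                 condition1 = cond1, condition2 = sp$converged,
                 outer_passes = outer,
                 iterations = list(mass_axis = ma_iters,
                                   resolution = res_iters,
                                   source = sp$iterations),
                 mass_axis_model = model, traces = traces,
                 settings = settings, config = config, seed = seed),
            class = "tune_report")
}

#' @export
print.tune_report <- function(x, ...) {
  cat("<tune_report> anchors:", paste(x$anchors, collapse = ", "), "m/z\n")
  df <- data.frame(anchor = x$anchors, fwhm = round(x$fwhm, 4),
                   mass_shift = round(x$mass_shift, 4),
                   intensity = signif(x$intensity, 4),
                   pass = x$pass_fwhm & x$pass_mass & x$pass_intensity)
  print(df)
  cat("  calibration condition met:", x$condition1,
      "| intensity condition met:", x$condition2, "\n")
  invisible(x)
}
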