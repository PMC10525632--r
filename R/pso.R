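#' Swarm configuration
#'
#' @param m Swarm size (number of particles).
#' @param n_iter Maximum number of iterations.
#' @param accel Acceleration coefficients.  Either a length-2 numeric range
#'   `c(lo, hi)` from which fresh `c1`, `c2` are drawn uniformly at every
#'   velocity update (the default, `c(0, 2)`), or a named list
#'   `list(c1 = , c2 = )` of fixed constants.
#' @param wmin,wmax Inertia-weight bounds.
#' @param w_fixed Constant inertia weight used by standard mode when
#'   `standard_schedule = "fixed"`.
#' @param alpha,beta Dynamic-boundary coefficients (both positive).
#' @param schedules Subset of `c("L","E","P","R")`, the inertia-weight
#'   proposals evaluated per particle in improved mode; order is the declared
#'   tie-break order.
#' @param standard_schedule Weight rule for standard mode: `"fixed"` or one
#'   of the schedule tags.
#' @param dynamic_bounds Use per-particle dynamic position boundaries in
#'   improved mode.
#' @param seed Optional integer; when given, [run_optimizer()] seeds the
#'   global RNG with it so runs are reproducible.
#' @return An object of class `"swarm_config"`.
#' @export
swarm_config <- function(m = 30, n_iter = 100, accel = c(0, 2),
                         wmin = 0.4, wmax = 0.9, w_fixed = 0.7,
                         alpha = 0.1, beta = 0.05,
                         schedules = c("L", "E", "P", "R"),
                         standard_schedule = "fixed",
                         dynamic_bounds = TRUE, seed = NULL) {
  if (m < 1 || n_iter < 1) stop("m and n_iter must be >= 1")
  if (wmin < 0 || wmin > wmax) stop("need 0 <= wmin <= wmax")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (length(schedules) == 0L || !all(schedules %in% c("L", "E", "P", "R")))
    stop("schedules must be a nonempty subset of L, E, P, R")
  if (is.list(accel)) {
    if (is.null(accel$c1) || is.null(accel$c2)) stop("fixed accel needs c1 and c2")
  } else if (length(accel) != 2L || accel[1] > accel[2]) {
    stop("accel range must be c(lo, hi) with lo <= hi")
  }
  if (!identical(standard_schedule, "fixed") &&
      !standard_schedule %in% c("L", "E", "P", "R"))
    stop("standard_schedule must be 'fixed' or one of L, E, P, R")
  structure(list(m = as.integer(m), n_iter = as.integer(n_iter), accel = accel,
                 wmin = wmin, wmax = wmax, w_fixed = w_fixed,
                 alpha = alpha, beta = beta, schedules = schedules,
                 standard_schedule = standard_schedule,
                 dynamic_bounds = isTRUE(dynamic_bounds), seed = seed),
            class = "swarm_config")
}

#' Simulated-annealing configuration
#'
#' @param t0 Initial temperature (positive).
#' @param eta Cooling factor in (0, 1); the temperature is multiplied by
#'   `eta` after every iteration, so `T(n) = t0 * eta^n`.
#' @param eps Acceptance threshold mode.  `NULL` (default) draws a fresh
#'   uniform \[0, 1\] threshold for every Metropolis test; a number in
#'   \[0, 1\] fixes it.  `eps = 0` disables escape moves entirely since
#'   `exp(-dE/T) > 0` always holds.
#' @return An object of class `"annealing_config"`.
#' @export
annealing_config <- function(t0 = 80, eta = 0.9, eps = NULL) {
  if (t0 <= 0) stop("t0 must be positive")
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  if (!is.null(eps) && (eps < 0 || eps > 1)) stop("fixed eps must lie in [0, 1]")
  structure(list(t0 = t0, eta = eta, eps = eps), class = "annealing_config")
}

draw_eps <- function(annealing) {
  if (is.null(annealing$eps)) stats::runif(1L) else annealing$eps
}

draw_accel <- function(config) {
  if (is.list(config$accel)) c(config$accel$c1, config$accel$c2)
  else stats::runif(2L, config$accel[1], config$accel[2])
}

#' Velocity update with clamping
#'
#' `v' = w*v + c1*(p - x) + c2*(g - x)`, clamped elementwise to
#' `[vlower, vupper]`.
#'
#' @param v Current velocity.
#' @param x Current position.
#' @param p Personal-best position.
#' @param g Global-best position.
#' @param w Inertia weight.
#' @param c1,c2 Acceleration coefficients.
#' @param vlower,vupper Velocity bounds.
#' @return The clamped new velocity.
#' @export
update_velocity <- function(v, x, p, g, w, c1, c2, vlower, vupper) {
  d <- length(x)
  if (length(v) != d || length(p) != d || length(g) != d)
    stop("dimension mismatch among v, x, p, g")
  clamp(w * v + c1 * (p - x) + c2 * (g - x), vlower, vupper)
}

#' Per-particle dynamic position boundaries
#'
#' Narrows the search box around the personal best: elementwise,
#' `p +/- alpha*|p - x|` where `p != x` and `p +/- beta*|p|` where `p == x`,
#' intersected with the static box `[lower, upper]`.  A degenerate zero-width
#' coordinate (p == x == 0) is widened by a positive floor so the particle
#' never freezes.
#'
#' @param p Personal-best position.
#' @param x Current position.
#' @param alpha,beta Positive narrowing coefficients.
#' @param lower,upper Static position bounds.
#' @param width_floor Minimum half-width; default `1e-6 * (upper - lower)`.
#' @return List with `lower`, `upper` (the dynamic box) and `floored`, a
#'   logical vector marking coordinates widened by the floor.
#' @export
update_dynamic_bounds <- function(p, x, alpha, beta, lower, upper,
                                  width_floor = NULL) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  gap <- abs(p - x)
  half <- ifelse(gap > 0, alpha * gap, beta * abs(p))
  if (is.null(width_floor)) width_floor <- 1e-6 * (upper - lower)
  floored <- half < width_floor
  half <- pmax(half, width_floor)
  list(lower = pmax(p - half, lower),
       upper = pmin(p + half, upper),
       floored = floored)
}

#' Metropolis acceptance test
#'
#' Accepts with probability 1 when `f_i >= f_j`, otherwise with probability
#' `exp((f_i - f_j) / temp)` — implemented as `exp((f_i - f_j)/temp) > eps`
#' where `eps` is a fresh uniform \[0, 1\] draw unless supplied.
#'
#' @param f_i Fitness of the candidate state.
#' @param f_j Fitness of the incumbent state.
#' @param temp Temperature (positive).
#' @param eps Optional fixed threshold in \[0, 1\]; `NULL` draws fresh.
#' @return Logical acceptance decision.
#' @export
metropolis_accept <- function(f_i, f_j, temp, eps = NULL) {
  if (temp <= 0) stop("temperature must be positive")
  if (f_i >= f_j) return(TRUE)
  if (is.null(eps)) eps <- stats::runif(1L)
  exp((f_i - f_j) / temp) > eps
}

#' Multi-weight position proposal
#'
#' For each inertia-weight schedule in `config$schedules` (declared order)
#' a candidate velocity and position `x + v` are computed with shared
#' acceleration draws; all candidates are evaluated and the fittest one is
#' kept (ties break to the first schedule in declared order).  The winning
#' position is then clamped to the particle's current dynamic box and
#' re-evaluated if clamping moved it.
#'
#' @param particle List with fields `x`, `v`, `p` (personal best), `lower`,
#'   `upper` (current dynamic bounds).
#' @param g Global-best position.
#' @param problem An [objective_problem()].
#' @param config A [swarm_config()].
#' @param n Current iteration (used by the weight schedules).
#' @return List with `x`, `v`, `f` (fitness of the clamped position),
#'   `schedule` (winning tag), `c1`, `c2` and `n_evals`.
#' @export
propose_and_select_position <- function(particle, g, problem, config, n) {
  sch <- config$schedules
  k <- length(sch)
  cc <- draw_accel(config)
  d <- problem$dim
  cand_v <- matrix(0, d, k)
  cand_x <- matrix(0, d, k)
  for (i in seq_len(k)) {
    w <- compute_inertia_weight(sch[i], n, config$n_iter, config$wmin, config$wmax)
    cand_v[, i] <- update_velocity(particle$v, particle$x, particle$p, g,
                                   w, cc[1], cc[2],
                                   problem$vlower, problem$vupper)
    cand_x[, i] <- particle$x + cand_v[, i]
  }
  cand_f <- eval_objective(problem, cand_x)
  best <- which.max(cand_f)  # first maximum wins ties, i.e. declared order
  x_new <- clamp(cand_x[, best], particle$lower, particle$upper)
  n_evals <- k
  if (all(x_new == cand_x[, best])) {
    f_new <- cand_f[best]
  } else {
    f_new <- eval_objective(problem, x_new)
    n_evals <- n_evals + 1L
  }
  list(x = x_new, v = cand_v[, best], f = f_new, schedule = sch[best],
       c1 = cc[1], c2 = cc[2], n_evals = n_evals)
}

#' Simulated-annealing update of personal and global bests
#'
#' Applies the annealed best-update: with `dE = f(g) - max_j f(x_j_new)`,
#' the reported global best follows the all-time history argmax when
#' `exp(-dE/T) > eps`, and is otherwise replaced by the current-iteration
#' best even if worse (an escape move).  Personal bests are updated
#' analogously with `dE_j = f(p_j) - f(x_j_new)`, each with its own
#' threshold draw.  Afterwards the temperature is cooled, `T <- eta * T`.
#'
#' Threshold draws consume the RNG in a fixed order: one global draw, then
#' one per particle in index order (no draws when `eps` is fixed).
#'
#' @param state Swarm state list with fields `P`, `fP` (reported personal
#'   bests), `Ph`, `fPh` (all-time personal bests), `g`, `f_g` (reported
#'   global best), `gh`, `f_gh` (all-time global best), `temp` and `n`.
#' @param new_x `D x M` matrix of the new positions.
#' @param new_f Length-`M` fitness vector of `new_x`.
#' @param annealing An [annealing_config()].
#' @return The updated state; element `record` holds `delta_E`,
#'   `accepted_escape` and the temperature at which the test ran.
#' @export
sa_update_bests <- function(state, new_x, new_f, annealing) {
  m <- length(new_f)
  if (m == 0L) stop("invalid state: empty swarm")
  temp <- state$temp
  # refresh all-time history with the new evaluations
  imp <- new_f > state$fPh
  state$Ph[, imp] <- new_x[, imp]
  state$fPh[imp] <- new_f[imp]
  jbest <- which.max(new_f)
  if (new_f[jbest] > state$f_gh) {
    state$gh <- new_x[, jbest]
    state$f_gh <- new_f[jbest]
  }
  d_e <- state$f_g - new_f[jbest]
  eps_g <- draw_eps(annealing)
  # log-space comparison: exp(-dE/T) > eps without underflow, so a fixed
  # eps of 0 really disables escape moves (exp(.) > 0 mathematically)
  escape <- !(-d_e / temp > log(eps_g))
  if (escape) {
    state$g <- new_x[, jbest]
    state$f_g <- new_f[jbest]
  } else {
    state$g <- state$gh
    state$f_g <- state$f_gh
  }
  for (j in seq_len(m)) {
    d_ej <- state$fP[j] - new_f[j]
    eps_j <- draw_eps(annealing)
    if (-d_ej / temp > log(eps_j)) {
      state$P[, j] <- state$Ph[, j]
      state$fP[j] <- state$fPh[j]
    } else {
      state$P[, j] <- new_x[, j]
      state$fP[j] <- new_f[j]
    }
  }
  state$temp <- annealing$eta * temp
  state$record <- list(delta_E = d_e, accepted_escape = escape, temperature = temp)
  state
}

greedy_update_bests <- function(state, new_x, new_f) {
  m <- length(new_f)
  imp <- new_f > state$fPh
  state$Ph[, imp] <- new_x[, imp]
  state$fPh[imp] <- new_f[imp]
  jbest <- which.max(new_f)
  d_e <- state$f_g - new_f[jbest]
  if (new_f[jbest] > state$f_gh) {
    state$gh <- new_x[, jbest]
    state$f_gh <- new_f[jbest]
  }
  state$P <- state$Ph
  state$fP <- state$fPh
  state$g <- state$gh
  state$f_g <- state$f_gh
  state$record <- list(delta_E = d_e, accepted_escape = FALSE,
                       temperature = state$temp)
  state
}

#' Run the particle swarm optimizer
#'
#' `mode = "standard"` is canonical PSO: a single inertia weight
#' (`standard_schedule`), static position bounds and greedy best updates.
#' `mode = "ipso"` is the improved optimizer: per-particle dynamic position
#' boundaries, multi-weight proposals with best-candidate selection, and
#' simulated-annealing acceptance of the reported bests.
#'
#' All randomness comes from the global RNG, seeded from `config$seed` when
#' set.  Draw order per iteration: for each particle, `c1`, `c2` (random
#' acceleration mode), then the random-schedule weight if `"R"` is active;
#' after evaluation, the annealing threshold draws (global, then per
#' particle).  Initial positions consume `D * M` uniforms, particle-major;
#' initial velocities are zero.
#'
#' @param problem An [objective_problem()] (fitness is maximised).
#' @param config A [swarm_config()].
#' @param annealing An [annealing_config()], required for `"ipso"`.
#' @param mode `"ipso"` or `"standard"`.
#' @param termination Optional predicate `function(state)`; checked after
#'   initial evaluation and after every iteration.  The state exposes `g`,
#'   `f_g`, `gh`, `f_gh`, `n`, `temp`, `X`, `P`, `fP`.
#' @param init Optional `D x M` matrix of starting positions (e.g. warm
#'   starts); skips the initial uniform draws.
#' @param keep_history Store per-iteration positions, velocities and dynamic
#'   bounds (for diagnostics/tests).
#' @return An object of class `"optimization_result"`: `g`, `f_g` (the
#'   all-time best and its fitness), `g_reported`, `f_g_reported` (the
#'   possibly escaped reported best), `records` (one row per iteration:
#'   `n`, `f_g`, `f_best`, `delta_E`, `accepted_escape`, `temperature`),
#'   `schedules` (winning schedule per particle and iteration), `n_evals`,
#'   `iterations`, and optional `history`.
#' @export
run_optimizer <- function(problem, config, annealing = NULL,
                          mode = c("ipso", "standard"),
                          termination = NULL, init = NULL,
                          keep_history = FALSE) {
  mode <- match.arg(mode)
  if (mode == "ipso" && is.null(annealing)) annealing <- annealing_config()
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- problem$dim
  m <- config$m
  n_max <- config$n_iter
  lower <- problem$lower
  upper <- problem$upper

  if (is.null(init)) {
    X <- matrix(stats::runif(d * m, rep(lower, m), rep(upper, m)), nrow = d)
  } else {
    X <- as.matrix(init)
    if (nrow(X) != d || ncol(X) != m) stop("init must be a D x M matrix")
  }
  V <- matrix(0, d, m)
  f <- eval_objective(problem, X)
  n_evals <- m
  state <- list(X = X, P = X, fP = f, Ph = X, fPh = f, n = 0L,
                temp = if (!is.null(annealing)) annealing$t0 else NA_real_)
  gi <- which.max(f)
  state$g <- X[, gi]; state$f_g <- f[gi]
  state$gh <- state$g; state$f_gh <- state$f_g

  blo <- matrix(rep(lower, m), d)
  bhi <- matrix(rep(upper, m), d)
  rec <- data.frame(n = integer(n_max), f_g = numeric(n_max),
                    f_best = numeric(n_max), delta_E = numeric(n_max),
                    accepted_escape = logical(n_max),
                    temperature = numeric(n_max))
  sched <- matrix(NA_character_, m, n_max)
  history <- if (keep_history) vector("list", n_max) else NULL
  n_done <- 0L

  stopped <- !is.null(termination) && isTRUE(termination(state))
  if (!stopped) for (n in seq_len(n_max)) {
    if (mode == "ipso" && config$dynamic_bounds) {
      for (j in seq_len(m)) {
        b <- update_dynamic_bounds(state$P[, j], state$X[, j],
                                   config$alpha, config$beta, lower, upper)
        blo[, j] <- b$lower
        bhi[, j] <- b$upper
      }
    }
    new_x <- matrix(0, d, m)
    new_f <- numeric(m)
    for (j in seq_len(m)) {
      if (mode == "ipso") {
        part <- list(x = state$X[, j], v = V[, j], p = state$P[, j],
                     lower = blo[, j], upper = bhi[, j])
        pr <- propose_and_select_position(part, state$g, problem, config, n)
        new_x[, j] <- pr$x
        new_f[j] <- pr$f
        V[, j] <- pr$v
        sched[j, n] <- pr$schedule
        n_evals <- n_evals + pr$n_evals
      } else {
        cc <- draw_accel(config)
        w <- if (identical(config$standard_schedule, "fixed")) config$w_fixed
             else compute_inertia_weight(config$standard_schedule, n, n_max,
                                         config$wmin, config$wmax)
        v <- update_velocity(V[, j], state$X[, j], state$P[, j], state$g,
                             w, cc[1], cc[2], problem$vlower, problem$vupper)
        x2 <- clamp(state$X[, j] + v, lower, upper)
        new_x[, j] <- x2
        new_f[j] <- eval_objective(problem, x2)
        V[, j] <- v
        n_evals <- n_evals + 1L
      }
    }
    state$X <- new_x
    state <- if (mode == "ipso") sa_update_bests(state, new_x, new_f, annealing)
             else greedy_update_bests(state, new_x, new_f)
    state$n <- n
    rec$n[n] <- n
    rec$f_g[n] <- state$f_g
    rec$f_best[n] <- state$f_gh
    rec$delta_E[n] <- state$record$delta_E
    rec$accepted_escape[n] <- state$record$accepted_escape
    rec$temperature[n] <- state$record$temperature
    if (keep_history) {
      history[[n]] <- list(X = new_x, V = V, f = new_f,
                           bounds_lower = blo, bounds_upper = bhi)
    }
    n_done <- n
    if (!is.null(termination) && isTRUE(termination(state))) break
  }
  rec <- rec[seq_len(n_done), , drop = FALSE]
  structure(list(g = state$gh, f_g = state$f_gh,
                 g_reported = state$g, f_g_reported = state$f_g,
                 records = rec,
                 schedules = sched[, seq_len(n_done), drop = FALSE],
                 n_evals = n_evals, iterations = n_done,
                 mode = mode, problem = problem$name,
                 history = if (keep_history) history[seq_len(n_done)]),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>", x$mode, "on", x$problem, "\n")
  cat("  iterations:", x$iterations, " evaluations:", x$n_evals, "\n")
  cat("  best fitness:", format(x$f_g), "\n")
  cat("  best position:", paste(signif(x$g, 6), collapse = ", "), "\n")
  invisible(x)
}
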