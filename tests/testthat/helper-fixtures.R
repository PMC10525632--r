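# Shared fixtures: small analytic problems and a fast instrument model.

# Concave quadratic with known maximum at `centre` (fitness 0 there).
quad_problem <- function(centre = c(2, -1), lower = -5, upper = 5) {
  d <- length(centre)
  objective_problem(function(X) -colSums((X - centre)^2),
                    lower = lower, upper = upper, dim = d,
                    vectorized = TRUE, name = "quadratic")
}

# Default synthetic instrument; noise parameters can be overridden.
test_truth <- function(...) instrument_ground_truth(...)

# Settings at truth except for the fields explicitly replaced.
settings_at_truth <- function(truth, offset = NULL, dac = NULL, source = NULL) {
  st <- true_settings(truth)
  if (!is.null(offset)) st$offset <- offset
  if (!is.null(dac)) st$dac <- dac
  if (!is.null(source)) st$source <- source
  st
}

# A fresh single-particle swarm state around position x with fitness f.
one_particle_state <- function(x, f, t0 = 80) {
  x <- matrix(x)
  list(X = x, P = x, fP = f, Ph = x, fPh = f,
       g = x[, 1], f_g = f, gh = x[, 1], f_gh = f,
       n = 0L, temp = t0)
}
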