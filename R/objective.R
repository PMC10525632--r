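#' Define a bounded maximisation problem
#'
#' The optimizer maximises fitness by internal convention; wrap a
#' minimisation objective as `function(x) -obj(x)`.
#'
#' @param fn Objective function.  If `vectorized = TRUE` it must accept a
#'   `D x k` matrix of column candidates and return a length-`k` numeric
#'   vector; otherwise it takes a single numeric vector of length `D`.
#' @param lower,upper Position bounds, numeric vectors of length `D`
#'   (scalars are recycled when `dim` is given).
#' @param vlower,vupper Velocity bounds.  Default is +/- 20% of the position
#'   range per coordinate.
#' @param dim Problem dimension; inferred from `lower` when omitted.
#' @param vectorized Whether `fn` is column-vectorized (see above).
#' @param name Optional label carried into results.
#' @return An object of class `"objective_problem"`.
#' @examples
#' p <- objective_problem(function(x) -sum(x^2), lower = -5, upper = 5, dim = 2)
#' eval_objective(p, c(1, 1))
#' @export
objective_problem <- function(fn, lower, upper, vlower = NULL, vupper = NULL,
                              dim = NULL, vectorized = FALSE, name = "objective") {
  stopifnot(is.function(fn))
  if (is.null(dim)) dim <- max(length(lower), length(upper))
  if (dim < 1) stop("dimension must be >= 1")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("position bounds must be finite with lower < upper elementwise")
  if (is.null(vlower)) vlower <- -0.2 * (upper - lower)
  if (is.null(vupper)) vupper <- 0.2 * (upper - lower)
  vlower <- rep_len(as.numeric(vlower), dim)
  vupper <- rep_len(as.numeric(vupper), dim)
  if (any(vlower >= vupper)) stop("velocity bounds must satisfy vlower < vupper elementwise")
  structure(list(dim = dim, fn = fn, lower = lower, upper = upper,
                 vlower = vlower, vupper = vupper,
                 vectorized = isTRUE(vectorized), name = name),
            class = "objective_problem")
}

#' Evaluate an objective problem at one or more positions
#'
#' @param problem An [objective_problem()].
#' @param x Numeric vector of length `D`, or a `D x k` matrix of column
#'   candidates.
#' @return Numeric vector of fitness values, one per candidate.
#' @export
eval_objective <- function(problem, x) {
  x <- as.matrix(x)
  if (nrow(x) != problem$dim) {
    if (ncol(x) == problem$dim && nrow(x) == 1L) x <- t(x)
    else stop("dimension mismatch: expected ", problem$dim, " rows, got ", nrow(x))
  }
  if (problem$vectorized) {
    out <- problem$fn(x)
  } else {
    out <- apply(x, 2L, problem$fn)
  }
  as.numeric(out)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.objective_problem <- function(x, ...) {
  cat("<objective_problem>", x$name, " dim =", x$dim, "\n")
  cat("  position box: [", paste(signif(x$lower, 4), collapse = ", "), "] .. [",
      paste(signif(x$upper, 4), collapse = ", "), "]\n")
  invisible(x)
}
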