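#' Inertia-weight schedules
#'
#' Computes the inertia weight `w(n)` for one of the four schedules used by
#' the improved optimizer:
#' \describe{
#'   \item{L (linear)}{`wmax - (n/N) * (wmax - wmin)`}
#'   \item{E (exponential)}{`wmax * exp(-n/N)`}
#'   \item{P (power)}{`wmax - (wmax - wmin) * (n/N)^2`}
#'   \item{R (random)}{a fresh uniform draw in `[wmin, wmax]`}
#' }
#' The `R` schedule consumes one draw from the R random-number stream.
#'
#' @param schedule One of `"L"`, `"E"`, `"P"`, `"R"`.
#' @param n Current iteration, `0 <= n <= n_max`.
#' @param n_max Maximum number of iterations (positive).
#' @param wmin,wmax Weight bounds, `wmin <= wmax`.
#' @return A single inertia weight.
#' @examples
#' compute_inertia_weight("L", 0, 100, 0.4, 0.9)   # wmax
#' compute_inertia_weight("E", 100, 100, 0.4, 0.9) # 0.9 * exp(-1)
#' @export
compute_inertia_weight <- function(schedule, n, n_max, wmin, wmax) {
  if (!is.character(schedule) || length(schedule) != 1L ||
      !schedule %in% c("L", "E", "P", "R"))
    stop("unknown inertia-weight schedule: ", paste(schedule, collapse = ","))
  if (n < 0 || n > n_max) stop("iteration n must satisfy 0 <= n <= n_max")
  if (wmin > wmax) stop("wmin must not exceed wmax")
  switch(schedule,
         L = wmax - (n / n_max) * (wmax - wmin),
         E = wmax * exp(-n / n_max),
         P = wmax - (wmax - wmin) * (n / n_max)^2,
         R = stats::runif(1L, wmin, wmax))
}
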