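#' Write / read an iteration trace as CSV
#'
#' The trace schema is the five columns
#' `n, f_g, delta_E, accepted_escape, temperature`.
#'
#' @param records Iteration records (the `records` element of an
#'   [run_optimizer()] result); must be nonempty.
#' @param path File path.
#' @return `write_iteration_trace` returns `path` invisibly;
#'   `read_iteration_trace` returns the records data frame.
#' @export
write_iteration_trace <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot write an empty iteration trace")
  out <- records[, c("n", "f_g", "delta_E", "accepted_escape", "temperature")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iteration_trace
#' @export
read_iteration_trace <- function(path) {
  want <- c("n", "f_g", "delta_E", "accepted_escape", "temperature")
  head <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (!identical(names(head), want))
    stop("malformed iteration trace at line 1: expected header ",
         paste(want, collapse = ", "))
  df <- utils::read.csv(path)
  bad <- which(!vapply(df[c("n", "f_g", "delta_E", "temperature")],
                       is.numeric, logical(1)))
  if (length(bad))
    stop("malformed iteration trace: non-numeric column starting at line 2")
  df$accepted_escape <- as.logical(df$accepted_escape)
  df$n <- as.integer(df$n)
  df
}

#' Write / read a tune report as JSON
#'
#' Serialises per-anchor finals, pass flags, stage iteration counts, stage
#' traces, the final settings, the configuration echo and the seed.
#'
#' @param report A `"tune_report"` from [run_autotune()].
#' @param path File path.
#' @return `write_tune_report` returns `path` invisibly;
#'   `read_tune_report` returns a `"tune_report"`.
#' @export
write_tune_report <- function(report, path) {
  x <- unclass(report)
  x$config <- unclass(x$config)
  x$settings <- unclass(x$settings)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_tune_report
#' @export
read_tune_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.matrix(x$config$fwhm_windows)) {
    x$config$fwhm_windows <- lapply(seq_len(nrow(x$config$fwhm_windows)),
                                    function(i) x$config$fwhm_windows[i, ])
  }
  x$config <- do.call(tune_config, x$config[setdiff(names(x$config), "eps_i")])
  x$settings <- do.call(control_settings, x$settings)
  structure(x, class = "tune_report")
}

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[substring(key, 3L)]] <- TRUE
      i <- i + 1L
    } else {
      out[[substring(key, 3L)]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop("missing required option --", key)
    default
  } else as.numeric(opts[[key]])
}

cli_usage <- function() {
  paste("usage: ipsotune <benchmark|tune|simulate> [options]",
        "  benchmark --func F1..F8 --dim D --pop M --iters N --runs K --seed S",
        "            [--algo pso|ipso|both] [--out DIR]",
        "  tune      --config FILE --seed S [--repeats K] [--out DIR]",
        "  simulate  --seed S [--out DIR]",
        "  any mode: --show-defaults prints the default configuration",
        sep = "\n")
}

tune_defaults_yaml <- function() {
  yaml::as.yaml(list(instrument = unclass(instrument_ground_truth()),
                     tune = unclass(tune_config())))
}

#' Command-line entry point
#'
#' Dispatches the `benchmark`, `tune` and `simulate` subcommands used by the
#' `inst/scripts/ipsotune` wrapper.  All artifacts (CSV traces, JSON
#' reports, spectra) are written under `--out` (default `"."`); runs are
#' fully reproducible from the emitted configuration echo plus `--seed`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Invisibly, the paths of the written artifacts.  Errors are
#'   signalled for unknown subcommands or missing inputs (the shell wrapper
#'   converts them to a nonzero exit status).
#' @export
run_cli <- function(argv) {
  if (length(argv) == 0L) stop("no subcommand given\n", cli_usage())
  cmd <- argv[1L]
  opts <- cli_args(argv[-1L])
  if (isTRUE(opts[["show-defaults"]])) {
    cat(tune_defaults_yaml())
    return(invisible(character(0)))
  }
  out_dir <- if (is.null(opts$out)) "." else opts$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  switch(cmd,
    benchmark = cli_benchmark(opts, out_dir),
    tune = cli_tune(opts, out_dir),
    simulate = cli_simulate(opts, out_dir),
    stop("unknown subcommand: ", cmd, "\n", cli_usage()))
}

cli_benchmark <- function(opts, out_dir) {
  func <- if (is.null(opts$func)) "F1" else opts$func
  if (!func %in% names(bench_f_star)) stop("unknown function id: ", func)
  d <- cli_num(opts, "dim", 10)
  pop <- cli_num(opts, "pop", 100)
  iters <- cli_num(opts, "iters", 300)
  runs <- cli_num(opts, "runs", 10)
  seed <- as.integer(cli_num(opts, "seed"))
  algo <- if (is.null(opts$algo)) "both" else opts$algo
  algos <- switch(algo, pso = "standard", ipso = "ipso",
                  both = c("standard", "ipso"),
                  stop("unknown algorithm: ", algo))
  prob <- make_problem(func, d, seed)
  rep <- compare_algorithms(list(prob), algorithms = algos, runs = runs,
                            budget = iters, pop = pop, base_seed = seed)
  paths <- file.path(out_dir, c("benchmark_results.csv", "benchmark_summary.csv",
                                "benchmark_traces.csv"))
  utils::write.csv(rep$results, paths[1], row.names = FALSE)
  utils::write.csv(rep$summary, paths[2], row.names = FALSE)
  tr <- do.call(rbind, lapply(names(rep$traces), function(k) {
    data.frame(cell = k, n = seq_along(rep$traces[[k]]),
               best_value = rep$traces[[k]])
  }))
  utils::write.csv(tr, paths[3], row.names = FALSE)
  invisible(paths)
}

cli_tune <- function(opts, out_dir) {
  seed <- as.integer(cli_num(opts, "seed"))
  repeats <- as.integer(cli_num(opts, "repeats", 1))
  conf <- list()
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) stop("config file not found: ", opts$config)
    conf <- yaml::read_yaml(opts$config)
  }
  truth <- do.call(instrument_ground_truth,
                   if (is.null(conf$instrument)) list() else conf$instrument)
  cfg <- do.call(tune_config, if (is.null(conf$tune)) list() else conf$tune)
  set.seed(seed)
  start <- detuned_settings(truth)
  paths <- character(0)
  for (r in seq_len(repeats)) {
    report <- run_autotune(truth, start, cfg, seed = seed + r)
    p <- file.path(out_dir, sprintf("tune_report_%d.json", r))
    write_tune_report(report, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

cli_simulate <- function(opts, out_dir) {
  seed <- as.integer(cli_num(opts, "seed"))
  set.seed(seed)
  truth <- instrument_ground_truth()
  settings <- detuned_settings(truth)
  paths <- file.path(out_dir, "ground_truth.json")
  write_ground_truth(truth, paths)
  for (mass in truth$anchors) {
    sp <- acquire_spectrum(truth, settings, mass)
    p <- file.path(out_dir, sprintf("spectrum_%.2f.csv", mass))
    write_spectrum(sp, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
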