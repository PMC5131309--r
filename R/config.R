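# Hierarchical text configuration (JSON) and the command-line entry
# point.

#' Write a scenario configuration to a hierarchical text file
#'
#' @param config a [scenario_config()].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$inlet <- as.list(cfg$inlet)   # keep species names in the JSON object
  jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a scenario configuration
#'
#' @param path a file written by [write_config()] (or hand-authored in
#'   the same structure).
#' @return A [scenario_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(scenario_config)))]
  if (!is.null(args$inlet)) args$inlet <- unlist(args$inlet)
  for (nm in c("kinetics", "transport", "flow", "geometry"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.list(args[[nm]])
  do.call(scenario_config, args)
}

#' Command-line interface
#'
#' Subcommands: `run <config.json>` (run one scenario),
#' `scenario <kind> <config.json>` (derive a variant -- or three, for
#' `flow_sweep` -- and run it), `postprocess <results-dir>` (print
#' summary metrics from a written `series.csv`).  An optional final
#' argument overrides the output directory.
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return Exit status, invisibly.
#' @export
hemoclot_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: hemoclot run <config.json> [outdir]",
                 "       hemoclot scenario <kind> <config.json> [outdir]",
                 "       hemoclot postprocess <results-dir>", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  run_one <- function(cfg, outdir) {
    if (!is.null(outdir)) cfg$outdir <- outdir
    res <- run_simulation(cfg, verbose = TRUE)
    print(res)
    res
  }
  if (cmd == "run" && length(args) >= 2L) {
    cfg <- read_config(args[[2L]])
    run_one(cfg, if (length(args) >= 3L) args[[3L]] else NULL)
  } else if (cmd == "scenario" && length(args) >= 3L) {
    base <- read_config(args[[3L]])
    out <- make_scenario(args[[2L]], base)
    outdir <- if (length(args) >= 4L) args[[4L]] else NULL
    if (inherits(out, "scenario_config")) {
      run_one(out, outdir)
    } else {
      for (nm in names(out))
        run_one(out[[nm]],
                if (is.null(outdir)) NULL else file.path(outdir, nm))
    }
  } else if (cmd == "postprocess" && length(args) >= 2L) {
    f <- file.path(args[[2L]], "series.csv")
    if (!file.exists(f)) stop("no series.csv under ", args[[2L]])
    s <- utils::read.csv(f)
    n <- nrow(s)
    cat(sprintf("final reported time: %g s\n", s$time_reported[n]))
    cat(sprintf("final deposit: %.5g PLT per m depth (%.4f%% volume)\n",
                s$deposit_total[n], s$percent_volume[n]))
    cat(sprintf("worst ledger residual: %.3e\n",
                max(abs(s$ledger_residual))))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
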