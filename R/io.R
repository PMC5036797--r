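# Run manifests and the command-line surface.

#' Hash a parameter table
#'
#' MD5 of the canonical `key = value` serialisation; used in run manifests
#' so outputs can be traced to the exact table that produced them.
#'
#' @param params A `copd_params` table.
#' @return Hex digest string.
#' @export
param_hash <- function(params) {
  params <- as_copd_params(params)
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(paste0(names(params), "=",
                    formatC(unclass(params), format = "g", digits = 17)), tmp)
  unname(tools::md5sum(tmp))
}

#' Build a run manifest
#'
#' A manifest records everything needed to re-run a deterministic
#' experiment bit-identically: parameter hash, protocol, experiment kind,
#' seed, solver settings, package version and a timestamp.
#'
#' @param experiment Experiment kind (string).
#' @param params A `copd_params` table.
#' @param protocol Optional [smoking_protocol()].
#' @param seed Optional integer seed.
#' @param solver Optional list of solver settings.
#' @param extra Optional named list merged into the manifest.
#' @return A named list.
#' @export
run_manifest <- function(experiment, params, protocol = NULL, seed = NULL,
                         solver = NULL, extra = NULL) {
  m <- list(
    experiment = experiment,
    params_hash = param_hash(params),
    protocol = if (!is.null(protocol)) format(protocol),
    seed = seed,
    solver = solver,
    package_version = as.character(utils::packageVersion("copdnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  c(m[!vapply(m, is.null, TRUE)], extra)
}

cli_usage <- function() {
  paste(
    "usage: copdnet <subcommand> [--params FILE] [--out DIR] [--seed INT] ...",
    "",
    "subcommands:",
    "  simulate            --S <num> --t-end <days> [--cessation-day <day>]",
    "  cessation-sweep     --S <num> --days <d1,d2,...> [--t-end <days>]",
    "  susceptibility-sweep --param <key> --values <v1,v2,...> [--S <num>]",
    "  knockout-screen     [--S <num>]",
    "  loop-screen         [--S <num>]",
    "  sensitivity         --n <count> --seed <int> [--S <num>]",
    "  make-cohort         --n <count> --seed <int>",
    "",
    "Without --params the packaged synthetic reference table is used.",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) {
    if (is.null(default)) stop("missing required flag --", key, call. = FALSE)
    return(default)
  }
  as.numeric(flags[[key]])
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/copdnet` script: runs one named
#' experiment with the packaged reference table (or a `--params` file),
#' writes CSV outputs plus a JSON run manifest into `--out`, and returns an
#' exit code. Deterministic subcommands are bit-reproducible given
#' `--seed`.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, 0 on success.
#' @export
run_cli <- function(args) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(if (length(args) == 0) 1L else 0L)
  }
  sub <- args[1]
  flags <- tryCatch(parse_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags)); cat(cli_usage(), "\n"); return(1L)
  }
  out_dir <- if (is.null(flags$out)) "." else flags$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (is.null(flags$params)) reference_params() else
    load_params(flags$params)
  seed <- if (is.null(flags$seed)) NULL else as.integer(flags$seed)

  res <- tryCatch(switch(sub,
    "simulate" = {
      S <- flag_num(flags, "S")
      t_end <- flag_num(flags, "t-end", 4000)
      cess <- flag_num(flags, "cessation-day", NA)
      protocol <- if (is.na(cess)) constant_smoking(S, t_end) else
        cessation_protocol(S, cess, t_end)
      sim <- simulate_copd(params, protocol)
      write_simulation(sim, file.path(out_dir, "trajectory.csv"))
      list(manifest = run_manifest("simulate", params, protocol, seed,
                                   sim$diagnostics))
    },
    "cessation-sweep" = {
      S <- flag_num(flags, "S", 1.67)
      t_end <- flag_num(flags, "t-end", 6000)
      days <- as.numeric(strsplit(flags$days, ",")[[1]])
      rows <- lapply(days, function(d) {
        td <- final_state(run_cessation(params, S, d, t_end, dt_out = 5))[["TD"]]
        data.frame(cessation_day = d, TD = td, TD_pct = td_percent(td),
                   copd = classify_copd(td))
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(out_dir, "cessation_sweep.csv"),
                       row.names = FALSE)
      list(manifest = run_manifest("cessation-sweep", params, seed = seed,
                                   extra = list(S = S, days = days)))
    },
    "susceptibility-sweep" = {
      key <- flags$param
      if (is.null(key)) stop("missing required flag --param", call. = FALSE)
      vals <- as.numeric(strsplit(flags$values, ",")[[1]])
      S <- flag_num(flags, "S", 1.67)
      p <- set_param(params, d_TD = flag_num(flags, "d-TD", 3.4e-3))
      rows <- lapply(vals, function(v) {
        cls <- classify_smoker(set_param(p, stats::setNames(v, key)), S)
        data.frame(value = v, class = cls$label,
                   TD_smoking_pct = td_percent(cls$td_smoking),
                   TD_post_cessation_pct = td_percent(cls$td_post_cessation))
      })
      tab <- do.call(rbind, rows)
      tab <- cbind(parameter = key, tab)
      utils::write.csv(tab, file.path(out_dir, "susceptibility_sweep.csv"),
                       row.names = FALSE)
      list(manifest = run_manifest("susceptibility-sweep", p, seed = seed,
                                   extra = list(parameter = key, values = vals)))
    },
    "knockout-screen" = {
      tab <- knockout_screen(params, S = flag_num(flags, "S", 1.67))
      utils::write.csv(tab, file.path(out_dir, "knockout_screen.csv"),
                       row.names = FALSE)
      list(manifest = run_manifest("knockout-screen", params, seed = seed))
    },
    "loop-screen" = {
      tab <- loop_screen(params, S = flag_num(flags, "S", 1.67))
      utils::write.csv(tab, file.path(out_dir, "loop_screen.csv"),
                       row.names = FALSE)
      list(manifest = run_manifest("loop-screen", params, seed = seed))
    },
    "sensitivity" = {
      if (is.null(seed)) stop("sensitivity requires --seed", call. = FALSE)
      n <- as.integer(flag_num(flags, "n", 2000))
      res <- run_sensitivity(params, S = flag_num(flags, "S", 1.67),
                             n = n, seed = seed, progress = TRUE)
      utils::write.csv(as.data.frame(res), file.path(out_dir, "prcc.csv"),
                       row.names = FALSE)
      list(manifest = run_manifest("sensitivity", params, seed = seed,
                                   extra = list(n = n)))
    },
    "make-cohort" = {
      if (is.null(seed)) stop("make-cohort requires --seed", call. = FALSE)
      n <- as.integer(flag_num(flags, "n", 20))
      cohort <- generate_cohort(cohort_spec(n, seed = seed), baseline = params)
      write_cohort(cohort, out_dir)
      list(manifest = run_manifest("make-cohort", params, seed = seed,
                                   extra = list(n = n)))
    },
    {
      message("unknown subcommand: ", sub); cat(cli_usage(), "\n")
      return(1L)
    }), error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(1L)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  0L
}
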