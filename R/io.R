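#' Run configuration
#'
#' Bundles everything one simulation needs: parameters, hypothesis/drug
#' selectors, schedule, initial condition, horizon and solver controls. The
#' `seed` field is reserved for forward compatibility; the model is
#' deterministic.
#'
#' @param params A [pacc_params()] object.
#' @param mode A [hypothesis_mode()] object.
#' @param schedule A [therapy_schedule()].
#' @param ic Initial condition (see [integrate_piecewise()]); `NULL` for the
#'   mode default.
#' @param t_end Horizon.
#' @param solver_opts Named list of numerical controls.
#' @param seed Integer, recorded but unused.
#' @return An object of class `pacc_config`.
#' @examples
#' cfg <- run_config(mode = hypothesis_mode("single_state"),
#'                   schedule = continuous_chemo(0))
#' @export
run_config <- function(params = pacc_params(),
                       mode = hypothesis_mode("evolutionary_triage"),
                       schedule = continuous_chemo(1),
                       ic = NULL, t_end = 1000, solver_opts = list(),
                       seed = 0L) {
  stopifnot(inherits(params, "pacc_params"), inherits(mode, "pacc_mode"),
            inherits(schedule, "therapy_schedule"))
  structure(list(params = params, mode = mode, schedule = schedule,
                 ic = ic, t_end = t_end, solver_opts = solver_opts,
                 seed = as.integer(seed)),
            class = "pacc_config")
}

config_fields <- c("params", "mode", "schedule", "ic", "t_end",
                   "solver_opts", "seed")

#' Write a run configuration to a YAML file
#'
#' @param config A [run_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_run_config()]
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "pacc_config"))
  lst <- list(params = unclass(config$params),
              mode = unclass(config$mode),
              schedule = schedule_to_spec(config$schedule),
              ic = if (is.null(config$ic)) NULL else as.numeric(config$ic),
              t_end = config$t_end,
              solver_opts = config$solver_opts,
              seed = config$seed)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Unknown top-level keys are rejected; every value is revalidated through
#' the corresponding constructor, so a round trip through
#' [write_run_config()] reproduces the configuration exactly.
#'
#' @param path YAML file written by [write_run_config()] (or by hand with
#'   the same keys).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  unknown <- setdiff(names(lst), config_fields)
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(pacc_params, lst$params %||% list())
  mode <- do.call(hypothesis_mode, lst$mode %||% list())
  schedule <- if (is.null(lst$schedule)) therapy_schedule()
              else spec_to_schedule(lst$schedule)
  run_config(params = params, mode = mode, schedule = schedule,
             ic = if (is.null(lst$ic)) NULL else as.numeric(lst$ic),
             t_end = lst$t_end %||% 1000,
             solver_opts = lst$solver_opts %||% list(),
             seed = lst$seed %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a over the YAML rendering; stamps outputs with a config digest.
config_digest <- function(config) {
  txt <- yaml::as.yaml(list(params = unclass(config$params),
                            mode = unclass(config$mode),
                            schedule = schedule_to_spec(config$schedule),
                            ic = config$ic, t_end = config$t_end,
                            solver_opts = config$solver_opts),
                       precision = 15L)
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h %% 2^31, b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run one configured scenario and write its trajectory
#'
#' Executes the configuration and, when `out` is given, writes the time
#' series as CSV with columns `t, x1, x2, v, m, n, kill_rate, k_eff, rho`
#' and a one-line header comment carrying the configuration digest.
#'
#' @param config A [run_config()] object.
#' @param out Optional CSV path.
#' @return The `pacc_trajectory` (with outcome), invisibly when `out` is
#'   given.
#' @export
run_simulate <- function(config, out = NULL) {
  stopifnot(inherits(config, "pacc_config"))
  traj <- simulate_pacc(config$params, config$schedule, config$mode,
                        config$ic, config$t_end, config$solver_opts)
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines(paste0("# paccsim trajectory; config digest ",
                      config_digest(config)), con)
    utils::write.csv(format(traj$data, digits = 17, trim = TRUE,
                            scientific = NA),
                     con, row.names = FALSE, quote = FALSE)
    return(invisible(traj))
  }
  traj
}

#' Run the scenario battery and write the verdict table
#'
#' @param params A [pacc_params()] object.
#' @param out Optional CSV path for the 25-row verdict table.
#' @param t_end,solver_opts Passed to [run_scenario_battery()].
#' @return The `pacc_battery` data frame (invisibly when `out` is given).
#' @export
run_battery <- function(params = pacc_params(), out = NULL, t_end = 1000,
                        solver_opts = list()) {
  bat <- run_scenario_battery(params, t_end, solver_opts)
  if (!is.null(out)) {
    utils::write.csv(bat, out, row.names = FALSE, quote = FALSE)
    return(invisible(bat))
  }
  bat
}
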