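#' Analytic no-therapy equilibrium of the structured model
#'
#' With no drug the steady state of the structured model solves
#' `x2*/x1* = gamma*zeta/c12` (PACC balance) together with
#' `x1* + x2* = K * (1 - gamma*(1 - 2*zeta)/r)` (2N+ balance after
#' substituting the ratio). When `zeta > 1/2` the total exceeds the carrying
#' capacity: each depolyploidization returns two daughters, so the PACC loop
#' adds net births.
#'
#' @param params A [pacc_params()] object with `c12 > 0`, `r > 0`.
#' @return Named numeric `c(x1, x2)`.
#' @examples
#' analytic_equilibrium_no_therapy(pacc_params()) # ~ (94.7040, 6.6293)
#' @export
analytic_equilibrium_no_therapy <- function(params) {
  if (params$c12 <= 0 || params$r <= 0)
    stop("equilibrium requires c12 > 0 and r > 0", call. = FALSE)
  total <- params$K * (1 - params$gamma * (1 - 2 * params$zeta) / params$r)
  if (total <= 0 || params$r <= params$gamma * (1 - 2 * params$zeta))
    stop("no positive equilibrium: growth cannot offset obligate losses",
         call. = FALSE)
  ratio <- params$gamma * params$zeta / params$c12
  x1 <- total / (1 + ratio)
  c(x1 = x1, x2 = ratio * x1)
}

#' Closed-form resistance trajectory of the single-state model
#'
#' Under a constant dose `m` from `v(0) = 0`, the trait equation
#' `dv/dt = k_const * b * m / (lam + b * v)^2` integrates to
#' \deqn{v(t) = \frac{(\lambda^3 + 3 k b^2 m t)^{1/3} - \lambda}{b}.}
#'
#' @param t Time (vectorized).
#' @param m Constant chemotherapy dose over `[0, t]`.
#' @param params A [pacc_params()] object.
#' @return `v(t)`.
#' @examples
#' closed_form_resistance_single(300, 1, pacc_params()) # 10^(1/3) - 1
#' @export
closed_form_resistance_single <- function(t, m, params) {
  ((params$lam^3 + 3 * params$k_const * params$b^2 * m * t)^(1 / 3) -
     params$lam) / params$b
}

#' Classify the outcome of a trajectory
#'
#' Operationalizes eradication-versus-persistence: a compartment is extinct
#' when the integrator clamped it below `extinction_eps` (and it was not
#' revived), and the population is `ERADICATED` when every compartment is
#' extinct at the end of the run — evolutionary rescue is simply
#' non-extinction at the horizon.
#'
#' @param traj A `pacc_trajectory` from [integrate_piecewise()].
#' @param params A [pacc_params()] object (defaults to the trajectory's own).
#' @return An object of class `pacc_outcome`: flags, extinction times, final
#'   state, final trait and a `label` in `{"ERADICATED", "PERSISTS"}`.
#' @examples
#' sim <- integrate_piecewise(pacc_params(), continuous_chemo(0),
#'                            hypothesis_mode("single_state"), t_end = 100)
#' classify_outcome(sim)$label
#' @export
classify_outcome <- function(traj, params = traj$params) {
  if (!inherits(traj, "pacc_trajectory"))
    stop("'traj' must be a pacc_trajectory", call. = FALSE)
  single <- !is_structured(traj$mode)
  fin <- traj$final_state
  ext <- !is.na(traj$extinction)
  label <- if (all(ext)) "ERADICATED" else "PERSISTS"
  structure(list(
    extinct_2n = ext[["x1"]],
    extinct_pacc = if (single) NA else ext[["x2"]],
    extinction_times = traj$extinction,
    final_state = fin,
    v_final = fin[[length(fin)]],
    label = label), class = "pacc_outcome")
}

#' @export
print.pacc_outcome <- function(x, ...) {
  cat("outcome:", x$label, "\n")
  cat("  final state:", paste(signif(x$final_state, 6), collapse = ", "), "\n")
  et <- x$extinction_times
  for (nm in names(et))
    cat(sprintf("  %s: %s\n", nm,
                if (is.na(et[[nm]])) "extant" else
                  paste0("extinct at t = ", et[[nm]])))
  invisible(x)
}

battery_scenarios <- function() {
  rows <- list(
    list("single_no_therapy", "single_state", "none", "none", 0, 0),
    list("single_low_dose", "single_state", "none", "none", 0.5, 0),
    list("single_high_dose", "single_state", "none", "none", 1, 0),
    list("np_continuous", "non_proliferation", "none", "none", 1, 0),
    list("np_intermittent", "non_proliferation", "none", "intermittent", 1, 0),
    list("et_continuous", "evolutionary_triage", "none", "none", 1, 0),
    list("et_intermittent", "evolutionary_triage", "none", "intermittent", 1, 0))
  for (hyp in c("non_proliferation", "evolutionary_triage"))
    for (drug in c("kifc1", "cdk", "metabolic"))
      for (timing in c("before", "during", "after"))
        rows[[length(rows) + 1L]] <- list(
          paste(if (hyp == "non_proliferation") "np" else "et",
                drug, timing, sep = "_"),
          hyp, drug, timing, 1, 0.8)
  rows
}

scenario_schedule <- function(timing, m_level, n_level) {
  base <- if (timing == "intermittent") intermittent_chemo(m_level)
          else continuous_chemo(m_level)
  if (timing %in% c("before", "during", "after"))
    targeted_regimen(timing, n_level, base)
  else base
}

#' Run the full scenario battery
#'
#' Simulates the 25 scenarios spanning the model comparisons: the
#' single-state triplet (no therapy, half dose, full dose), continuous and
#' intermittent full-dose chemotherapy under the non-proliferation and
#' evolutionary-triage hypotheses, and the 18 targeted-therapy cells (three
#' drugs x two hypotheses x before/during/after windows at dose 0.8 on top
#' of continuous full-dose chemotherapy).
#'
#' @param params A [pacc_params()] object.
#' @param t_end Horizon per scenario (default 1000).
#' @param solver_opts Passed to [integrate_piecewise()].
#' @return A data frame of class `pacc_battery` with one row per scenario:
#'   `scenario`, `hypothesis`, `drug`, `timing`, `verdict`,
#'   `extinction_time_2n`, `extinction_time_pacc`, `v_final`.
#' @examples
#' \donttest{
#' bat <- run_scenario_battery()
#' table(bat$verdict)
#' }
#' @export
run_scenario_battery <- function(params = pacc_params(), t_end = 1000,
                                 solver_opts = list()) {
  rows <- battery_scenarios()
  out <- lapply(rows, function(sc) {
    mode <- hypothesis_mode(sc[[2]], sc[[3]])
    sched <- scenario_schedule(sc[[4]], sc[[5]], sc[[6]])
    traj <- tryCatch(
      integrate_piecewise(params, sched, mode, t_end = t_end,
                          solver_opts = solver_opts),
      error = function(e) stop("scenario '", sc[[1]], "' failed: ",
                               conditionMessage(e), call. = FALSE))
    oc <- classify_outcome(traj, params)
    data.frame(scenario = sc[[1]], hypothesis = sc[[2]], drug = sc[[3]],
               timing = sc[[4]], verdict = oc$label,
               extinction_time_2n = unname(oc$extinction_times["x1"]),
               extinction_time_pacc =
                 if ("x2" %in% names(oc$extinction_times))
                   unname(oc$extinction_times["x2"]) else NA_real_,
               v_final = unname(oc$v_final))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pacc_battery", class(res))
  res
}

#' @export
print.pacc_battery <- function(x, ...) {
  cat("scenario battery (", nrow(x), " scenarios)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
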