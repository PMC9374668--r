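#' Right-hand side of the structured 2N+/PACC model
#'
#' Population derivatives are exactly the matrix-vector product
#' `A %*% c(x1, x2)` with `A` from [assemble_ppm()] — the printed population
#' equations of the model, including every targeted-drug variant, are of
#' this form. The trait obeys `dv/dt = k * dG/dv` with `k` from
#' [evolvability()] and the gradient from [fitness_gradient()].
#'
#' @inheritParams assemble_ppm
#' @return Numeric `c(dx1, dx2, dv)`.
#' @examples
#' p <- pacc_params()
#' rhs_structured(system_state(50, 5, 0), m = 1, n = 0,
#'                hypothesis_mode("evolutionary_triage"), p)
#' @export
rhs_structured <- function(state, m = 0, n = 0, mode, params) {
  if (!is_structured(mode))
    stop("use rhs_single() for the single-state model", call. = FALSE)
  x1 <- max(state[[1]], 0); x2 <- max(state[[2]], 0); v <- max(state[[3]], 0)
  s <- c(x1, x2, v)
  A <- assemble_ppm(s, m, n, mode, params)
  dx <- as.numeric(A %*% c(x1, x2))
  dv <- evolvability(x1, x2, mode, params) *
    fitness_gradient(s, m, n, mode, params)
  c(dx1 = dx[1L], dx2 = dx[2L], dv = dv)
}

#' Right-hand side of the single-state model
#'
#' Logistic growth minus Michaelis-Menten drug kill for the one proliferative
#' compartment, with the closed-form selection gradient:
#' `dx/dt = r x (K - x)/K - x m/(lam + b v)`,
#' `dv/dt = k_const * b m / (lam + b v)^2`.
#'
#' @param state Numeric `c(x, v)`.
#' @param m Chemotherapy dose.
#' @param params A [pacc_params()] object.
#' @return Numeric `c(dx, dv)`.
#' @examples
#' rhs_single(c(100, 0), m = 1, pacc_params()) # c(-100, 0.01)
#' @export
rhs_single <- function(state, m = 0, params) {
  x <- max(state[[1]], 0); v <- max(state[[2]], 0)
  kill <- drug_kill_rate(v, m, params)
  dx <- params$r * x * (params$K - x) / params$K - x * kill
  dv <- params$k_const * params$b * m / (params$lam + params$b * v)^2
  c(dx = dx, dv = dv)
}

#' Integrate the model over a therapy schedule
#'
#' Integrates segment-by-segment between schedule breakpoints with lsoda
#' (adaptive, stiff-capable); doses are constant within a segment. Segments
#' longer than `max_segment` are subdivided so that extinction is checked at
#' least that often. After each segment any population compartment below
#' `extinction_eps` is clamped to exactly 0 and its extinction time recorded
#' (a compartment revived above the threshold by inflow from the other state
#' clears its record); when every compartment is extinct the integration
#' terminates early. The non-proliferation trigger is state-dependent
#' (through the evolving trait) and is evaluated inside the right-hand side,
#' not at breakpoints.
#'
#' @param params A [pacc_params()] object.
#' @param schedule A [therapy_schedule()].
#' @param mode A [hypothesis_mode()] object.
#' @param ic Initial condition: `c(x1, x2, v)` for structured variants
#'   (see [system_state()]), `c(x, v)` for the single-state model. Defaults
#'   to 100 cells, no PACCs, no resistance.
#' @param t_end Final time (default 1000; therapy scenarios end at 800 and
#'   the remainder shows post-therapy relaxation).
#' @param solver_opts List of numerical controls: `rtol` (default 1e-8),
#'   `atol` (1e-10), `dt_out` (output spacing, 1), `max_segment` (100).
#' @return An object of class `pacc_trajectory`: a list with `data` (data
#'   frame of `t, x1, x2, v, m, n, kill_rate, k_eff, rho`), `extinction`
#'   (named times, `NA` when extant), `final_state`, `t_end`,
#'   `terminated_early`, plus the inputs.
#' @examples
#' p <- pacc_params()
#' tr <- integrate_piecewise(p, continuous_chemo(0),
#'                           hypothesis_mode("evolutionary_triage"),
#'                           t_end = 50)
#' tail(tr$data[c("t", "x1", "x2", "v")], 3)
#' @export
integrate_piecewise <- function(params, schedule, mode,
                                ic = NULL, t_end = 1000,
                                solver_opts = list()) {
  check_mode_params(mode, params)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  so <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, dt_out = 1,
                               max_segment = 100), solver_opts)
  single <- !is_structured(mode)
  if (is.null(ic)) ic <- if (single) c(x = 100, v = 0) else system_state()
  if (length(ic) != (if (single) 2L else 3L))
    stop("initial condition has the wrong length for this mode",
         call. = FALSE)
  if (any(ic < 0)) stop("initial condition must be nonnegative", call. = FALSE)
  npop <- if (single) 1L else 2L

  bp <- sort(unique(c(0, schedule$breakpoints, t_end)))
  bp <- bp[bp >= 0 & bp <= t_end]
  bp <- refine_breakpoints(bp, so$max_segment)

  y <- as.numeric(ic)
  ext <- rep(NA_real_, npop)
  rows <- vector("list", length(bp) - 1L)
  terminated <- FALSE
  for (i in seq_len(length(bp) - 1L)) {
    t0 <- bp[i]; t1 <- bp[i + 1L]
    dose <- dose_at(schedule, t0)
    times <- unique(c(seq(t0, t1, by = so$dt_out), t1))
    deriv <- if (single) {
      function(t, y, p) list(rhs_single(y, dose[["m"]], params))
    } else {
      function(t, y, p) list(rhs_structured(y, dose[["m"]], dose[["n"]],
                                            mode, params))
    }
    sol <- try(deSolve::ode(y, times, deriv, parms = NULL, method = "lsoda",
                            rtol = so$rtol, atol = so$atol), silent = TRUE)
    if (inherits(sol, "try-error") ||
        attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times))
      stop(sprintf("solver failure on segment [%g, %g) from state (%s)",
                   t0, t1, paste(signif(y, 6), collapse = ", ")),
           call. = FALSE)
    ymat <- unclass(sol)[, -1L, drop = FALSE]
    if (min(ymat) < -1e-6)
      stop(sprintf(
        "negative excursion %.3g on segment [%g, %g): tighten tolerances",
        min(ymat), t0, t1), call. = FALSE)
    ymat[ymat < 0] <- 0
    y <- ymat[nrow(ymat), ]
    for (j in seq_len(npop)) {
      if (y[j] < params$extinction_eps) {
        y[j] <- 0
        if (is.na(ext[j])) ext[j] <- t1
      } else ext[j] <- NA_real_
    }
    ymat[nrow(ymat), ] <- y
    seg <- cbind(t = sol[, 1L], ymat, m = dose[["m"]], n = dose[["n"]])
    rows[[i]] <- if (i == 1L) seg else seg[-1L, , drop = FALSE]
    if (all(y[seq_len(npop)] == 0)) { terminated <- i < length(bp) - 1L; break }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- if (single) c("t", "x1", "v", "m", "n") else
    c("t", "x1", "x2", "v", "m", "n")
  if (single) tab$x2 <- NA_real_
  tab <- tab[c("t", "x1", "x2", "v", "m", "n")]
  tab <- add_channels(tab, mode, params)

  names(ext) <- if (single) "x1" else c("x1", "x2")
  structure(list(data = tab, extinction = ext,
                 final_state = stats::setNames(y, names(ic)),
                 t_end = tab$t[nrow(tab)], terminated_early = terminated,
                 params = params, mode = mode, schedule = schedule,
                 solver_opts = so),
            class = "pacc_trajectory")
}

refine_breakpoints <- function(bp, max_segment) {
  out <- numeric(0)
  for (i in seq_len(length(bp) - 1L)) {
    len <- bp[i + 1L] - bp[i]
    k <- ceiling(len / max_segment)
    out <- c(out, seq(bp[i], bp[i + 1L], length.out = k + 1L))
  }
  sort(unique(c(out, bp)))
}

# Derived channels, recomputable from states + schedule (self-consistency).
add_channels <- function(tab, mode, params) {
  nr <- nrow(tab)
  kill <- k_eff <- rho <- numeric(nr)
  single <- !is_structured(mode)
  for (i in seq_len(nr)) {
    kill[i] <- drug_kill_rate(tab$v[i], tab$m[i], params)
    if (single) {
      k_eff[i] <- params$k_const
      rho[i] <- params$r * (params$K - tab$x1[i]) / params$K - kill[i]
    } else {
      k_eff[i] <- evolvability(tab$x1[i], tab$x2[i], mode, params)
      rho[i] <- spectral_bound(assemble_ppm(
        c(tab$x1[i], tab$x2[i], tab$v[i]), tab$m[i], tab$n[i], mode, params))
    }
  }
  tab$kill_rate <- kill
  tab$k_eff <- k_eff
  tab$rho <- rho
  tab
}

#' Simulate one scenario
#'
#' Convenience wrapper around [integrate_piecewise()] followed by
#' [classify_outcome()].
#'
#' @inheritParams integrate_piecewise
#' @return The `pacc_trajectory` with its `pacc_outcome` attached as
#'   element `outcome`.
#' @examples
#' sim <- simulate_pacc(pacc_params(), continuous_chemo(0),
#'                      hypothesis_mode("single_state"), t_end = 100)
#' sim$outcome$label
#' @export
simulate_pacc <- function(params = pacc_params(),
                          schedule = continuous_chemo(1),
                          mode = hypothesis_mode("evolutionary_triage"),
                          ic = NULL, t_end = 1000, solver_opts = list()) {
  traj <- integrate_piecewise(params, schedule, mode, ic, t_end, solver_opts)
  traj$outcome <- classify_outcome(traj, params)
  traj
}
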