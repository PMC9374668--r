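#' Per-capita drug-induced death rate
#'
#' Michaelis-Menten kill kinetics `m / (lam + b * v)`: mortality rises with
#' the chemotherapy dose `m` and falls as the resistance trait `v` grows.
#' Only 2N+ cells experience this mortality; PACCs are fully resistant.
#'
#' @param v Resistance trait (nonnegative).
#' @param m Chemotherapy dose (nonnegative).
#' @param params A [pacc_params()] object.
#' @return Per-capita kill rate (1/time).
#' @examples
#' p <- pacc_params()
#' drug_kill_rate(0, 1, p) # 1
#' drug_kill_rate(1, 1, p) # 0.5
#' @export
drug_kill_rate <- function(v, m, params) {
  if (any(v < 0) || any(m < 0))
    stop("'v' and 'm' must be nonnegative", call. = FALSE)
  m / (params$lam + params$b * v)
}

#' Effective evolvability of the resistance trait
#'
#' Under evolutionary triage the evolvability is the density-weighted mean
#' `(k1*x1 + k2*x2) / (x1 + x2)`, so a PACC-rich population evolves faster
#' (`k2 > k1`). All other variants use the constant `k_const`. With no cells
#' at all the triage value is defined as 0: an empty population has no trait
#' motion, which keeps the coupled system well-defined near extinction.
#'
#' @param x1,x2 Compartment densities (nonnegative).
#' @param mode A [hypothesis_mode()] object.
#' @param params A [pacc_params()] object.
#' @return Evolvability (trait^2/time).
#' @examples
#' p <- pacc_params()
#' et <- hypothesis_mode("evolutionary_triage")
#' evolvability(5, 0, et, p) # k1
#' evolvability(0, 5, et, p) # k2
#' @export
evolvability <- function(x1, x2, mode, params) {
  if (x1 < 0 || x2 < 0) stop("densities must be nonnegative", call. = FALSE)
  if (mode$hypothesis != "evolutionary_triage") return(params$k_const)
  tot <- x1 + x2
  if (tot == 0) return(0)
  (params$k1 * x1 + params$k2 * x2) / tot
}

#' Non-proliferation depolyploidization trigger
#'
#' Under the non-proliferation hypothesis PACCs act as a refuge: when the
#' per-capita drug-kill rate reaches the threshold (`np_threshold`, default
#' 1), the PACC-to-2N+ transition shuts off entirely. The trigger depends on
#' the evolving trait through the kill rate, so it is re-evaluated at every
#' right-hand-side call rather than at schedule breakpoints.
#'
#' @inheritParams drug_kill_rate
#' @return `TRUE` when depolyploidization is blocked.
#' @examples
#' p <- pacc_params()
#' np_depoly_blocked(0, 1, p) # TRUE: kill rate 1 meets the threshold
#' np_depoly_blocked(1, 1, p) # FALSE: kill rate 0.5
#' @export
np_depoly_blocked <- function(v, m, params) {
  drug_kill_rate(v, m, params) >= params$np_threshold
}

#' Assemble the population projection matrix
#'
#' Builds the 2x2 projection matrix `A` over (2N+, PACC) whose product with
#' the density vector gives the population derivatives. Baseline entries:
#' \deqn{a_{11} = r(K - x_1 - x_2)/K - \gamma - (1 + c_{21})\,\mu,\quad
#'       a_{12} = 2 c_{12},}
#' \deqn{a_{21} = \zeta(\gamma + c_{21}\,\mu),\quad a_{22} = -c_{12},}
#' with \eqn{\mu = m/(\lambda + b v)} the drug-kill rate. Targeted drugs
#' modify single entries: KIFC1 scales the depolyploidization inflow,
#' `a12 = 2 c12 (1 - n)` (transitioning PACCs still leave: `a22` keeps
#' `-c12`); the cyclin/CDK inhibitor scales PACC formation,
#' `a21 = zeta (1 - n) (gamma + c21 mu)`; the metabolic modulator adds direct
#' PACC death, `a22 = -c12 - n`. Under the non-proliferation hypothesis,
#' while the trigger is active `c12` is zeroed in both terms it appears in
#' (`a12` and `a22`), freezing the PACC compartment.
#'
#' Off-diagonal entries are nonnegative for all valid inputs (Metzler
#' structure), so both eigenvalues are real.
#'
#' @param state Numeric `c(x1, x2, v)`, e.g. from [system_state()].
#' @param m Chemotherapy dose (nonnegative).
#' @param n Targeted-drug dose; must lie in \[0, 1\] for the transition
#'   blockers (KIFC1, CDK).
#' @param mode A [hypothesis_mode()] object; must be structured.
#' @param params A [pacc_params()] object.
#' @return A 2x2 numeric matrix of class `pacc_ppm` with a `"provenance"`
#'   attribute labelling each entry's terms.
#' @examples
#' p <- pacc_params()
#' assemble_ppm(system_state(0, 0, 0), m = 0, n = 0,
#'              hypothesis_mode("evolutionary_triage"), p)
#' @export
assemble_ppm <- function(state, m = 0, n = 0, mode, params) {
  if (!is_structured(mode))
    stop("the single-state model has scalar fitness; no projection matrix",
         call. = FALSE)
  if (n < 0) stop("'n' must be nonnegative", call. = FALSE)
  if (mode$drug %in% c("kifc1", "cdk") && n > 1)
    stop("transition-blocking doses must lie in [0, 1]", call. = FALSE)
  x1 <- state[[1]]; x2 <- state[[2]]; v <- state[[3]]
  kill <- drug_kill_rate(v, m, params)
  blocked <- mode$hypothesis == "non_proliferation" &&
    np_depoly_blocked(v, m, params)
  c12_eff <- if (blocked) 0 else params$c12
  f12 <- if (mode$drug == "kifc1") 1 - n else 1
  f21 <- if (mode$drug == "cdk") 1 - n else 1
  mu2 <- if (mode$drug == "metabolic") n else 0
  a11 <- params$r * (params$K - x1 - x2) / params$K - params$gamma -
    (1 + params$c21) * kill
  a12 <- 2 * c12_eff * f12
  a21 <- params$zeta * f21 * (params$gamma + params$c21 * kill)
  a22 <- -c12_eff - mu2
  A <- matrix(c(a11, a21, a12, a22), 2L, 2L,
              dimnames = list(c("2N+", "PACC"), c("2N+", "PACC")))
  attr(A, "provenance") <- c(
    a11 = "logistic growth - obligate out - drug death - facultative out",
    a12 = "from PACC (x2 depolyploidization, KIFC1-scaled, NP-gated)",
    a21 = "obligate in + facultative in (CDK-scaled)",
    a22 = "to 2N+ (NP-gated) - modulator death")
  attr(A, "np_blocked") <- blocked
  class(A) <- c("pacc_ppm", class(A))
  A
}

#' Spectral bound of a projection matrix
#'
#' Fitness of the structured population: the larger eigenvalue of the 2x2
#' projection matrix, computed via the closed form
#' `(tr + sqrt(tr^2 - 4 det)) / 2`. The Metzler structure of the matrix
#' guarantees a nonnegative discriminant and hence real eigenvalues; a
#' materially negative discriminant signals an invariant breach and errors.
#'
#' @param A A 2x2 matrix, normally from [assemble_ppm()].
#' @return The spectral bound (1/time).
#' @examples
#' A <- matrix(c(0.58, 0.014, 0.4, -0.2), 2, 2)
#' spectral_bound(A) # ~0.587115
#' @export
spectral_bound <- function(A) {
  tr <- A[1L, 1L] + A[2L, 2L]
  de <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  disc <- tr * tr - 4 * de
  if (disc < -1e-12)
    stop("negative discriminant: matrix violates the Metzler invariant",
         call. = FALSE)
  (tr + sqrt(max(disc, 0))) / 2
}

# Trait derivatives of the v-dependent matrix entries (a11 and a21; the kill
# rate falls with v, so a11 rises and the facultative inflow a21 falls).
ppm_entry_derivs <- function(v, m, n, mode, params) {
  d <- params$b * m / (params$lam + params$b * v)^2
  f21 <- if (mode$drug == "cdk") 1 - n else 1
  list(a11p = (1 + params$c21) * d,
       a21p = -params$zeta * f21 * params$c21 * d)
}

#' Selection gradient of fitness with respect to resistance
#'
#' Derivative of fitness with respect to the trait `v`. For the single-state
#' model the fitness is scalar and the gradient has the closed form
#' `b*m / (lam + b*v)^2`. For structured variants it is the derivative of
#' the spectral bound of the current (variant-modified) projection matrix:
#' on the analytic path, implicit differentiation of the characteristic
#' polynomial gives `ds/dv = (s*tr' - det') / (2s - tr)` with `tr' = a11'`
#' and `det' = a11'*a22 - a12*a21'`. While the non-proliferation trigger is
#' active the matrix is triangular with eigenvalues `{a11, 0}`, so the
#' gradient is `a11'` when `a11 > 0` and exactly 0 otherwise (the trait is
#' frozen while the inert PACC eigenvalue dominates). Near a degenerate
#' eigenvalue (`|2s - tr|` below 1e-12) the analytic path falls back to a
#' central finite difference.
#'
#' Resistance carries no cost in this model, so the gradient is nonnegative
#' throughout the ecologically admissible region (total density up to the
#' no-therapy equilibrium), and it is exactly 0 whenever `m = 0`. Far above
#' carrying capacity the derivative can turn negative: there crowding makes
#' the 2N+ state a net sink and weaker drug kill also means weaker sheltering
#' into the PACC refuge. The function returns the true derivative either way.
#'
#' @inheritParams assemble_ppm
#' @param method `"analytic"` (default) or `"finite_difference"` (central
#'   difference on the spectral bound, `h = 1e-6`; used as an independent
#'   oracle).
#' @return dG/dv (1/time per trait unit), nonnegative.
#' @examples
#' p <- pacc_params()
#' fitness_gradient(system_state(100, 0, 0), m = 1,
#'                  mode = hypothesis_mode("single_state"), params = p) # 1
#' @export
fitness_gradient <- function(state, m = 0, n = 0, mode, params,
                             method = c("analytic", "finite_difference")) {
  method <- match.arg(method)
  if (m < 0 || n < 0) stop("doses must be nonnegative", call. = FALSE)
  v <- state[[length(state)]]
  if (mode$hypothesis == "single_state")
    return(params$b * m / (params$lam + params$b * v)^2)

  if (method == "finite_difference")
    return(gradient_fd(state, m, n, mode, params))

  A <- assemble_ppm(state, m, n, mode, params)
  dv <- ppm_entry_derivs(v, m, n, mode, params)
  if (isTRUE(attr(A, "np_blocked"))) {
    # triangular matrix: eigenvalues {a11, 0}; at the kink a11 = 0 the
    # subgradient 0 is used (trait frozen while the inert state dominates)
    return(if (A[1L, 1L] > 0) dv$a11p else 0)
  }
  s <- spectral_bound(A)
  tr <- A[1L, 1L] + A[2L, 2L]
  denom <- 2 * s - tr
  if (abs(denom) < 1e-12)
    return(gradient_fd(state, m, n, mode, params))
  detp <- dv$a11p * A[2L, 2L] - A[1L, 2L] * dv$a21p
  (s * dv$a11p - detp) / denom
}

gradient_fd <- function(state, m, n, mode, params, h = 1e-6) {
  v <- state[[3]]
  sp <- state; sm <- state
  sp[[3]] <- v + h
  sm[[3]] <- max(v - h, 0)
  gp <- spectral_bound(assemble_ppm(sp, m, n, mode, params))
  gm <- spectral_bound(assemble_ppm(sm, m, n, mode, params))
  (gp - gm) / (sp[[3]] - sm[[3]])
}
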