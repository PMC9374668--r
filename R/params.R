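#' Model parameters for the 2N+/PACC life-history model
#'
#' Collects every rate and constant of the eco-evolutionary model, pre-filled
#' with the baseline simulation values. Densities are in cell-density units,
#' rates in 1/time, the resistance trait `v` is dimensionless.
#'
#' @param r Intrinsic growth rate of 2N+ cells (1/time).
#' @param K Carrying capacity shared by both states (cell-density units).
#' @param gamma Obligate 2N+ to PACC transition rate (1/time).
#' @param lam Baseline level of resistance; denominator offset of the
#'   Michaelis-Menten drug-kill term (dimensionless, must be positive).
#' @param b Efficacy of the resistance strategy (dimensionless).
#' @param c21 Facultative (stress-induced) 2N+ to PACC transition scaling
#'   rate, applied to the drug-kill term (dimensionless).
#' @param c12 PACC to 2N+ depolyploidization rate (1/time). Each successful
#'   depolyploidization yields two 2N+ daughters.
#' @param zeta Probability that a poly-aneuploid transition succeeds
#'   (fraction in \[0, 1\]).
#' @param k_const Evolvability used by the single-state and non-proliferation
#'   variants (trait^2/time).
#' @param k1 2N+ evolvability under evolutionary triage.
#' @param k2 PACC evolvability under evolutionary triage; must exceed `k1`
#'   when that variant is simulated.
#' @param np_threshold Per-capita drug-kill rate at or above which
#'   depolyploidization shuts off under the non-proliferation hypothesis
#'   (1/time).
#' @param extinction_eps Density below which a compartment is declared
#'   extinct and clamped to zero at integration-segment boundaries.
#'
#' @details
#' The defaults are the baseline parameterization used throughout the
#' scenario battery: `r = 0.6`, `K = 100`, `gamma = 0.02`, `lam = 1`,
#' `b = 1`, `c21 = 0.7`, `c12 = 0.2`, `zeta = 0.7`, with chemotherapy dose
#' `m = 1` supplied through the therapy schedule. The evolvabilities
#' (`k_const = k1 = 0.01`, `k2 = 0.5`) are calibration values: small enough
#' that a single-state population cannot rescue under full-dose therapy, and
#' large enough that evolutionary triage rescues under continuous full-dose
#' therapy.
#'
#' @return An object of class `pacc_params`: a validated named list.
#' @examples
#' p <- pacc_params()
#' p$r
#' pacc_params(gamma = 0) # pure logistic 2N+ dynamics
#' @export
pacc_params <- function(r = 0.6, K = 100, gamma = 0.02, lam = 1, b = 1,
                        c21 = 0.7, c12 = 0.2, zeta = 0.7,
                        k_const = 0.01, k1 = 0.01, k2 = 0.5,
                        np_threshold = 1, extinction_eps = 1e-3) {
  p <- list(r = r, K = K, gamma = gamma, lam = lam, b = b, c21 = c21,
            c12 = c12, zeta = zeta, k_const = k_const, k1 = k1, k2 = k2,
            np_threshold = np_threshold, extinction_eps = extinction_eps)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  nonneg <- c("r", "K", "gamma", "b", "c21", "c12", "zeta",
              "k_const", "k1", "k2", "np_threshold")
  for (nm in nonneg) {
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  }
  if (p$lam <= 0) stop("'lam' must be positive", call. = FALSE)
  if (p$zeta > 1) stop("'zeta' must lie in [0, 1]", call. = FALSE)
  if (p$extinction_eps <= 0)
    stop("'extinction_eps' must be positive", call. = FALSE)
  if (p$extinction_eps >= p$K)
    stop("'extinction_eps' must be far below the carrying capacity",
         call. = FALSE)
  structure(p, class = "pacc_params")
}

#' @export
print.pacc_params <- function(x, ...) {
  cat("2N+/PACC model parameters\n")
  vals <- unlist(x)
  for (nm in names(vals)) cat(sprintf("  %-15s %g\n", nm, vals[[nm]]))
  invisible(x)
}

#' Hypothesis and targeted-drug selector
#'
#' Chooses which model variant is simulated: the population-structure
#' hypothesis (single proliferative state, non-proliferation refuge, or
#' evolutionary triage) and, for structured variants, which PACC-targeted
#' drug the targeted dose `n` refers to.
#'
#' @param hypothesis One of `"single_state"`, `"non_proliferation"`,
#'   `"evolutionary_triage"`.
#' @param drug One of `"none"`, `"kifc1"` (depolyploidization blocker),
#'   `"cdk"` (PACC-formation blocker), `"metabolic"` (direct PACC killing).
#'   The single-state model admits no targeted drug.
#' @return An object of class `pacc_mode`.
#' @examples
#' hypothesis_mode("evolutionary_triage", "kifc1")
#' @export
hypothesis_mode <- function(hypothesis = c("single_state", "non_proliferation",
                                           "evolutionary_triage"),
                            drug = c("none", "kifc1", "cdk", "metabolic")) {
  hypothesis <- match.arg(hypothesis)
  drug <- match.arg(drug)
  if (hypothesis == "single_state" && drug != "none")
    stop("the single-state model is incompatible with a targeted drug",
         call. = FALSE)
  structure(list(hypothesis = hypothesis, drug = drug), class = "pacc_mode")
}

#' @export
print.pacc_mode <- function(x, ...) {
  cat("hypothesis:", x$hypothesis, "| targeted drug:", x$drug, "\n")
  invisible(x)
}

is_structured <- function(mode) mode$hypothesis != "single_state"

check_mode_params <- function(mode, params) {
  if (mode$hypothesis == "evolutionary_triage" && !(params$k1 < params$k2))
    stop("evolutionary triage requires k1 < k2", call. = FALSE)
  invisible(TRUE)
}

#' System state constructor
#'
#' A structured state holds the 2N+ density `x1`, the PACC density `x2` and
#' the resistance trait `v`; the single-state model uses `x1` as its only
#' compartment (with `x2 = 0`).
#'
#' @param x1 2N+ density (nonnegative).
#' @param x2 PACC density (nonnegative).
#' @param v Resistance trait (nonnegative).
#' @return A named numeric vector `c(x1, x2, v)`.
#' @examples
#' system_state(100, 0, 0)
#' @export
system_state <- function(x1 = 100, x2 = 0, v = 0) {
  if (any(!is.finite(c(x1, x2, v))))
    stop("state components must be finite", call. = FALSE)
  if (x1 < 0 || x2 < 0 || v < 0)
    stop("state components must be nonnegative", call. = FALSE)
  c(x1 = x1, x2 = x2, v = v)
}
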