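# Random valid model inputs for property-style tests.

draw_state <- function() {
  c(x1 = runif(1, 0, 120), x2 = runif(1, 0, 60), v = runif(1, 0, 4))
}

draw_structured_mode <- function(drugs = c("none", "kifc1", "cdk",
                                           "metabolic")) {
  hypothesis_mode(sample(c("non_proliferation", "evolutionary_triage"), 1),
                  sample(drugs, 1))
}

draw_doses <- function() {
  c(m = runif(1, 0, 1.5), n = runif(1, 0, 1))
}

# Hand expansion of the printed population equations for every variant,
# written term by term; the independent oracle for the A %*% x identity.
rhs_by_hand <- function(state, m, n, mode, p) {
  x1 <- state[[1]]; x2 <- state[[2]]; v <- state[[3]]
  kill <- m / (p$lam + p$b * v)
  blocked <- mode$hypothesis == "non_proliferation" && kill >= p$np_threshold
  c12 <- if (blocked) 0 else p$c12
  from_pacc <- 2 * c12 * x2
  if (mode$drug == "kifc1") from_pacc <- 2 * c12 * (1 - n) * x2
  obligate_in <- p$gamma * p$zeta * x1
  facultative_in <- p$c21 * p$zeta * x1 * kill
  if (mode$drug == "cdk") {
    obligate_in <- obligate_in * (1 - n)
    facultative_in <- facultative_in * (1 - n)
  }
  metab_death <- if (mode$drug == "metabolic") n * x2 else 0
  dx1 <- p$r * x1 * (p$K - x1 - x2) / p$K - p$gamma * x1 - x1 * kill -
    p$c21 * x1 * kill + from_pacc
  dx2 <- obligate_in + facultative_in - c12 * x2 - metab_death
  c(dx1, dx2)
}

# Spectral bound through a general eigensolver; the oracle for the closed
# form and for finite-difference gradients.
eigen_bound <- function(A) max(Re(eigen(A, only.values = TRUE)$values))

fd_gradient_eigen <- function(state, m, n, mode, params, h = 1e-6) {
  up <- state; dn <- state
  up[[3]] <- state[[3]] + h
  dn[[3]] <- max(state[[3]] - h, 0)
  (eigen_bound(assemble_ppm(up, m, n, mode, params)) -
     eigen_bound(assemble_ppm(dn, m, n, mode, params))) /
    (up[[3]] - dn[[3]])
}
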