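p <- pacc_params()
et <- hypothesis_mode("evolutionary_triage")
np <- hypothesis_mode("non_proliferation")
ss <- hypothesis_mode("single_state")

test_that("drug kill rate follows Michaelis-Menten kinetics in the trait", {
  expect_identical(drug_kill_rate(0, 1, p), 1)
  expect_identical(drug_kill_rate(0, 0, p), 0)
  expect_identical(drug_kill_rate(1, 1, p), 0.5)
  v <- seq(0, 5, by = 0.5)
  expect_true(all(diff(drug_kill_rate(v, 1, p)) < 0))
  expect_error(drug_kill_rate(-0.1, 1, p), "nonnegative")
  expect_error(drug_kill_rate(0, -1, p), "nonnegative")
})

test_that("evolvability is the density-weighted mean under triage", {
  expect_identical(evolvability(5, 0, et, p), p$k1)
  expect_identical(evolvability(0, 5, et, p), p$k2)
  expect_equal(evolvability(3, 3, et, p), (p$k1 + p$k2) / 2)
  expect_identical(evolvability(0, 0, et, p), 0)
  for (x2 in c(0, 1, 40)) {
    k <- evolvability(10, x2, et, p)
    expect_gte(k, p$k1); expect_lte(k, p$k2)
  }
  expect_identical(evolvability(5, 5, np, p), p$k_const)
  expect_identical(evolvability(0, 0, ss, p), p$k_const)
  expect_error(evolvability(-1, 0, et, p), "nonnegative")
})

test_that("non-proliferation trigger fires at the kill-rate threshold", {
  expect_true(np_depoly_blocked(0, 1, p))   # kill rate exactly 1
  expect_false(np_depoly_blocked(0, 0, p))
  expect_false(np_depoly_blocked(1, 1, p))  # kill rate 0.5
  expect_true(np_depoly_blocked(0, 1.5, p))
})

test_that("baseline projection matrix matches hand substitution", {
  A <- assemble_ppm(system_state(0, 0, 0), 0, 0, et, p)
  expect_equal(unclass(A)[1:4], c(0.58, 0.014, 0.4, -0.2),
               tolerance = 1e-15, ignore_attr = TRUE)
  # full-dose, zero-density variant
  A1 <- assemble_ppm(system_state(0, 0, 0), 1, 0, et, p)
  expect_equal(unclass(A1)[1:4], c(-1.12, 0.504, 0.4, -0.2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(assemble_ppm(system_state(), 0, 0, ss, p), "single-state")
})

test_that("targeted drugs modify exactly their own matrix entry", {
  s <- system_state(10, 5, 0.5)
  base <- assemble_ppm(s, 1, 0, et, p)
  kif <- assemble_ppm(s, 1, 0.8, hypothesis_mode("evolutionary_triage", "kifc1"), p)
  expect_equal(kif[1, 2], 2 * p$c12 * 0.2)
  expect_equal(kif[c(1, 2, 4)], base[c(1, 2, 4)])
  cdk <- assemble_ppm(s, 1, 0.8, hypothesis_mode("evolutionary_triage", "cdk"), p)
  expect_equal(cdk[2, 1], 0.2 * base[2, 1])
  expect_equal(cdk[c(1, 3, 4)], base[c(1, 3, 4)])
  met <- assemble_ppm(s, 1, 0.8, hypothesis_mode("evolutionary_triage", "metabolic"), p)
  expect_equal(met[2, 2], -1.0)   # -c12 - n
  expect_equal(met[c(1, 2, 3)], base[c(1, 2, 3)])
  expect_error(
    assemble_ppm(s, 1, 1.2, hypothesis_mode("evolutionary_triage", "kifc1"), p),
    "\\[0, 1\\]")
})

test_that("active non-proliferation trigger freezes the PACC compartment", {
  s <- system_state(10, 5, 0)
  A <- assemble_ppm(s, 1, 0, np, p)  # kill rate 1 >= threshold
  expect_identical(A[1, 2], 0)
  expect_identical(A[2, 2], 0)
  base <- assemble_ppm(s, 1, 0, et, p)
  expect_equal(A[2, 1], base[2, 1])  # inflow to PACC unchanged
  expect_equal(A[1, 1], base[1, 1])
  # below threshold the matrix is the baseline one
  A2 <- assemble_ppm(system_state(10, 5, 1), 1, 0, np, p)
  expect_equal(A2, assemble_ppm(system_state(10, 5, 1), 1, 0, et, p),
               ignore_attr = TRUE)
})

test_that("zero targeted dose reproduces the baseline matrix entrywise", {
  set.seed(42)
  for (i in 1:200) {
    s <- draw_state(); d <- draw_doses()
    base <- assemble_ppm(s, d[["m"]], 0, et, p)
    for (drug in c("kifc1", "cdk", "metabolic")) {
      md <- hypothesis_mode("evolutionary_triage", drug)
      expect_identical(unclass(assemble_ppm(s, d[["m"]], 0, md, p))[1:4],
                       unclass(base)[1:4])
    }
  }
})

test_that("matrices are Metzler and the spectral bound is real", {
  set.seed(7)
  for (i in 1:10000) {
    s <- draw_state(); d <- draw_doses()
    md <- draw_structured_mode()
    A <- assemble_ppm(s, d[["m"]], d[["n"]], md, p)
    expect_gte(A[1, 2], 0)
    expect_gte(A[2, 1], 0)
    sb <- spectral_bound(A)
    expect_true(is.finite(sb))
  }
})

test_that("closed-form spectral bound agrees with a general eigensolver", {
  A <- matrix(c(0.58, 0.014, 0.4, -0.2), 2, 2)
  expect_equal(spectral_bound(A), eigen_bound(A), tolerance = 1e-10)
  expect_equal(spectral_bound(A), 0.5871146, tolerance = 1e-6)
  A2 <- matrix(c(-1.12, 0.504, 0.4, -0.2), 2, 2)
  expect_equal(spectral_bound(A2), eigen_bound(A2), tolerance = 1e-10)
  expect_equal(spectral_bound(A2), -0.0171936528, tolerance = 1e-6)
  # triangular structure: eigenvalues {a, 0}
  expect_equal(spectral_bound(matrix(c(-0.7, 0.3, 0, 0), 2, 2)), 0)
  expect_equal(spectral_bound(matrix(c(0.7, 0.3, 0, 0), 2, 2)), 0.7)
  set.seed(11)
  for (i in 1:500) {
    A <- assemble_ppm(draw_state(), runif(1, 0, 1.5), runif(1),
                      draw_structured_mode(), p)
    expect_equal(spectral_bound(A), eigen_bound(A), tolerance = 1e-10)
  }
  expect_error(spectral_bound(matrix(c(0, 1, -1, 0), 2, 2)), "Metzler")
})

test_that("single-state selection gradient has its closed form", {
  expect_identical(fitness_gradient(c(100, 0, 0), 1, 0, ss, p), 1)
  expect_equal(fitness_gradient(c(50, 0, 1), 1, 0, ss, p), 1 / 4)
  expect_identical(fitness_gradient(c(50, 0, 1), 0, 0, ss, p), 0)
})

test_that("structured gradient at vanishing density matches its oracle", {
  g <- fitness_gradient(system_state(0, 0, 0), 1, 0, et, p)
  expect_equal(g, 0.089273, tolerance = 1e-4)
  expect_equal(g, fd_gradient_eigen(system_state(0, 0, 0), 1, 0, et, p),
               tolerance = 1e-6)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(23)
  n_ok <- 0
  while (n_ok < 1000) {
    s <- draw_state(); s[3] <- runif(1, 0.01, 4)
    m <- runif(1, 0.1, 1.5); n <- runif(1, 0, 0.95)
    md <- draw_structured_mode()
    kill <- drug_kill_rate(s[[3]], m, p)
    # stay away from the trigger discontinuity and the eigenvalue kink
    if (md$hypothesis == "non_proliferation" && abs(kill - 1) < 0.02) next
    A <- assemble_ppm(s, m, n, md, p)
    if (abs(2 * spectral_bound(A) - A[1, 1] - A[2, 2]) < 1e-6) next
    g <- fitness_gradient(s, m, n, md, p)
    fd <- fd_gradient_eigen(s, m, n, md, p)
    expect_lt(abs(g - fd) / max(abs(fd), 1e-8), 1e-5)
    n_ok <- n_ok + 1
  }
})

test_that("zero dose gives an exactly zero gradient in every mode", {
  set.seed(5)
  for (i in 1:100) {
    s <- draw_state()
    expect_identical(fitness_gradient(s, 0, 0, ss, p), 0)
    expect_identical(fitness_gradient(s, 0, 0, et, p), 0)
    expect_identical(fitness_gradient(s, 0, 0.8,
      hypothesis_mode("non_proliferation", "metabolic"), p), 0)
  }
})

test_that("resistance never hurts fitness at admissible densities", {
  # nonnegativity holds wherever the dynamics can go (total density up to
  # the no-therapy equilibrium, ~101.3); far above carrying capacity the
  # 2N+ state is a net sink and the derivative can legitimately reverse
  set.seed(13)
  for (i in 1:2000) {
    tot <- runif(1, 0, 110)
    x1 <- runif(1, 0, tot)
    s <- c(x1, tot - x1, runif(1, 0, 4))
    d <- draw_doses()
    md <- draw_structured_mode()
    expect_gte(fitness_gradient(s, d[["m"]], d[["n"]], md, p), 0)
  }
})

test_that("trigger-frozen fitness has zero gradient when 2N+ decline wins", {
  # full dose at high density: a11 < 0 while depolyploidization is blocked
  s <- system_state(94.7, 6.6, 0)
  A <- assemble_ppm(s, 1, 0, np, p)
  expect_lt(A[1, 1], 0)
  expect_identical(fitness_gradient(s, 1, 0, np, p), 0)
  # blocked but 2N+ eigenvalue positive: gradient is a11' > 0
  p_mild <- pacc_params(np_threshold = 0.2)
  s2 <- system_state(1, 1, 1)
  A2 <- assemble_ppm(s2, 0.5, 0, np, p_mild)
  expect_identical(A2[1, 2], 0)
  expect_gt(A2[1, 1], 0)
  expect_gt(fitness_gradient(s2, 0.5, 0, np, p_mild), 0)
})

test_that("parameter and mode validation reject invalid input", {
  expect_error(pacc_params(lam = 0), "positive")
  expect_error(pacc_params(zeta = 1.2), "\\[0, 1\\]")
  expect_error(pacc_params(r = -1), "nonnegative")
  expect_error(pacc_params(extinction_eps = 0), "positive")
  expect_error(hypothesis_mode("single_state", "kifc1"), "incompatible")
  expect_error(system_state(-1, 0, 0), "nonnegative")
  bad_k <- pacc_params(k1 = 0.5, k2 = 0.5)
  expect_error(integrate_piecewise(bad_k, continuous_chemo(0), et, t_end = 1),
               "k1 < k2")
})
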