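p_wide <- growth_preset("wide", nu0 = 3.3)
chi_std <- control_function("hill",
                            K_chi = sqrt(p_wide$K_gamma * p_wide$K_nu))

test_that("both derivatives vanish at the fixed point and the defining
           identity chi_R(a*) = phiR* holds", {
  ss <- find_fixed_point(chi_std, p_wide)
  rhs <- ode_rhs(c(ss$a_star, ss$phiR_star), p_wide, chi_std)
  expect_lt(max(abs(rhs)), 1e-10)
  expect_identical(ss$phiR_star, unname(chi_std(ss$a_star)))
  expect_lt(abs(ss$residual), 1e-10)
  expect_equal(ss$lambda_star,
               translation_flux(ss$a_star, ss$phiR_star, p_wide))
})

test_that("rhs limits: growth arrest below phiR_min, pure supply at empty
           pool", {
  r1 <- ode_rhs(c(1e-4, p_wide$phiR_min), p_wide, chi_std)
  expect_equal(r1[2], 0)          # no growth, frozen composition
  r2 <- ode_rhs(c(1e-4, 0.02), p_wide, chi_std)
  expect_equal(r2[2], 0)
  r3 <- ode_rhs(c(0, 0.3), p_wide, chi_std)
  expect_gt(r3[1], 0)             # supply only
  expect_equal(r3[1], supply_flux(0, 0.3, p_wide))
})

test_that("dropping the dilution term changes da/dt by exactly a*lambda", {
  st <- c(5e-4, 0.3)
  lam <- translation_flux(st[1], st[2], p_wide)
  expect_equal(ode_rhs(st, p_wide, chi_std, dilution = FALSE)[1] -
                 ode_rhs(st, p_wide, chi_std, dilution = TRUE)[1],
               st[1] * lam)
})

test_that("a trajectory started at the fixed point stays there", {
  ss <- find_fixed_point(chi_std, p_wide)
  tr <- simulate_regulation(ss$a_star, ss$phiR_star, chi_std, p_wide,
                            t_end = 20)
  expect_lt(max(abs(tr$series$a - ss$a_star) / ss$a_star), 1e-6)
  expect_lt(max(abs(tr$series$phiR - ss$phiR_star)), 1e-8)
})

test_that("with constant chi the composition converges to chi and the
           fixed point reduces to the 1D flux-balance solution", {
  const <- control_function("constant", baseline = 0.3)
  ss <- find_fixed_point(const, p_wide, dilution = FALSE)
  expect_equal(ss$phiR_star, 0.3)
  expect_equal(ss$a_star, solve_steady_amino_acid(0.3, p_wide),
               tolerance = 1e-10)
  tr <- simulate_regulation(1e-5, 0.15, const, p_wide, t_end = 200)
  expect_equal(tr$terminal$phiR, 0.3, tolerance = 1e-6)
})

test_that("trajectories stay in the physical domain and converge to the
           fixed point from scattered starts", {
  ss <- find_fixed_point(chi_std, p_wide)
  set.seed(101)
  for (i in 1:5) {
    a0 <- 10^runif(1, -6, -1)
    f0 <- runif(1, 0.08, 0.54)
    tr <- simulate_regulation(a0, f0, chi_std, p_wide, t_end = 2000)
    expect_true(all(tr$series$a >= 0))
    expect_true(all(tr$series$phiR >= 0 & tr$series$phiR <= 1))
    expect_true(tr$converged)
    expect_equal(tr$terminal$a, ss$a_star, tolerance = 1e-6)
    expect_equal(tr$terminal$phiR, ss$phiR_star, tolerance = 1e-6)
  }
})

test_that("fixed-point existence failures name the failing side", {
  high <- control_function("constant", baseline = 0.6)
  expect_error(find_fixed_point(high, p_wide), "above")
  low <- control_function("constant", baseline = 0.05)
  expect_error(find_fixed_point(low, p_wide), "below")
})

test_that("the balance curve crossing is unique for a monotone control", {
  a <- 10^seq(-8, 0, length.out = 500)
  for (chi in list(chi_std,
                   control_function("piecewise", K_chi = 7e-4,
                                    amplitude = 0.9),
                   control_function("constant", baseline = 0.3))) {
    s <- sign(chi(a) - phiR_balance(a, p_wide))
    expect_equal(sum(diff(s[s != 0]) != 0), 1)
  }
})

test_that("fixed points of monotone hill controls are linearly stable and
           attract a 10% pool perturbation", {
  set.seed(202)
  for (i in 1:6) {
    chi <- control_function("hill",
                            baseline = runif(1, 0, 0.05),
                            amplitude = runif(1, 0.4, 0.9),
                            K_chi = 10^runif(1, -4, -2.5),
                            h = sample(1:3, 1))
    ss <- find_fixed_point(chi, p_wide)
    expect_true(ss$stable)
    expect_true(all(Re(ss$eigenvalues) < 0))
  }
  ss <- find_fixed_point(chi_std, p_wide)
  tr <- simulate_regulation(1.1 * ss$a_star, ss$phiR_star, chi_std, p_wide,
                            t_end = 500)
  expect_equal(tr$terminal$a, ss$a_star, tolerance = 1e-6)
})

test_that("constant-chi eigenvalues reduce to the pool subsystem derivative
           and the composition relaxation rate -lambda*", {
  const <- control_function("constant", baseline = 0.3)
  ss <- find_fixed_point(const, p_wide)
  st <- stability(ss, const, p_wide)
  # oracle: d(da/dt)/da at fixed phiR, central difference
  h <- 1e-6 * ss$a_star
  dfa <- (ode_rhs(c(ss$a_star + h, 0.3), p_wide, const)[1] -
            ode_rhs(c(ss$a_star - h, 0.3), p_wide, const)[1]) / (2 * h)
  ev <- sort(Re(st$eigenvalues))
  expect_equal(ev, sort(c(dfa, -ss$lambda_star)), tolerance = 1e-4)
})

test_that("stability() refuses states that are not fixed points", {
  expect_error(stability(list(a_star = 1e-3, phiR_star = 0.5),
                         chi_std, p_wide), "fixed point")
})
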