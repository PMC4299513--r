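p_narrow <- growth_preset("narrow", nu0 = 2.5)

test_that("flux-balance solver agrees with an independent bisection oracle", {
  for (phiR in c(0.1, 0.2, 0.4)) {
    for (nu0 in c(0.8, 2.5, 5.8)) {
      p <- update_params(p_narrow, nu0 = nu0)
      a <- solve_steady_amino_acid(phiR, p)
      expect_equal(a, bisect_steady_a(phiR, p), tolerance = 1e-12)
      expect_lt(abs(flux_residual(a, phiR, p)), 1e-9)
    }
  }
})

test_that("solver boundary behavior matches the model's degeneracies", {
  p <- p_narrow
  expect_equal(solve_steady_amino_acid(p$phiR_max, p), 0)
  expect_error(solve_steady_amino_acid(p$phiR_min, p), "degenerate")
  expect_error(solve_steady_amino_acid(0.6, p), "phiR")
  # no supply at all: pool drains to zero
  expect_equal(solve_steady_amino_acid(0.3, update_params(p, nu0 = 0)), 0)
})

test_that("steady pool decreases as more proteome goes to ribosomes", {
  phis <- seq(0.08, 0.54, length.out = 25)
  a <- solve_steady_amino_acid(phis, p_narrow)
  expect_true(all(diff(a) < 0))
})

test_that("growth rate curve is the efficiency times active allocation,
           vanishing at both bounds", {
  p <- p_narrow
  phis <- seq(0.08, 0.54, length.out = 20)
  lam <- growth_rate_at(phis, p)
  # grid oracle: compose gamma(a*) with the active fraction explicitly
  oracle <- vapply(phis, function(f)
    translational_efficiency(bisect_steady_a(f, p), p) * (f - p$phiR_min),
    numeric(1))
  expect_equal(lam, oracle, tolerance = 1e-10)
  expect_equal(growth_rate_at(p$phiR_min, p), 0)
  expect_equal(growth_rate_at(p$phiR_max, p), 0)
  expect_lt(growth_rate_at(p$phiR_max - 1e-7, p), 1e-3)
})

test_that("closed-form optimum matches hand arithmetic and its limits", {
  cf <- closed_form_optimum(p_narrow)
  expect_equal(cf$lambda_hat, 5.9 * 2.5 * 0.48 / 8.4, tolerance = 1e-12)
  # brute-force intersection of the two law lines
  inter <- uniroot(function(phi) 5.9 * (phi - 0.07) - 2.5 * (0.55 - phi),
                   c(0.07, 0.55), tol = 1e-14)$root
  expect_equal(cf$phiR_hat, inter, tolerance = 1e-10)
  expect_equal(5.9 * (inter - 0.07), cf$lambda_hat, tolerance = 1e-10)
  # symmetric efficiencies put the optimum at the midpoint
  cfs <- closed_form_optimum(update_params(p_narrow, nu0 = 5.9))
  expect_equal(cfs$phiR_hat, (0.07 + 0.55) / 2)
  # unlimited supply: translation-limited growth at full allocation
  cfi <- closed_form_optimum(update_params(p_narrow, nu0 = 1e9))
  expect_equal(cfi$lambda_hat, 5.9 * 0.48, tolerance = 1e-6)
  expect_equal(cfi$phiR_hat, 0.55, tolerance = 1e-6)
})

test_that("allocation optimum is interior, bounded by the plateau limit,
           and monotone in the driving parameters", {
  opt <- optimize_allocation(p_narrow)
  expect_gt(opt$phiR_opt, p_narrow$phiR_min)
  expect_lt(opt$phiR_opt, p_narrow$phiR_max)
  expect_lt(opt$lambda_opt, opt$lambda_hat)
  # unimodality: the profile rises then falls around the reported optimum
  phis <- seq(0.08, 0.54, length.out = 41)
  lam <- growth_rate_at(phis, p_narrow)
  i <- which.max(lam)
  expect_true(all(diff(lam[1:i]) > 0) && all(diff(lam[i:length(lam)]) < 0))
  expect_lt(abs(phis[i] - opt$phiR_opt), diff(phis[1:2]))

  lam_of <- function(p) optimize_allocation(p)$lambda_opt
  base <- opt$lambda_opt
  expect_gt(lam_of(update_params(p_narrow, gamma0 = 7)), base)
  expect_gt(lam_of(update_params(p_narrow, nu0 = 3.3)), base)
  expect_gt(lam_of(update_params(p_narrow, K_nu = 5e-3)), base)
  expect_gt(lam_of(update_params(p_narrow, phiR_max = 0.6)), base)

  degen <- optimize_allocation(update_params(p_narrow, nu0 = 0))
  expect_true(degen$degenerate)
  expect_equal(degen$lambda_opt, 0)
})

test_that("optimum approaches the closed-form bound as the thresholds
           separate", {
  gaps <- vapply(c(5e-4, 5e-2, 1), function(Kn) {
    p <- update_params(p_narrow, K_nu = Kn)
    opt <- optimize_allocation(p)
    1 - opt$lambda_opt / opt$lambda_hat
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)  # ratio 1e4
})

test_that("optimality plateau contains the optimum, shrinks with rel_tol
           and widens with threshold separation", {
  opt <- optimize_allocation(p_narrow)
  pb <- opt$plateau
  expect_true(pb$a_lo <= opt$a_opt && opt$a_opt <= pb$a_hi)
  tiny <- plateau_band(p_narrow, rel_tol = 1e-4, phiR_opt = opt$phiR_opt)
  expect_lt(tiny$log10_width, pb$log10_width)
  expect_equal(tiny$a_lo, opt$a_opt, tolerance = 1e-2)
  # monotone non-shrinking in K_nu
  w <- vapply(c(5e-4, 1e-3, 5e-3, 5e-2), function(Kn) {
    p <- update_params(p_narrow, K_nu = Kn)
    plateau_band(p)$log10_width
  }, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("flux-balance curve phiR_balance spans the bounds monotonically
           and inverts the solver", {
  a <- 10^seq(-7, 0, length.out = 100)
  fb <- phiR_balance(a, p_narrow)
  expect_true(all(diff(fb) <= 0))
  expect_equal(phiR_balance(0, p_narrow), p_narrow$phiR_max)
  # consistency: a*(phiR_balance(a)) recovers a
  for (ai in c(1e-5, 5e-4, 1e-2)) {
    phi <- phiR_balance(ai, p_narrow)
    expect_equal(solve_steady_amino_acid(phi, p_narrow), ai,
                 tolerance = 1e-9)
  }
})
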