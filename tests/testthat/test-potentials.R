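test_that("wfAlpha matches the closed form and its scale invariance", {
  expect_equal(wfAlpha(1, 3, 1, 1), 18 * (3 / 16)^3, tolerance = 1e-14)
  expect_equal(wfAlpha(0.5, 1.5, 2, 1), wfAlpha(2, 6, 2, 1),
               tolerance = 1e-14)
  expect_error(wfAlpha(1, 0.9, 1, 1), "exceed sigma")
})

test_that("canonical potential vanishes at sigma and R and has depth -eps", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      sp <- randomSpec()
      expect_equal(wfPotential(sp@sigma, sp), 0, tolerance = 1e-12)
      expect_equal(wfPotential(sp@R, sp), 0, tolerance = 1e-12)
      expect_gt(wfPotential(0.8 * sp@sigma, sp), 0)  # repulsive core
      opt <- optimize(function(r) wfPotential(r, sp),
                      c(sp@sigma, sp@R), tol = 1e-12)
      expect_equal(opt$objective, -sp@eps, tolerance = 1e-7)
      expect_equal(opt$minimum, sp@rstar, tolerance = 1e-5)
    }
  })
})

test_that("rStar closed form agrees with numerical root-finding", {
  expect_equal(rStar(1, 3, 1, 1), 3 * sqrt(3 / 19), tolerance = 1e-14)
  withr::with_seed(22, {
    for (rep in 1:20) {
      mu <- runif(1, 1, 5); nu <- runif(1, 1, 5)
      sigma <- runif(1, 0.3, 1); R <- 3 * sigma
      ra <- rStar(sigma, R, mu, nu)
      rn <- rStar(sigma, R, mu, nu, method = "numeric")
      expect_lt(abs(ra - rn) / ra, 1e-10)
      expect_true(ra > sigma && ra < R)
    }
  })
})

test_that("extremum magnitude equals |eps| on both branches", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      sp <- randomSpec()
      expect_equal(abs(pairPotential(sp@rstar, sp)), abs(sp@eps),
                   tolerance = 1e-10)
      rp <- randomRepulsiveSpec()
      # at r* the shifted branch touches zero: |phi_WF(r*)| = |eps|
      expect_equal(pairPotential(rp@rstar * (1 - 1e-9), rp), 0,
                   tolerance = 1e-6)
    }
  })
})

test_that("repulsive branch is zero beyond r*, non-negative, divergent, monotone", {
  sp <- pairPotentialSpec(-0.5, 1, mu = 1, nu = 1, R = 3)
  expect_identical(repulsiveWF(c(sp@rstar, 2, 2.9, 5), sp), rep(0, 4))
  r <- seq(0.05, sp@rstar * 0.9999, length.out = 400)
  v <- repulsiveWF(r, sp)
  expect_true(all(v >= 0))
  expect_true(all(diff(v) <= 1e-12))              # monotone non-increasing
  expect_gt(repulsiveWF(0.9, sp), repulsiveWF(0.99, sp))
  expect_gt(repulsiveWF(0.02, sp), 1e4)           # divergence at contact
  expect_error(repulsiveWF(1, randomSpec()), "eps < 0")
  expect_error(wfPotential(1, sp), "eps >= 0")
  expect_error(repulsiveWF(-1, sp), "> 0")
})

test_that("forces are exact derivatives of energies (finite differences)", {
  withr::with_seed(24, {
    for (rep in 1:20) {
      sp <- if (rep %% 2) randomSpec() else randomRepulsiveSpec()
      cutoff <- if (sp@eps >= 0) sp@R else sp@rstar
      r <- runif(5, 0.6 * sp@sigma, 0.98 * cutoff)
      h <- 1e-6
      fd <- (pairPotential(r + h, sp) - pairPotential(r - h, sp)) / (2 * h)
      an <- pairPotential(r, sp, deriv = TRUE)
      expect_equal(an, fd, tolerance = 1e-6)
    }
  })
})

test_that("yukawa has the right sign, screening limit and Coulomb limit", {
  r <- seq(0.2, 3, by = 0.2)
  expect_true(all(yukawa(r, 1, 1, kappa = 1, eps = 78.4) > 0))
  expect_true(all(yukawa(r, 1, -1, kappa = 1, eps = 78.4) < 0))
  expect_lt(yukawa(0.5, 1, 1, kappa = 100, eps = 78.4), 1e-10)
  # kappa = 0 reduces to bare Coulomb in the chosen unit system:
  # e^2/(4 pi eps0) = 138.935458 kJ/mol nm = 33.2063 kcal/mol nm
  coulomb <- 138.935458 / 4.184 / 78.4 / 0.71
  expect_equal(yukawa(0.71, 1, 1, kappa = 0, eps = 78.4), coulomb,
               tolerance = 1e-6)
  # derivative consistent with finite differences
  h <- 1e-7
  fd <- (yukawa(0.9 + h, 1, 1, 1.27, 78.4) -
           yukawa(0.9 - h, 1, 1, 1.27, 78.4)) / (2 * h)
  expect_equal(yukawa(0.9, 1, 1, 1.27, 78.4, deriv = TRUE), fd,
               tolerance = 1e-6)
  expect_identical(yukawa(4, 1, 1, 0, 78.4), 0)  # beyond cutoff
})

test_that("pairTable samples the correct branch with consistent forces", {
  spA <- pairPotentialSpec(0.8, 0.6)
  spR <- pairPotentialSpec(-0.3, 0.6)
  r <- seq(0.3, 1.9, length.out = 200)
  tabA <- pairTable(spA, r)
  tabR <- pairTable(spR, r)
  expect_true(all(tabA$energy[r >= spA@R] == 0))
  expect_true(all(tabR$energy >= 0))
  expect_true(all(tabR$energy[r >= spR@rstar] == 0))
  mid <- r[c(50, 120)]
  h <- 1e-6
  fd <- -(pairPotential(mid + h, spA) - pairPotential(mid - h, spA)) /
    (2 * h)
  expect_equal(tabA$force[c(50, 120)], fd, tolerance = 1e-6)
  expect_error(pairTable(spA, numeric(0)), "empty")
  expect_error(pairTable(spA, c(1, 0.5)), "increasing")
})

test_that("energy and cutoff scale correctly under (sigma, R, r) -> c*(...)", {
  sp1 <- pairPotentialSpec(0.7, 0.5, mu = 2, nu = 1, R = 1.5)
  sp2 <- pairPotentialSpec(0.7, 1.0, mu = 2, nu = 1, R = 3.0)
  r <- seq(0.3, 1.45, length.out = 50)
  expect_equal(pairPotential(r, sp1), pairPotential(2 * r, sp2),
               tolerance = 1e-12)
  expect_equal(sp2@rstar, 2 * sp1@rstar, tolerance = 1e-12)
})
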