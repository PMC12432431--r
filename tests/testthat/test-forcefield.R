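test_that("Kell water density matches steam-table values and peaks near 4 C", {
  expect_equal(waterDensity(298.15), 0.99705, tolerance = 1e-4)
  Tg <- seq(273.15, 373, by = 0.1)
  rho <- waterDensity(Tg)
  expect_true(all(waterDensity(277.13) >= rho))
  expect_error(waterDensity(250), "outside")
  expect_error(waterDensity(380), "outside")
})

test_that("dielectric model tracks tabulated water permittivity", {
  expect_equal(dielectric(298.15), 78.4, tolerance = 0.02)
  Tg <- seq(273.15, 373, by = 1)
  eps <- dielectric(Tg)
  expect_true(all(diff(eps) < 0))      # monotone decreasing, like water
  expect_true(all(abs(eps - waterPermittivityTable(Tg)) /
                    waterPermittivityTable(Tg) < 0.02))
  # limiting case: no solvent-dependent parameter means vacuum
  expect_equal(dielectric(300, list(d0 = 0, d1 = 0)), 1)
})

test_that("inverse Debye length follows the closed-form electrolyte law", {
  salt <- data.frame(z = c(1, -1), c = c(0.15, 0.15))
  kappa <- inverseDebyeLength(298.15, salt, eps = 78.4)
  expect_equal(1 / kappa, 0.78, tolerance = 0.015)

  expect_equal(inverseDebyeLength(298.15, data.frame(z = c(1, -1),
                                                     c = c(0, 0)),
                                  eps = 78.4), 0)
  # square-root law: quadrupling all concentrations doubles kappa
  expect_equal(inverseDebyeLength(298.15, transform(salt, c = 4 * c),
                                  eps = 78.4), 2 * kappa,
               tolerance = 1e-12)
  expect_error(inverseDebyeLength(298.15, data.frame(z = 1, c = -0.1),
                                  eps = 78.4), "concentrations")
  # kappa^2 * eps * T is invariant in eps and T at fixed composition
  k1 <- inverseDebyeLength(280, salt, eps = 85)
  k2 <- inverseDebyeLength(360, salt, eps = 60)
  expect_equal(k1^2 * 85 * 280, k2^2 * 60 * 360, tolerance = 1e-10)
})

test_that("mu is the parabola a T^2 + b T + c", {
  expect_equal(muT(321, list(a = 0, b = 0, c = 5)), 5)
  expect_equal(muT(10, list(a = 1, b = 2, c = 3)), 123)
  f <- defaultModelParams(2)$functionals["V", ]
  expect_equal(muT(f$Tref, f) - muT(f$Tref, f), 0)
})

test_that("pair well depths anchor at the homotypic mean at Tref", {
  p <- defaultModelParams(1)
  res <- p$residues
  Tref <- 298.15
  for (i in res$code) for (j in res$code) {
    expect_equal(epsilonPair(Tref, i, j, p),
                 mean(res[c(i, j), "eps"]), tolerance = 1e-12,
                 label = paste(i, j))
  }
})

test_that("pair well depths are symmetric and scale only hydrophobic pairs", {
  p <- defaultModelParams(3)
  withr::with_seed(5, {
    for (rep in 1:25) {
      i <- sample(p$residues$code, 1); j <- sample(p$residues$code, 1)
      Tk <- runif(1, 273, 373)
      expect_equal(epsilonPair(Tk, i, j, p), epsilonPair(Tk, j, i, p),
                   tolerance = 1e-14)
    }
  })
  # pairs with no hydrophobic member are temperature-invariant
  for (pair in list(c("G", "S"), c("K", "E"), c("F", "Y"))) {
    expect_identical(epsilonPair(280, pair[1], pair[2], p),
                     epsilonPair(360, pair[1], pair[2], p))
  }
  # hydrophobic-containing pairs move with T in this parameterization
  expect_gt(epsilonPair(360, "V", "L", p), epsilonPair(280, "V", "L", p))
  expect_gt(epsilonPair(360, "V", "S", p), epsilonPair(280, "V", "S", p))
})

test_that("epsilon formula reproduces hand-computed synthetic case", {
  # eps_ii = 1, eps_jj = 2, alpha_i = 1, alpha_j = 0,
  # mu_i(T) - mu_i(Tref) = 0.4  ->  eps_ij = 0.5*1.4 + 0.5*2 = 1.7
  p <- defaultModelParams(1)
  p$residues["V", "eps"] <- 1
  p$residues["L", "eps"] <- 2
  # linear mu with slope s: mu(T)-mu(Tref) = s*(T-Tref); pick T for 0.4
  s <- p$functionals["V", "b"]
  p$functionals["V", "alpha"] <- 1
  p$functionals["L", "alpha"] <- 0
  Tq <- 298.15 + 0.4 / s
  p$solvent$Trange <- c(273, 500)  # allow the probe temperature
  expect_equal(epsilonPair(Tq, "V", "L", p), 1.7, tolerance = 1e-10)
})

test_that("a hydrophobic residue without a functional is an error", {
  p <- defaultModelParams(1)
  p$functionals <- p$functionals[p$functionals$code != "M", ]
  expect_error(epsilonPair(320, "M", "G", p), "missing temperature functional")
})

test_that("alpha = 0 freezes the temperature dependence", {
  p <- defaultModelParams(1)
  p$functionals$alpha <- 0
  expect_equal(epsilonPair(280, "V", "L", p), epsilonPair(360, "V", "L", p))
})

test_that("resolvePair assembles a valid spec with R = 3 sigma", {
  p <- defaultModelParams(1)
  sp <- resolvePair(320, "V", "L", p)
  expect_s4_class(sp, "PairPotentialSpec")
  expect_equal(sp@sigma, mean(p$residues[c("V", "L"), "sigma"]))
  expect_equal(sp@R, 3 * sp@sigma)
  expect_equal(sp@eps, epsilonPair(320, "V", "L", p))
})
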