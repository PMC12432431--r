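test_that("Flory relation reproduces direct substitution and power-law scaling", {
  # nu = 0.5, N = 100, b = 0.55 nm
  expected <- 0.55 * 10 * sqrt(1.1615 * 2.1615 / (2 * 2.1615 * 3.1615))
  expect_equal(rgFromNu(0.5, 100), expected, tolerance = 1e-12)
  # S ~ N^nu exactly
  for (nu in c(0.3, 0.55, 0.8))
    expect_equal(rgFromNu(nu, 400) / rgFromNu(nu, 200), 2^nu,
                 tolerance = 1e-12)
  # monotone increasing in nu at fixed N
  nus <- seq(0.1, 0.9, by = 0.02)
  expect_true(all(diff(rgFromNu(nus, 50)) > 0))
  expect_error(rgFromNu(1.2, 50), "nu")
})

test_that("Flory inversion is a bijection on the admissible range", {
  for (N in c(20, 84, 150, 800)) {
    for (nu in seq(0.1, 0.9, by = 0.1)) {
      S <- rgFromNu(nu, N)
      expect_lt(abs(nuFromRg(S, N) - nu), 1e-8)
    }
  }
  # out-of-range radii are rejected with the attainable bounds
  expect_error(nuFromRg(0.9 * rgFromNu(0.051, 100), 100), "outside")
  expect_error(nuFromRg(1.1 * rgFromNu(0.949, 100), 100), "outside")
  # larger S at fixed N gives larger nu
  S <- rgFromNu(c(0.3, 0.5, 0.7), 150)
  nus <- vapply(S, nuFromRg, numeric(1), N = 150)
  expect_true(all(diff(nus) > 0))
})

test_that("theta temperature interpolates the nu = 0.5 crossing", {
  s <- new("NuSeries", temperatures = c(310, 320), nu = c(0.55, 0.45),
           se = c(NA_real_, NA_real_))
  th <- thetaTemperature(s)
  expect_equal(as.numeric(th), 315)
  expect_equal(attr(th, "transition"), "LCST-like")

  sUp <- new("NuSeries", temperatures = c(310, 320, 330),
             nu = c(0.4, 0.48, 0.56), se = rep(NA_real_, 3))
  thUp <- thetaTemperature(sUp)
  expect_equal(as.numeric(thUp), 320 + 10 * 0.02 / 0.08)
  expect_equal(attr(thUp, "transition"), "UCST-like")

  sNone <- new("NuSeries", temperatures = c(310, 320), nu = c(0.6, 0.55),
               se = rep(NA_real_, 2))
  expect_true(is.na(thetaTemperature(sNone)))

  sMulti <- new("NuSeries", temperatures = c(300, 310, 320, 330),
                nu = c(0.55, 0.45, 0.55, 0.45), se = rep(NA_real_, 4))
  expect_warning(thM <- thetaTemperature(sMulti), "multiple")
  expect_equal(as.numeric(thM), 305)
})

test_that("nuSeries converts Rg data and closes the loop with the generator", {
  tab <- syntheticRgCurve(N = 128, nuStart = 0.6, nuEnd = 0.4,
                          TGrid = seq(280, 370, by = 10))
  s <- nuSeries(tab$T, tab$rg, N = 128)
  expect_equal(s@nu, tab$nuTrue, tolerance = 1e-8)
  th <- thetaTemperature(s)
  # nu crosses 0.5 halfway along the linear ramp
  expect_equal(as.numeric(th), 325, tolerance = 0.5)
  expect_equal(attr(th, "transition"), "LCST-like")
})

test_that("CLOUD-FIT detects the spike onset and handles edge cases", {
  profs <- syntheticProfiles(seq(275, 370, by = 5), spikeOnsetT = 320,
                             seed = 2L)
  expect_equal(cloudFit(profs), 320)

  flat <- syntheticProfiles(seq(275, 315, by = 5), spikeOnsetT = 1000,
                            seed = 3L)
  expect_true(is.na(cloudFit(flat)))

  # spike already present at the lowest scanned temperature
  low <- syntheticProfiles(seq(300, 320, by = 5), spikeOnsetT = 290,
                           seed = 4L)
  expect_warning(cp <- cloudFit(low), "lowest scanned")
  expect_equal(cp, 300)

  expect_error(cloudFit(rev(profs)), "ascending")
  shuffled <- profs
  shuffled[[2]] <- new("DensityProfile", temperature = 280,
                       binCenters = profs[[2]]@binCenters[1:50],
                       densities = profs[[2]]@densities[, 1:50],
                       frameTimes = profs[[2]]@frameTimes)
  expect_error(cloudFit(shuffled), "binning")
})

test_that("coexistence densities recover plateau values from slab profiles", {
  # sharp step profile 0.05 / 0.60
  z <- seq(0.5, 99.5, by = 1)
  dens <- ifelse(z > 35 & z < 65, 0.60, 0.05)
  prof <- new("DensityProfile", temperature = 320, binCenters = z,
              densities = rbind(dens, dens), frameTimes = c(1, 2))
  cx <- coexistenceDensities(prof)
  expect_equal(unname(cx["rhoDilute"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(cx["rhoDense"]), 0.60, tolerance = 1e-6)

  # tanh-smoothed interfaces recovered within 1%
  smooth <- 0.05 + (0.60 - 0.05) / 2 *
    (tanh(z - 35) - tanh(z - 65))
  profS <- new("DensityProfile", temperature = 320, binCenters = z,
               densities = rbind(smooth), frameTimes = 1)
  cxS <- coexistenceDensities(profS)
  expect_equal(unname(cxS["rhoDilute"]), 0.05, tolerance = 0.01)
  expect_equal(unname(cxS["rhoDense"]), 0.60, tolerance = 0.01)

  # a uniform profile is a single phase
  flat <- new("DensityProfile", temperature = 320, binCenters = z,
              densities = rbind(rep(0.3, length(z))), frameTimes = 1)
  expect_error(coexistenceDensities(flat), "single phase")

  # dense slab wrapped across the periodic boundary
  densW <- ifelse(z < 15 | z > 85, 0.60, 0.05)
  profW <- new("DensityProfile", temperature = 320, binCenters = z,
               densities = rbind(densW), frameTimes = 1)
  cxW <- coexistenceDensities(profW)
  expect_equal(unname(cxW["rhoDense"]), 0.60, tolerance = 1e-6)
})

test_that("binodal fitting recovers generator parameters", {
  ds <- syntheticBinodal(Tc = 300, rhoc = 0.3, noiseSd = 0, mode = "LCST")
  fit <- fitBinodal(ds)
  cp <- criticalPoint(fit)
  expect_lt(abs(cp["Tc"] - 300), 0.1)
  expect_lt(abs(cp["rhoc"] - 0.3), 0.001)

  # UCST branch handled with T < Tc
  dsU <- syntheticBinodal(Tc = 350, rhoc = 0.25, noiseSd = 0,
                          mode = "UCST")
  cpU <- criticalPoint(fitBinodal(dsU))
  expect_lt(abs(cpU["Tc"] - 350), 0.1)
  expect_true(all(coexPoints(dsU)$T < 350))

  expect_error(fitBinodal(syntheticBinodal(TOffsets = c(5, 10))),
               "at least 3")
  expect_error(criticalPoint(ds), "not been fitted")
})

test_that("binodal fitting is robust to 1% multiplicative noise", {
  errs <- vapply(1:20, function(s) {
    ds <- syntheticBinodal(Tc = 300, rhoc = 0.3, noiseSd = 0.01, seed = s)
    abs(criticalPoint(fitBinodal(ds))["Tc"] - 300)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("block statistics follow the 3-block error convention", {
  st <- blockStats(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_equal(unname(st["mean"]), 2)
  expect_equal(unname(st["se"]), 1 / sqrt(3))

  expect_equal(unname(blockStats(rep(7, 30))["se"]), 0)

  # permuting values within one block leaves the result unchanged
  x <- c(4, 5, 6, 1, 2, 3, 9, 8, 7)
  y <- c(6, 5, 4, 1, 2, 3, 9, 8, 7)
  expect_equal(blockStats(x), blockStats(y))

  # remainder joins the last block
  st10 <- blockStats(1:10)
  expect_equal(unname(st10["mean"]),
               mean(c(mean(1:3), mean(4:6), mean(7:10))))
  expect_error(blockStats(c(1, 2), 3), "shorter")
})

test_that("absorbance cloud points interpolate the 0.301 threshold", {
  # -log10(0.5) = 0.3010300; crossing from 0.0 to 0.602 over 300-310 K
  expect_equal(cloudPointFromAbsorbance(c(300, 310), c(0, 0.602)),
               300 + 10 * (-log10(0.5)) / 0.602, tolerance = 1e-10)
  expect_warning(
    cp <- cloudPointFromAbsorbance(c(300, 310), c(0.5, 0.9)), "boundary")
  expect_equal(cp, 300)
  expect_error(cloudPointFromAbsorbance(c(300, 310, 320),
                                        c(0.29, 0.2, 0.1)), "never crosses")
})

test_that("model RMSD matches its closed form and is order-invariant", {
  expect_equal(modelRmsd(c(300, 310), c(300, 310)), 0)
  expect_equal(modelRmsd(300, 310), 10)
  a <- c(300, 320, 340); b <- c(305, 315, 350)
  perm <- c(3, 1, 2)
  expect_equal(modelRmsd(a, b), modelRmsd(a[perm], b[perm]))
  expect_error(modelRmsd(c(300, 310), 300), "equal length")
})
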