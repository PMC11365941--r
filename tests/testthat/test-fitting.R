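fastTimes <- c(2, 10, 20, 30, 40)

test_that("cost is zero for self-consistent targets and shifts quadratically", {
  ly <- threeLayout()
  tr <- spineSizes(simulateSpines(ly, refParams, times = fastTimes,
                                  dt = 0.05))
  expect_lt(spineCost(refParams, ly, tr, fastTimes), 1e-20)

  sham <- spineLayout(c(0, 1.6, 3.2), rep(TRUE, 3), paradigm = "sham")
  expect_identical(spineCost(refParams, sham,
                             matrix(1, 3, length(fastTimes)), fastTimes), 0)

  # shifting every target by +0.1 costs 0.01 per (spine, time) point
  k <- length(tr)
  expect_equal(spineCost(refParams, ly, tr + 0.1, fastTimes), 0.01 * k,
               tolerance = 1e-10)
})

test_that("cost is invariant to spine relabelling and layout reflection", {
  ly <- referenceLayout("seven")
  tr <- spineSizes(simulateSpines(ly, refParams, times = fastTimes,
                                  dt = 0.05))
  c0 <- spineCost(refParams, ly, tr, fastTimes)
  mir <- spineLayout(100 - rev(ly@position), rev(ly@stimulated),
                     paradigm = "seven", nHat = 7)
  cMir <- spineCost(refParams, mir, tr[rev(seq_len(nrow(tr))), ], fastTimes)
  expect_lt(abs(cMir - c0), 1e-6)  # equal up to grid-placement rounding
})

test_that("adjoint gradients match central finite differences at random points", {
  ly <- spineLayout(c(0, 2), c(TRUE, TRUE), paradigm = "three")
  target <- matrix(1.2, 2, 3)
  times <- c(2, 6, 10)
  v0 <- paramValues(refParams)
  set.seed(7)
  worst <- 0
  for (rep in 1:10) {
    fac <- exp(runif(length(FIT_PARAM_NAMES), log(0.6), log(1.6)))
    vals <- v0[FIT_PARAM_NAMES] * fac
    vals["nu"] <- max(vals["nu"], 1.05)
    p <- do.call(updateParameters, c(list(refParams), as.list(vals)))
    chk <- gradientCheck(p, ly, target, times, dt = 0.05, pad = 12)
    worst <- max(worst, chk$rel_diff)
  }
  expect_lt(worst, 1e-3)
})

test_that("multi-start fitting is deterministic and start-monotone", {
  ly <- threeLayout()
  target <- spineSizes(simulateSpines(ly, refParams, times = fastTimes,
                                      dt = 0.1))
  mkCfg <- function(k) fitConfig(nRestarts = k, seed = 11, dt = 0.1,
                                 maxit = 15)
  f2a <- fitModel(target, ly, mkCfg(2), times = fastTimes)
  f2b <- fitModel(target, ly, mkCfg(2), times = fastTimes)
  expect_identical(paramValues(fittedParameters(f2a)),
                   paramValues(fittedParameters(f2b)))
  expect_identical(fitCost(f2a), fitCost(f2b))

  f3 <- fitModel(target, ly, mkCfg(3), times = fastTimes)
  expect_lte(fitCost(f3), fitCost(f2a))  # extra restart can only improve
  # same seed stream prefix: first two restarts coincide
  expect_equal(f3@restarts$cost[1:2], f2a@restarts$cost, tolerance = 1e-12)
})

test_that("a fit started at the generating parameters stays at the optimum", {
  ly <- threeLayout()
  target <- spineSizes(simulateSpines(ly, refParams, times = fastTimes,
                                      dt = 0.1))
  fit <- fitModel(target, ly,
                  fitConfig(nRestarts = 1, seed = 3, dt = 0.1, maxit = 25),
                  times = fastTimes)  # restart 1 starts at the reference set
  expect_lt(fitCost(fit), 1e-6)
  expect_lt(max(abs(fit@trajectory - target)), 2e-2)
})

test_that("drug-variant fits free only the susceptibilities with directional bounds", {
  ly <- referenceLayout("single")
  # a weaker-decay single-spine target, as under calcineurin block
  slow <- updateParameters(refParams, zeta2 = 0.15)
  target <- spineSizes(simulateSpines(ly, slow, times = fastTimes, dt = 0.1))
  cfg <- fitConfig(nRestarts = 2, seed = 5, dt = 0.1, maxit = 25)
  fit <- fitDrugVariant(target, refParams, "FK506", ly, cfg,
                        times = fastTimes)
  vb <- paramValues(refParams); vf <- paramValues(fittedParameters(fit))
  frozen <- setdiff(names(vb), c("zeta1", "zeta2"))
  expect_identical(vf[frozen], vb[frozen])
  expect_gte(vf[["zeta1"]], vb[["zeta1"]] * (1 - 1e-9))  # ratio increased
  expect_lte(vf[["zeta2"]], vb[["zeta2"]] * (1 + 1e-9))

  aip <- fitDrugVariant(target, refParams, "AIP", ly,
                        fitConfig(nRestarts = 1, seed = 5, dt = 0.1,
                                  maxit = 10), times = fastTimes)
  va <- paramValues(fittedParameters(aip))
  expect_lte(va[["zeta1"]], vb[["zeta1"]] * (1 + 1e-9))  # ratio decreased
  expect_gte(va[["zeta2"]], vb[["zeta2"]] * (1 - 1e-9))
  expect_lte(va[["nu"]], vb[["nu"]] * (1 + 1e-9))        # threshold lowered

  # freezing every parameter skips optimisation and returns the base cost
  cfg0 <- fitConfig(nRestarts = 1, seed = 1, dt = 0.1)
  cfg0$free <- character()
  f0 <- fitModel(target, ly, cfg0, times = fastTimes, start = refParams)
  expect_equal(fitCost(f0),
               spineCost(refParams, ly, target, fastTimes, dt = 0.1))
})

test_that("drug-variant parameter changes move trajectories as observed", {
  ly <- referenceLayout("single")
  ctrl <- spineSizes(simulateSpines(ly, refParams))[1, ]
  # calcineurin block: weaker slow-resource action, slower decay after peak
  fk <- spineSizes(simulateSpines(
    ly, updateParameters(refParams, zeta2 = 1e-12)))[1, ]
  decay <- function(tr) max(tr) - tr[length(tr)]
  expect_lt(decay(fk), decay(ctrl))
  # CaMKII block: stronger depression, lower threshold: smaller peak
  aip <- spineSizes(simulateSpines(
    ly, updateParameters(refParams, zeta1 = 0.7 * 0.177,
                         zeta2 = 1.6 * 0.45, nu = 1.22)))[1, ]
  expect_lt(max(aip), max(ctrl))
})

test_that("forward prediction reuses the fitted parameters unchanged", {
  ly <- threeLayout()
  pred <- predictParadigm(refParams, ly, times = fastTimes, dt = 0.05)
  direct <- simulateSpines(ly, refParams, times = fastTimes, dt = 0.05)
  expect_identical(spineSizes(pred), spineSizes(direct))

  # denser co-located stimulation lowers the early mean response
  s3 <- mean(spineSizes(predictParadigm(refParams, colocLayout(3, "three"),
                                        times = 2))[, 1])
  s15 <- mean(spineSizes(predictParadigm(refParams,
                                         colocLayout(15, "fifteen"),
                                         times = 2))[, 1])
  expect_lt(s15, s3)
})
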