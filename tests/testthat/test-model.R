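test_that("initial fast-resource profile matches the kernel sum", {
  p <- refParams
  single <- spineLayout(0, TRUE, paradigm = "single")
  g <- makeGrid(single)
  C0 <- initialC(g, single, p)
  v <- paramValues(p)
  node <- which.min(abs(gridPoints(g)))
  expect_equal(C0[node], v[["C_s"]] + v[["C_d"]])      # D = 1, exp(0) = 1
  expect_lt(C0[1], 1e-12)                              # Gaussian tail

  co <- colocLayout(3, "three")
  g3 <- makeGrid(co)
  C0co <- initialC(g3, co, p)
  expect_equal(max(C0co), 3 * v[["C_s"]] + v[["C_d"]]) # 3 (C_s + C_d/3)

  expect_error(initialC(makeGrid(single, spacing = 0.5), single, p),
               "too coarse")
})

test_that("initial inactive-resource profile depletes by share and clamps at zero", {
  p <- refParams
  v <- paramValues(p)
  single <- spineLayout(0, TRUE, paradigm = "single")
  g <- makeGrid(single)
  expect_equal(initialPin(g, single, p), rep(v[["rho"]], g@nPoints))  # D = 1

  # an isolated site with share exactly 1/2 (one competing unstimulated
  # spine): trough depth is half the baseline
  half <- spineLayout(0, TRUE, paradigm = "single", nHat = 1)
  Pin <- initialPin(g, half, p)
  node <- which.min(abs(gridPoints(g)))
  expect_equal(Pin[node], v[["rho"]] / 2)

  # three co-located spines deplete (1 - 1/3) each: raw trough rho*(1-2) < 0
  co <- colocLayout(3, "three")
  g3 <- makeGrid(co)
  Pco <- initialPin(g3, co, p)
  expect_equal(min(Pco), 0)
  expect_true(all(Pco >= 0))
})

test_that("decision function switches sign at the size threshold", {
  expect_equal(decisionF(1.4, phi = 2, nu = 1.4), 0)
  expect_equal(decisionF(1e6, phi = 2, nu = 1.4), -1)
  expect_equal(decisionF(1.0, phi = 2, nu = 1.4), tanh(0.8))
  expect_error(decisionF(1, phi = 0, nu = 1.4), "phi")
})

test_that("integrator reproduces the diffusing-decaying Gaussian closed form", {
  # C decoupled (beta2 = zeta1 = zeta2 = 0) from a unit Gaussian
  p <- modelParameters(beta2 = 1e-12, zeta1 = 0, zeta2 = 0,
                       alpha1 = 6, alpha2 = 1.2)
  ly <- spineLayout(0, TRUE, paradigm = "single")
  g <- makeGrid(ly, spacing = 0.125, pad = 30)
  x <- gridPoints(g)
  s0sq <- 1 / (2 * 4 * log(2))       # variance of the exp(-4 ln2 x^2) kernel
  C0 <- exp(-4 * log(2) * x^2)
  tEnd <- 4
  res <- integrateFields(g, C0, numeric(g@nPoints), params = p,
                         times = tEnd, dt = 0.02, storeFields = TRUE)
  vT <- s0sq + 2 * 6 * tEnd
  exact <- sqrt(s0sq / vT) * exp(-x^2 / (2 * vT)) * exp(-1.2 * tEnd)
  l2 <- sqrt(sum((res$field_C[, 1] - exact)^2) * gridSpacing(g))
  expect_lt(l2, 1e-3)
})

test_that("slow-resource mass is conserved without degradation", {
  p <- modelParameters(gamma = 0)
  ly <- threeLayout()
  g <- makeGrid(ly)
  C0 <- initialC(g, ly, p)
  Pin0 <- initialPin(g, ly, p)
  res <- integrateFields(g, C0, Pin0, params = p, times = c(10, 40),
                         dt = 0.02, storeFields = TRUE)
  m0 <- sum(Pin0)
  for (j in 1:2) {
    mT <- sum(res$field_Pin[, j] + res$field_P[, j])
    expect_lt(abs(mT - m0) / m0, 1e-6)
  }
})

test_that("all-zero resources are a fixed point with constant spine size", {
  ly <- spineLayout(0, TRUE, paradigm = "single")
  g <- makeGrid(ly)
  z <- numeric(g@nPoints)
  res <- integrateFields(g, z, z, params = refParams,
                         times = c(10, 40), dt = 0.05, storeFields = TRUE)
  expect_equal(max(abs(res$field_C)), 0)
  expect_equal(max(abs(res$field_P)), 0)
  expect_equal(res$field_S, matrix(1, g@nPoints, 2))
})

test_that("time-step halving and grid doubling leave trajectories unchanged within contract", {
  ly <- threeLayout()
  run <- function(dt, sp) spineSizes(simulateSpines(ly, refParams,
                                                    dt = dt, spacing = sp))
  base <- run(0.02, 0.125)
  expect_lt(max(abs(base - run(0.01, 0.125))), 1e-4)
  expect_lt(max(abs(base - run(0.02, 0.0625))), 1e-3)
})

test_that("integration reports blow-up with the offending time", {
  ly <- spineLayout(0, TRUE, paradigm = "single")
  g <- makeGrid(ly)
  # activation rate far beyond the explicit step's stability limit
  bad <- modelParameters(beta2 = 1e10)
  C0 <- initialC(g, ly, bad)
  Pin0 <- initialPin(g, ly, bad)
  expect_error(integrateFields(g, C0, Pin0, params = bad,
                               times = 10, dt = 0.05),
               "non-finite")
})

test_that("sham simulations stay at baseline", {
  sham <- spineLayout(c(0, 1.6, 3.2), rep(TRUE, 3), paradigm = "sham")
  res <- simulateSpines(sham, refParams)
  expect_true(all(spineSizes(res) == 1))
})

test_that("an isolated spine rises then decays with one interior maximum", {
  res <- simulateSpines(referenceLayout("single"), refParams)
  tr <- spineSizes(res)[1, ]
  pk <- which.max(tr)
  expect_gt(pk, 1)
  expect_lt(pk, length(tr))
  expect_gt(tr[pk], tr[1])
  expect_gt(tr[length(tr)], 1)             # ends above baseline
  expect_lt(tr[length(tr)], tr[pk])        # below its peak
  d <- diff(tr)
  expect_identical(sum(diff(sign(d)) != 0), 1L)  # single sign change
})

test_that("trajectories are invariant to reflecting the layout", {
  # positions on grid nodes so nearest-node sampling is identical
  pos <- seq(0, 10.5, by = 1.75)
  ly <- spineLayout(pos, rep(TRUE, 7), paradigm = "seven", nHat = 7)
  mirrored <- spineLayout(50 - rev(pos), rep(TRUE, 7),
                          paradigm = "seven", nHat = 7)
  a <- spineSizes(simulateSpines(ly, refParams, times = c(2, 20, 40)))
  b <- spineSizes(simulateSpines(mirrored, refParams, times = c(2, 20, 40)))
  expect_equal(unname(a), unname(b[rev(seq_len(nrow(b))), ]),
               tolerance = 1e-10)
})

test_that("windowed readout approximates the nearest-node readout", {
  ly <- referenceLayout("single")
  node <- spineSizes(simulateSpines(ly, refParams, times = c(2, 10)))
  win <- spineSizes(simulateSpines(ly, refParams, times = c(2, 10),
                                   window = 0.5))
  expect_equal(unname(win), unname(node), tolerance = 0.05)
})
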