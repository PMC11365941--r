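test_that("proximity sum matches hand-evaluated cases and domain checks", {
  single <- spineLayout(0, TRUE, paradigm = "single")
  expect_identical(proximitySum(single, lam = 2, i = 1), 0)

  two <- spineLayout(c(0, 1), c(TRUE, TRUE), paradigm = "three")
  expect_equal(proximitySum(two, lam = 1, i = 1), 0.5)  # (1/(1+1))^1

  co <- colocLayout(3, "three")
  for (i in 1:3) expect_equal(proximitySum(co, lam = 5, i = i), 0)

  mixed <- spineLayout(c(0, 1, 2), c(TRUE, FALSE, TRUE), paradigm = "three")
  expect_error(proximitySum(mixed, lam = 1, i = 2), "not a stimulated")
  expect_error(proximitySum(mixed, lam = 0, i = 1), "lam")
})

test_that("competing unstimulated spines require proximity to two sites", {
  base <- c(0, 4)  # two stimulation sites
  near2 <- spineLayout(c(base, 2), c(TRUE, TRUE, FALSE), paradigm = "three")
  expect_identical(countCompetingUnstim(near2, radius = 2), 1L)

  near1 <- spineLayout(c(base, 0.5), c(TRUE, TRUE, FALSE),
                       paradigm = "three")
  expect_identical(countCompetingUnstim(near1, radius = 2), 0L)

  none <- spineLayout(base, c(TRUE, TRUE), paradigm = "three")
  expect_identical(countCompetingUnstim(none), 0L)

  override <- spineLayout(base, c(TRUE, TRUE), paradigm = "seven", nHat = 7)
  expect_identical(countCompetingUnstim(override), 7L)
})

test_that("competition factors attain their analytic limits", {
  expect_equal(competitionFactors(spineLayout(0, TRUE), lam = 1)@D, 1)

  co <- competitionFactors(colocLayout(3, "three"), lam = 2)
  expect_equal(co@D, rep(1 / 3, 3))

  far <- spineLayout(c(0, 100), c(TRUE, TRUE), paradigm = "three")
  cf <- competitionFactors(far, lam = 1)
  expect_equal(cf@d, rep(100 / 101, 2))
  expect_equal(cf@D, rep((1 + 100 / 101) / 2, 2), tolerance = 1e-12)

  expect_error(competitionFactors(
    spineLayout(0, FALSE, paradigm = "sham"), lam = 1), "no stimulated")
})

test_that("competition factor invariants hold on random layouts", {
  set.seed(42)
  for (rep in 1:25) {
    nStim <- sample(2:15, 1)
    ly <- randomLayout(nStim, sample(0:10, 1), runif(1, 1, 40))
    lam <- runif(1, 0.3, 6)
    cf <- competitionFactors(ly, lam)
    expect_true(all(cf@d >= 0 & cf@d <= nStim - 1))
    lo <- 1 / (nStim + cf@nHat); hi <- nStim / (nStim + cf@nHat)
    expect_true(all(cf@D >= lo - 1e-12 & cf@D <= hi + 1e-12))

    # permutation invariance: relabelling spines preserves the D multiset
    perm <- sample(length(ly@position))
    ly2 <- spineLayout(ly@position[perm], ly@stimulated[perm],
                       paradigm = ly@paradigm)
    cf2 <- competitionFactors(ly2, lam)
    expect_equal(sort(cf2@D), sort(cf@D), tolerance = 1e-12)
  }
})

test_that("co-located share decreases with cluster size and recovers with distance", {
  # adding a co-located stimulated spine reduces every share
  D <- vapply(2:10, function(n)
    competitionFactors(colocLayout(n, "seven"), lam = 1)@D[1], numeric(1))
  expect_true(all(diff(D) < 0))

  # two spines decouple monotonically with separation
  Dsep <- vapply(c(10, 100), function(s) {
    competitionFactors(spineLayout(c(0, s), c(TRUE, TRUE),
                                   paradigm = "three"), lam = 1)@D[1]
  }, numeric(1))
  expect_true(Dsep[1] < Dsep[2])
  expect_true(Dsep[2] < 1)
})

test_that("edge/middle classification follows the published split", {
  sev <- referenceLayout("seven")
  expect_identical(unname(classifyEdgeMiddle(sev)),
                   c("edge", "edge", "middle", "middle", "middle",
                     "edge", "edge"))

  fif <- classifyEdgeMiddle(referenceLayout("fifteen"))
  expect_identical(sum(fif == "edge"), 8L)
  expect_identical(sum(fif == "middle"), 7L)

  thr <- classifyEdgeMiddle(threeLayout())
  expect_identical(unname(thr), c("edge", "middle", "edge"))

  # unordered positions are classified by sorted position, not input order
  shuffled <- spineLayout(c(3.2, 0, 1.6), rep(TRUE, 3), paradigm = "three")
  expect_identical(unname(classifyEdgeMiddle(shuffled)),
                   c("edge", "edge", "middle"))

  expect_error(classifyEdgeMiddle(spineLayout(0, TRUE)), "edgePerSide")
  expect_identical(unname(classifyEdgeMiddle(
    spineLayout(1:5, rep(TRUE, 5), paradigm = "single"), edgePerSide = 2)),
    c("edge", "edge", "middle", "edge", "edge"))
})
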