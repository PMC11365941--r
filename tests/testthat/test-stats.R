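test_that("baseline normalisation divides by the pre-stimulation mean", {
  mk <- function(vals) spineTrajectoryExperiment(
    matrix(vals, 1), c(-6, -4, -2, 2), "e1", "sp1", 0, TRUE)
  expect_equal(as.numeric(normalisedSize(normaliseTrajectories(
    mk(c(2, 2, 2, 3))))), c(1, 1, 1, 1.5))
  expect_equal(as.numeric(normalisedSize(normaliseTrajectories(
    mk(rep(5, 4))))), rep(1, 4))
  expect_equal(as.numeric(normalisedSize(normaliseTrajectories(
    mk(c(1, 2, 3, 4))))), c(0.5, 1, 1.5, 2))

  neg <- spineTrajectoryExperiment(matrix(c(-1, 0, 1, 2), 1),
                                   c(-6, -4, -2, 2), "e1", "spX", 0, TRUE)
  expect_error(normaliseTrajectories(neg), "spX")
  expect_error(normaliseTrajectories(mk(1:4), nPre = 2), "pre-stimulation")

  # pre-stimulation mean is exactly 1 after normalisation
  set.seed(1)
  raw <- matrix(rlnorm(50 * 10, 4, 0.3), 50)
  ste <- spineTrajectoryExperiment(raw, c(-6, -4, -2, seq(2, 14, 2)),
                                   rep("e", 50), paste0("s", 1:50),
                                   runif(50, 0, 10), rep(TRUE, 50))
  sz <- normalisedSize(normaliseTrajectories(ste))
  expect_lt(max(abs(rowMeans(sz[, 1:3]) - 1)), 1e-12)
  expect_true(all(sz > 0))
})

test_that("NMSE equals 1 at the per-snapshot mean and matches hand cases", {
  obs <- cbind(c(0, 2), c(1, 3))
  expect_identical(nmse(colMeans(obs), obs), 1)
  expect_equal(nmse(0, matrix(c(0, 2), 2, 1)), 2)  # ((0-0)^2+(0-2)^2)/2
  expect_equal(nmse(1, matrix(c(0, 2), 2, 1)), 1)  # prediction at the mean

  set.seed(2)
  big <- matrix(rnorm(400, 1.4, 0.1), 20)
  expect_equal(nmse(colMeans(big), big), 1, tolerance = 1e-12)
  expect_gt(nmse(colMeans(big) + 0.05, big), 1)

  # invariance to reordering observations within snapshots and snapshots
  pred <- colMeans(big) + 0.03
  shuf <- apply(big, 2, sample)
  expect_equal(nmse(pred, shuf), nmse(pred, big), tolerance = 1e-12)
  ord <- sample(ncol(big))
  expect_equal(nmse(pred[ord], big[, ord]), nmse(pred, big),
               tolerance = 1e-12)

  degen <- cbind(c(1, 1), c(0, 2))
  expect_warning(v <- nmse(c(1, 1), degen), "degenerate")
  expect_equal(v, 1)
})

test_that("weighted R-squared matches its reference points and hand case", {
  set.seed(3)
  obs <- matrix(rnorm(300, 1.3, 0.1), 15)
  m <- colMeans(obs)
  expect_equal(r2w(m, obs), 1)
  expect_equal(r2w(rep(mean(obs), ncol(obs)), obs), 0, tolerance = 1e-12)
  expect_lt(r2w(rev(m), obs), 1)

  # two snapshots, means (1, 2), equal variances, prediction swapped -> -3
  hand <- cbind(c(0.9, 1.1), c(1.9, 2.1))
  expect_equal(r2w(c(2, 1), hand), -3, tolerance = 1e-12)

  flat <- cbind(c(0.9, 1.1), c(1.1, 0.9))
  expect_error(r2w(c(1, 1), flat), "undefined")
})

test_that("Welch pairwise tests with BH adjustment behave on reference cases", {
  g <- rep(c("a", "b"), each = 3)
  out <- welchFdr(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(out$p_adj, 1)

  # family of one: BH is the identity
  set.seed(4)
  one <- welchFdr(c(rnorm(5), rnorm(5, 1)), g = rep(c("x", "y"), each = 5))
  expect_identical(one$p_adj, one$p)

  # BH never lowers a raw p and preserves pairs
  set.seed(5)
  vals <- rnorm(40, rep(c(0, 0.5, 1, 3), each = 10))
  fam <- welchFdr(vals, rep(letters[1:4], each = 10))
  expect_identical(nrow(fam), 6L)
  expect_true(all(fam$p_adj >= fam$p - 1e-15))
  expect_identical(fam$p_adj, p.adjust(fam$p, "BH"))
})

test_that("studentised bootstrap interval is deterministic and asymptotically normal", {
  expect_warning(const <- studentisedBootstrapCI(rep(2, 10), seed = 1),
                 "constant")
  expect_identical(const$sem, 0)
  expect_identical(const$upper - const$lower, 0)

  set.seed(6)
  x <- rnorm(1e4)
  a <- studentisedBootstrapCI(x, nBoot = 2000, seed = 9)
  b <- studentisedBootstrapCI(x, nBoot = 2000, seed = 9)
  expect_identical(a, b)
  halfWidth <- (a$upper - a$lower) / 2
  expect_lt(abs(halfWidth - 1.96 / sqrt(1e4)) / (1.96 / sqrt(1e4)), 0.1)
  expect_equal(a$sem, sd(x) / 100)
})

test_that("exponential decay fit recovers noiseless parameters and flags degeneracy", {
  t <- c(2, 10, 20, 30, 40)
  f <- fitExpDecay(t, 0.5 * exp(-0.1 * t) + 1.2)
  expect_equal(c(f@a, f@b, f@c), c(0.5, 0.1, 1.2), tolerance = 1e-4)
  expect_true(f@identifiable)

  const <- fitExpDecay(t, rep(1.2, 5))
  expect_false(const@identifiable)
  expect_equal(const@a, 0)
  expect_equal(const@c, 1.2)

  # b = 0 generating model: only a + c identified, reported via c
  flat <- fitExpDecay(t, rep(0.3 + 1.0, 5))
  expect_false(flat@identifiable)
  expect_equal(flat@a + flat@c, 1.3)

  expect_error(fitExpDecay(c(2, 4), c(1, 2)), "at least 3")
})

test_that("cohort bootstrap of the exponential fit is reproducible and degenerate-safe", {
  t <- seq(2, 40, 2)
  curve <- 0.4 * exp(-0.05 * t) + 1.15
  same <- matrix(rep(curve, 4), 4, byrow = TRUE)
  bf <- bootstrapExpDecay(same, t, nBoot = 50, seed = 2)
  s <- expDecaySummary(bf)
  expect_equal(s$iqr_upper - s$iqr_lower, rep(0, 3), tolerance = 1e-10)

  noisy <- expCohortMatrix(0.4, 0.05, 1.15, t, nExp = 8, sigma = 0.05,
                           seed = 21)
  b1 <- bootstrapExpDecay(noisy, t, nBoot = 200, seed = 5)
  b2 <- bootstrapExpDecay(noisy, t, nBoot = 200, seed = 5)
  expect_identical(b1@boot, b2@boot)
  expect_identical(nrow(b1@boot) + b1@nFail, 200L)
  expect_error(bootstrapExpDecay(same[1, , drop = FALSE], t), "at least 2")
})

test_that("rank-based omnibus and post-hoc tests match hand-computed oracles", {
  # all values tied: omnibus trivially non-significant, no pairwise tests
  tied <- kruskalDunnFdr(list(a = c(1, 1), b = c(1, 1)))
  expect_identical(tied$omnibus_p, 1)
  expect_null(tied$pairwise)

  # hand oracle for {1,2,3} vs {4,5,6}: mean ranks 2 and 5, no ties,
  # z = 3 / sqrt((6*7/12) * (2/3)) = 1.963961..., p = 0.0495346
  two <- kruskalDunnFdr(list(lo = 1:3, hi = 4:6))
  expect_equal(abs(two$pairwise$z), 3 / sqrt(3.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(two$pairwise$p, 2 * pnorm(-3 / sqrt(3.5 * 2 / 3)),
               tolerance = 1e-12)

  # well-separated groups: everything significant
  sep <- kruskalDunnFdr(list(a = 1:100, b = 101:200, c = 201:300))
  expect_lt(sep$omnibus_p, 1e-3)
  expect_true(all(sep$pairwise$p_adj < 0.05))

  expect_error(kruskalDunnFdr(list(a = 1:3)), "at least 2")

  # tie correction: matches kruskal.test's tie handling on tied data
  g <- list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4), c = c(5, 5, 6, 7))
  res <- kruskalDunnFdr(g)
  kw <- kruskal.test(unlist(g), rep(names(g), lengths(g)))
  expect_equal(res$omnibus_p, unname(kw$p.value))
})
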