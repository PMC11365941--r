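# Shared fixtures: small layouts and fast-but-contract-respecting solver
# settings for tests that do not probe numerical accuracy itself.

refParams <- referenceParameters()

threeLayout <- function() referenceLayout("three")

colocLayout <- function(n, paradigm) {
  spineLayout(rep(0, n), rep(TRUE, n), paradigm = paradigm, nHat = 0)
}

# exponential-curve cohort: per-experiment trajectories around
# a*exp(-b*t) + c with multiplicative log-normal noise
expCohortMatrix <- function(a, b, c, times, nExp, sigma, seed) {
  set.seed(seed)
  t(replicate(nExp,
              (a * exp(-b * times) + c) * exp(rnorm(length(times), 0, sigma))))
}

randomLayout <- function(nStim, nUnstim, span, paradigm = "seven") {
  xs <- sort(runif(nStim, 0, span))
  xu <- runif(nUnstim, -2, span + 2)
  spineLayout(c(xs, xu), c(rep(TRUE, nStim), rep(FALSE, nUnstim)),
              paradigm = paradigm)
}
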