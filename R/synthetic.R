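# Synthetic cohorts: layouts whose cluster-span statistics match the
# reported geometry of each stimulation paradigm, forward-model
# trajectories, and multiplicative log-normal measurement noise.

DEFAULT_N_EXPERIMENTS <- c(single = 13L, three = 7L, seven = 25L,
                           seven_distributed = 10L, fifteen = 13L,
                           sham = 10L)

#' Specification of a synthetic cohort
#'
#' Defaults emulate the experimental design: 3 pre-stimulation snapshots at
#' -6, -4, -2 min, post-stimulation snapshots every 2 min out to +40 min,
#' per-experiment counts mirroring the published dataset table (e.g. 7
#' three-spine experiments, 25 seven-spine, 13 fifteen-spine),
#' multiplicative log-normal measurement noise with sigma = 0.05, and
#' log-normal per-spine baseline fluorescence.
#'
#' @param paradigm stimulation paradigm.
#' @param nExperiments experiments in the cohort (default per paradigm).
#' @param sigma log-scale standard deviation of the multiplicative
#'   measurement noise (>= 0).
#' @param preTimes,postTimes snapshot schedules (min).
#' @param params ground-truth [ModelParameters-class].
#' @param seed RNG seed for the whole cohort.
#' @param unstimDensity linear density of unstimulated spines along the
#'   cluster (per um).
#' @param baselineMeanlog,baselineSdlog log-normal baseline fluorescence
#'   parameters (arbitrary units).
#' @param dt,spacing solver settings for the ground-truth simulation.
#' @return A list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(paradigm = "three",
                       nExperiments = DEFAULT_N_EXPERIMENTS[[paradigm]],
                       sigma = 0.05, preTimes = c(-6, -4, -2),
                       postTimes = seq(2, 40, by = 2),
                       params = referenceParameters(), seed = 1,
                       unstimDensity = 0.66,
                       baselineMeanlog = log(100), baselineSdlog = 0.3,
                       dt = 0.05, spacing = 0.125) {
  stopifnot(paradigm %in% PARADIGMS, nExperiments >= 1, sigma >= 0,
            all(preTimes < 0), all(postTimes >= 2))
  structure(list(paradigm = paradigm,
                 nExperiments = as.integer(nExperiments), sigma = sigma,
                 preTimes = preTimes, postTimes = postTimes,
                 params = params, seed = as.integer(seed),
                 unstimDensity = unstimDensity,
                 baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog, dt = dt, spacing = spacing),
            class = "cohortSpec")
}

N_STIM_PER_PARADIGM <- c(single = 1L, three = 3L, seven = 7L,
                         seven_distributed = 7L, fifteen = 15L, sham = 3L)

# Cluster span draws anchored to the reported geometry:
#   3-spine: min 2.2, mean 3.2, max 4.2 um (uniform matches all three);
#   7-spine: quartiles 5.6 / 14.1 um, mean about 10.6 (log-normal matched
#            to the quartiles; mean ~11.2);
#   distributed 7-spine: inter-spine distances 3x the clustered draw;
#   15-spine: min 20, mean 28.3, max 30.6 um (scaled Beta with that mean).
drawSpan <- function(paradigm) {
  switch(paradigm,
    single = 0,
    three = runif(1, 2.2, 4.2),
    sham = runif(1, 2.2, 4.2),
    seven = min(max(rlnorm(1, log(8.89), 0.685), 2.5), 35),
    seven_distributed = 3 * min(max(rlnorm(1, log(8.89), 0.685), 2.5), 35),
    fifteen = 20 + 10.6 * rbeta(1, 4, 1.108),
    stop("unknown paradigm: ", paradigm))
}

#' Draw a synthetic spine layout for a paradigm
#'
#' Stimulated positions span a cluster whose width is drawn to match the
#' reported span statistics of the paradigm (see [cohortSpec()]); interior
#' spines sit at jittered regular spacings. Unstimulated spines are
#' interleaved as a Poisson process of the given density over the cluster
#' plus a 2-um margin.
#'
#' @param paradigm stimulation paradigm.
#' @param unstimDensity unstimulated spines per um.
#' @param experiment id used to label spines.
#' @return A [SpineLayout-class]. Uses the current RNG state.
#' @export
makeLayout <- function(paradigm, unstimDensity = 0.66, experiment = "e1") {
  nStim <- N_STIM_PER_PARADIGM[[paradigm]]
  span <- drawSpan(paradigm)
  if (nStim == 1L) {
    xs <- 0
  } else {
    xs <- seq(0, span, length.out = nStim)
    if (nStim > 2) {
      gap <- span / (nStim - 1)
      mid <- xs[-c(1, nStim)] + runif(nStim - 2, -0.3, 0.3) * gap
      xs <- c(0, sort(pmin(pmax(mid, 0.05 * span), 0.95 * span)), span)
    }
  }
  lo <- min(xs) - 2; hi <- max(xs) + 2
  nUn <- rpois(1, unstimDensity * (hi - lo))
  xu <- sort(runif(nUn, lo, hi))
  pos <- c(xs, xu)
  stim <- c(rep(TRUE, length(xs)), rep(FALSE, nUn))
  ids <- paste0(experiment, "_sp", seq_along(pos))
  spineLayout(pos, stim, ids, paradigm = paradigm)
}

#' Simulate one synthetic experiment
#'
#' Ground-truth trajectories come from the forward model; the raw
#' fluorescence is `baseline * S * exp(noise)` with i.i.d. Gaussian
#' log-noise per (spine, snapshot) and log-normal per-spine baselines.
#' Pre-stimulation snapshots have S = 1. Uses the current RNG state.
#'
#' @param layout a [SpineLayout-class].
#' @param params ground-truth [ModelParameters-class].
#' @param spec a [cohortSpec()].
#' @param experiment experiment identifier.
#' @return List: `data` (a [SpineTrajectoryExperiment-class], raw and
#'   normalised assays), `truth` (noiseless size matrix over all
#'   snapshots).
#' @export
simulateExperiment <- function(layout, params, spec, experiment = "e1") {
  res <- simulateSpines(layout, params, times = spec$postTimes,
                        dt = spec$dt, spacing = spec$spacing,
                        allSpines = TRUE)
  nSpine <- length(layout@position)
  S <- cbind(matrix(1, nSpine, length(spec$preTimes)), res@sizes)
  times <- c(spec$preTimes, spec$postTimes)
  baseline <- rlnorm(nSpine, spec$baselineMeanlog, spec$baselineSdlog)
  eps <- matrix(rnorm(length(S), 0, spec$sigma), nSpine)
  raw <- baseline * S * exp(eps)
  ste <- spineTrajectoryExperiment(
    raw = raw, times = times,
    experiment_id = rep(experiment, nSpine),
    spine_id = layout@spineId,
    position_um = layout@position,
    stimulated = layout@stimulated,
    paradigm = layout@paradigm)
  list(data = normaliseTrajectories(ste, nPre = length(spec$preTimes)),
       truth = S)
}

#' Generate a synthetic cohort with its ground truth
#'
#' Draws one layout per experiment, simulates the model, applies
#' measurement noise, and returns the pooled dataset together with a
#' ground-truth sidecar for recovery studies. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohortSpec()].
#' @return List: `data` (pooled [SpineTrajectoryExperiment-class]),
#'   `truth` (list: `params`, per-experiment `layouts` and noiseless
#'   `trajectories`, and `meanTrajectory`, the mean noiseless stimulated
#'   trajectory at the post-stimulation snapshots).
#' @examples
#' cohort <- generateCohort(cohortSpec("three", nExperiments = 2, seed = 1))
#' dim(normalisedSize(cohort$data))
#' @export
generateCohort <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  experiments <- vector("list", spec$nExperiments)
  layouts <- vector("list", spec$nExperiments)
  truths <- vector("list", spec$nExperiments)
  for (i in seq_len(spec$nExperiments)) {
    id <- sprintf("exp%02d", i)
    layouts[[i]] <- makeLayout(spec$paradigm, spec$unstimDensity, id)
    sim <- simulateExperiment(layouts[[i]], spec$params, spec, id)
    experiments[[i]] <- sim$data
    truths[[i]] <- sim$truth
  }
  data <- do.call(rbind, experiments)
  nPost <- length(spec$postTimes)
  stimMeans <- vapply(seq_along(truths), function(i) {
    stim <- layouts[[i]]@stimulated
    colMeans(truths[[i]][stim, length(spec$preTimes) + seq_len(nPost),
                         drop = FALSE])
  }, numeric(nPost))
  list(data = data,
       truth = list(params = spec$params, layouts = layouts,
                    trajectories = truths,
                    meanTrajectory = rowMeans(stimMeans),
                    postTimes = spec$postTimes, spec = spec))
}

#' Per-experiment mean stimulated trajectories of a cohort
#'
#' @param x a [SpineTrajectoryExperiment-class] with a `size` assay.
#' @param postOnly restrict to post-stimulation snapshots.
#' @return List: `mat` (experiments x snapshots matrix of mean normalised
#'   sizes over stimulated spines), `times`.
#' @export
experimentMeans <- function(x, postOnly = TRUE) {
  rd <- SummarizedExperiment::rowData(x)
  tm <- trajectoryTimes(x)
  keep <- if (postOnly) tm >= 2 else rep(TRUE, length(tm))
  a <- normalisedSize(x)[, keep, drop = FALSE]
  stim <- rd$stimulated
  ids <- unique(rd$experiment_id)
  mat <- t(vapply(ids, function(e) {
    colMeans(a[stim & rd$experiment_id == e, , drop = FALSE])
  }, numeric(sum(keep))))
  rownames(mat) <- ids
  list(mat = mat, times = tm[keep])
}
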