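# Model fitting: squared-error cost on spine trajectories, discrete-adjoint
# or finite-difference gradients, multi-start L-BFGS-B in log-parameter space.

DEFAULT_BOUNDS <- list(
  lower = c(C_s = 1e-4, C_d = 0.05, lam = 0.2, alpha1 = 0.02, alpha2 = 0.02,
            beta1 = 0.005, beta2 = 0.2, gamma = 0.01, rho = 0.05,
            phi = 0.3, nu = 1.01, zeta1 = 0.005, zeta2 = 0.005),
  upper = c(C_s = 0.5, C_d = 5, lam = 8, alpha1 = 10, alpha2 = 5,
            beta1 = 5, beta2 = 50, gamma = 3, rho = 10,
            phi = 10, nu = 2.5, zeta1 = 5, zeta2 = 5))

#' Fit configuration
#'
#' @param nRestarts number of random multi-start repeats (default 10).
#' @param seed integer seed for the restart starting points.
#' @param gradient `"adjoint"` (discrete adjoint of the integrator; the
#'   reference mode) or `"fd"` (central finite differences).
#' @param free character vector of parameters to optimise (default: all 13
#'   fitted constants; the kernel width `g_eff` is always fixed).
#' @param lower,upper named numeric bounds (positive); optimisation runs in
#'   log space inside this box, which also enforces positivity.
#' @param maxit maximum L-BFGS-B iterations per restart.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]).
#' @param dt,spacing,pad solver settings used during fitting.
#' @param radius competing-unstimulated-spine radius (um).
#' @return A list of class `"fitConfig"`.
#' @export
fitConfig <- function(nRestarts = 10, seed = 1,
                      gradient = c("adjoint", "fd"),
                      free = FIT_PARAM_NAMES,
                      lower = DEFAULT_BOUNDS$lower,
                      upper = DEFAULT_BOUNDS$upper,
                      maxit = 200, factr = 1e8,
                      dt = 0.05, spacing = 0.125, pad = 20, radius = 2) {
  gradient <- match.arg(gradient)
  stopifnot(nRestarts >= 1, all(free %in% FIT_PARAM_NAMES))
  lo <- DEFAULT_BOUNDS$lower; lo[names(lower)] <- lower
  up <- DEFAULT_BOUNDS$upper; up[names(upper)] <- upper
  if (any(lo <= 0) || any(!is.finite(up)))
    stop("bounds must be finite and positive")
  structure(list(nRestarts = as.integer(nRestarts), seed = as.integer(seed),
                 gradient = gradient, free = free, lower = lo, upper = up,
                 maxit = maxit, factr = factr, dt = dt, spacing = spacing,
                 pad = pad, radius = radius),
            class = "fitConfig")
}

# Precomputed geometry for repeated simulations of one layout.
simContext <- function(layout, spacing, pad, radius) {
  grid <- makeGrid(layout, spacing = spacing, pad = pad)
  stim <- which(layout@stimulated)
  xs <- layout@position[stim]
  x <- gridPoints(grid)
  G <- vapply(xs, function(xi) (x - xi)^2, numeric(length(x)))  # squared dist
  nhat <- countCompetingUnstim(layout, radius)
  list(grid = grid, xs = xs, x = x, dist2 = G, nhat = nhat,
       nodes = nearestNodes(grid, xs), nStim = length(xs))
}

# Initial conditions and their parameter derivatives on a context.
buildIC <- function(ctx, v, withGrad = FALSE) {
  m <- abs(outer(ctx$xs, ctx$xs, "-"))
  mm <- m / (1 + m)
  lm <- mm^v[["lam"]]
  d <- rowSums(lm) - diag(lm)   # diagonal terms are 0^lam = 0 anyway
  D <- (1 + d) / (ctx$nStim + ctx$nhat)
  G <- exp(v[["g_eff"]] * ctx$dist2)          # grid x nstim
  sumG <- rowSums(G)
  sumDG <- as.numeric(G %*% D)
  C0 <- v[["C_s"]] * sumG + v[["C_d"]] * sumDG
  h <- 1 - (sumG - sumDG)                     # 1 - sum (1-D_i) G_i
  Pin0 <- pmax(0, v[["rho"]] * h)
  out <- list(C0 = C0, Pin0 = Pin0, D = D)
  if (withGrad) {
    lnm <- ifelse(mm > 0, log(mm), 0)
    dd <- rowSums(lm * lnm)                   # d d_i / d lam
    dD <- dd / (ctx$nStim + ctx$nhat)
    live <- h > 0
    out$dC0 <- list(C_s = sumG, C_d = sumDG,
                    lam = v[["C_d"]] * as.numeric(G %*% dD))
    out$dPin0 <- list(rho = ifelse(live, h, 0),
                      lam = ifelse(live, v[["rho"]] * as.numeric(G %*% dD), 0))
  }
  out
}

dynPars <- function(v) v[c("alpha1", "alpha2", "beta1", "beta2", "gamma",
                           "phi", "nu", "zeta1", "zeta2")]

asTargetMatrix <- function(target, nStim, nTimes) {
  if (is.null(dim(target)))
    target <- matrix(target, nrow = nStim, ncol = nTimes, byrow = TRUE)
  if (nrow(target) != nStim)
    stop("target has ", nrow(target), " rows but the layout has ", nStim,
         " stimulated spines")
  if (ncol(target) != nTimes)
    stop("target has ", ncol(target), " columns but ", nTimes,
         " snapshot times were given")
  target
}

#' Squared-error cost of a parameter set against target trajectories
#'
#' Sum over stimulated spines and post-stimulation snapshots of the squared
#' difference between the simulated normalised size and the target value.
#'
#' @param params a [ModelParameters-class].
#' @param layout a [SpineLayout-class].
#' @param target matrix (stimulated spines x times) of target normalised
#'   sizes, or a single mean trajectory (recycled across spines).
#' @param times snapshot times (min, within the 2-40 min model window).
#' @param dt,spacing,pad,radius solver settings (see [simulateSpines()]).
#' @return Non-negative scalar.
#' @examples
#' ly <- spineLayout(c(0, 1.6, 3.2), rep(TRUE, 3), paradigm = "three")
#' p <- referenceParameters()
#' tr <- spineSizes(simulateSpines(ly, p, times = c(2, 20, 40)))
#' spineCost(p, ly, tr, c(2, 20, 40))  # ~0 by self-consistency
#' @export
spineCost <- function(params, layout, target, times = seq(2, 40, by = 2),
                      dt = 0.05, spacing = 0.125, pad = 20, radius = 2) {
  res <- simulateSpines(layout, params, times = times, dt = dt,
                        spacing = spacing, pad = pad, radius = radius)
  target <- asTargetMatrix(target, nrow(res@sizes), length(times))
  sum((res@sizes - target)^2)
}

#' Cost and gradient with respect to the fitted parameters
#'
#' The adjoint mode integrates the model forward, then sweeps the discrete
#' adjoint of the exact numerical scheme backward, accumulating the
#' gradient of the squared-error cost with respect to the nine dynamical
#' constants and chaining the initial-condition adjoint to `C_s`, `C_d`,
#' `lam` and `rho`. The finite-difference mode uses central differences.
#' Both return the same gradient to about 1e-6 relative error.
#'
#' @inheritParams spineCost
#' @param mode `"adjoint"` or `"fd"`.
#' @param free parameters to differentiate with respect to.
#' @return List with `cost` and named numeric `gradient`.
#' @export
costGradient <- function(params, layout, target, times = seq(2, 40, by = 2),
                         mode = c("adjoint", "fd"), free = FIT_PARAM_NAMES,
                         dt = 0.05, spacing = 0.125, pad = 20, radius = 2) {
  mode <- match.arg(mode)
  v <- paramValues(params)
  if (mode == "fd") {
    grad <- vapply(free, function(nm) {
      h <- max(1e-6, 1e-6 * abs(v[[nm]]))
      up <- updateParameters(params, setNames(v[[nm]] + h, nm))
      dn <- updateParameters(params, setNames(v[[nm]] - h, nm))
      (spineCost(up, layout, target, times, dt, spacing, pad, radius) -
       spineCost(dn, layout, target, times, dt, spacing, pad, radius)) / (2 * h)
    }, numeric(1))
    cost <- spineCost(params, layout, target, times, dt, spacing, pad, radius)
    return(list(cost = cost, gradient = grad))
  }
  ctx <- simContext(layout, spacing, pad, radius)
  ic <- buildIC(ctx, v, withGrad = TRUE)
  steps <- as.integer(round(times / dt))
  if (any(abs(times / dt - steps) > 1e-8))
    stop("snapshot times must be multiples of dt")
  n <- ctx$grid@nPoints
  target <- asTargetMatrix(target, ctx$nStim, length(times))
  adj <- .rd_adjoint(ic$C0, ic$Pin0, numeric(n), rep(1, n),
                     gridSpacing(ctx$grid), dt, max(steps), dynPars(v),
                     steps, ctx$nodes - 1L, target)
  gdyn <- setNames(adj$grad_dyn, c("alpha1", "alpha2", "beta1", "beta2",
                                   "gamma", "phi", "nu", "zeta1", "zeta2"))
  gic <- c(C_s = sum(adj$psi_C0 * ic$dC0$C_s),
           C_d = sum(adj$psi_C0 * ic$dC0$C_d),
           lam = sum(adj$psi_C0 * ic$dC0$lam) +
                 sum(adj$psi_Pin0 * ic$dPin0$lam),
           rho = sum(adj$psi_Pin0 * ic$dPin0$rho))
  grad <- c(gic, gdyn)[FIT_PARAM_NAMES]
  list(cost = adj$cost, gradient = grad[free])
}

#' Compare adjoint and finite-difference gradients
#'
#' @inheritParams costGradient
#' @return data.frame with one row per parameter: both gradients and their
#'   relative difference.
#' @export
gradientCheck <- function(params, layout, target, times = seq(2, 40, by = 2),
                          free = FIT_PARAM_NAMES, dt = 0.05, spacing = 0.125,
                          pad = 20, radius = 2) {
  ga <- costGradient(params, layout, target, times, "adjoint", free,
                     dt, spacing, pad, radius)$gradient
  gf <- costGradient(params, layout, target, times, "fd", free,
                     dt, spacing, pad, radius)$gradient
  scale <- pmax(abs(gf), 1e-8)
  data.frame(parameter = free, adjoint = as.numeric(ga),
             fd = as.numeric(gf),
             rel_diff = as.numeric(abs(ga - gf) / scale))
}

runif_seeded <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  runif(n)
}

meanTargetFromCohort <- function(x) {
  stopifnot(is(x, "SpineTrajectoryExperiment"))
  tm <- SummarizedExperiment::colData(x)$time_min
  post <- tm >= 2 & tm <= 40
  stim <- SummarizedExperiment::rowData(x)$stimulated
  a <- SummarizedExperiment::assay(x, "size")
  list(target = colMeans(a[stim, post, drop = FALSE]), times = tm[post])
}

#' Fit the model to spine trajectories by multi-start least squares
#'
#' Minimises the squared-error cost with gradient-based local optimisation
#' (L-BFGS-B in log-parameter space, which enforces positivity) from
#' `nRestarts` seeded random starting points drawn log-uniformly within the
#' bounds; the first start is the reference parameter set. Deterministic
#' given the configuration seed.
#'
#' @param x a [SpineTrajectoryExperiment-class] (the cohort-mean normalised
#'   trajectory over stimulated spines is fitted) or a numeric target
#'   matrix/vector as in [spineCost()].
#' @param layout the [SpineLayout-class] to simulate during fitting.
#' @param config a [fitConfig()].
#' @param times snapshot times when `x` is a numeric target.
#' @param start optional [ModelParameters-class] used as the first start
#'   (default [referenceParameters()]).
#' @return A [FitResult-class].
#' @export
fitModel <- function(x, layout, config = fitConfig(), times = NULL,
                     start = referenceParameters()) {
  if (is(x, "SpineTrajectoryExperiment")) {
    mt <- meanTargetFromCohort(x)
    target <- mt$target; times <- mt$times
  } else {
    if (is.null(times)) stop("times must be given with a numeric target")
    target <- x
  }
  free <- config$free
  nStim <- sum(layout@stimulated)
  target <- asTargetMatrix(target, nStim, length(times))

  if (!length(free)) {  # nothing to optimise: evaluate the start point
    cost <- spineCost(start, layout, target, times, config$dt,
                      config$spacing, config$pad, config$radius)
    traj <- spineSizes(simulateSpines(layout, start, times = times,
                                      dt = config$dt,
                                      spacing = config$spacing,
                                      pad = config$pad,
                                      radius = config$radius))
    return(new("FitResult", par = start, cost = cost,
               restarts = data.frame(restart = integer(), cost = numeric(),
                                     convergence = integer(),
                                     message = character()),
               seed = config$seed, gradientCheck = data.frame(),
               gof = list(), trajectory = traj,
               times = as.numeric(times), config = unclass(config)))
  }

  lo <- log(config$lower[free]); up <- log(config$upper[free])
  v0 <- paramValues(start)
  base <- pmin(pmax(v0[free], config$lower[free] * (1 + 1e-9)),
               config$upper[free] / (1 + 1e-9))

  u <- runif_seeded(config$seed, config$nRestarts * length(free))
  starts <- matrix(u, nrow = config$nRestarts, byrow = TRUE)
  starts <- sweep(sweep(starts, 2, up - lo, "*"), 2, lo, "+")
  starts[1, ] <- log(base)  # restart 1: supplied start point

  evalEnv <- new.env()
  objective <- function(lp, what) {
    key <- paste(format(lp, digits = 17), collapse = ",")
    if (!identical(evalEnv$key, key)) {
      pv <- v0
      pv[free] <- exp(lp)
      pars <- new("ModelParameters", values = pv)
      res <- costGradient(pars, layout, target, times, config$gradient, free,
                          config$dt, config$spacing, config$pad, config$radius)
      evalEnv$key <- key
      evalEnv$res <- res
    }
    if (what == "fn") evalEnv$res$cost else
      evalEnv$res$gradient * exp(lp)  # chain rule d/d log(theta)
  }

  rows <- vector("list", config$nRestarts)
  best <- NULL
  for (k in seq_len(config$nRestarts)) {
    opt <- tryCatch(
      optim(starts[k, ], fn = function(p) objective(p, "fn"),
            gr = function(p) objective(p, "gr"), method = "L-BFGS-B",
            lower = lo, upper = up,
            control = list(maxit = config$maxit, factr = config$factr)),
      error = function(e) e)
    if (inherits(opt, "error")) {
      rows[[k]] <- data.frame(restart = k, cost = NA_real_,
                              convergence = NA_integer_,
                              message = conditionMessage(opt))
      next
    }
    rows[[k]] <- data.frame(restart = k, cost = opt$value,
                            convergence = opt$convergence, message = "")
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  restarts <- do.call(rbind, rows)
  if (is.null(best))
    stop("all restarts failed to converge; per-restart diagnostics:\n",
         paste(restarts$message, collapse = "\n"))

  vb <- v0
  vb[free] <- exp(best$par)
  parBest <- new("ModelParameters", values = vb)
  traj <- spineSizes(simulateSpines(layout, parBest, times = times,
                                    dt = config$dt, spacing = config$spacing,
                                    pad = config$pad,
                                    radius = config$radius))
  gof <- list()
  if (is(x, "SpineTrajectoryExperiment")) {
    tm <- SummarizedExperiment::colData(x)$time_min
    post <- tm >= 2 & tm <= 40
    stim <- SummarizedExperiment::rowData(x)$stimulated
    obs <- SummarizedExperiment::assay(x, "size")[stim, post, drop = FALSE]
    pred <- colMeans(traj)
    gof <- list(nmse = nmse(pred, obs), r2w = r2w(pred, obs))
  }
  new("FitResult", par = parBest, cost = best$value, restarts = restarts,
      seed = config$seed, gradientCheck = data.frame(), gof = gof,
      trajectory = traj, times = as.numeric(times),
      config = unclass(config))
}

#' @describeIn fitModel best-fit parameters of a fit.
#' @param fit a `FitResult`.
#' @export
fittedParameters <- function(fit) fit@par

#' @describeIn fitModel best cost of a fit.
#' @export
fitCost <- function(fit) fit@cost

setMethod("show", "FitResult", function(object) {
  ok <- sum(!is.na(object@restarts$cost))
  cat(sprintf("FitResult: best cost %.6g over %d/%d converged restarts (seed %d)\n",
              object@cost, ok, nrow(object@restarts), object@seed))
  if (length(object@gof))
    cat(sprintf("  goodness of fit: NMSE %.3f, weighted R^2 %.3f\n",
                object@gof$nmse, object@gof$r2w))
})

#' Forward prediction for a new paradigm without refitting
#'
#' Pure forward simulation of a fitted (or given) parameter set on another
#' layout: the initial resources are rescaled only through the competition
#' factors and the initial-condition expressions; no parameter changes.
#'
#' @param fit a [FitResult-class] or [ModelParameters-class].
#' @param layout target [SpineLayout-class].
#' @param times snapshot times (min).
#' @param ... further arguments for [simulateSpines()].
#' @return A [SimulationResult-class].
#' @export
predictParadigm <- function(fit, layout, times = seq(2, 40, by = 2), ...) {
  params <- if (is(fit, "FitResult")) fit@par else fit
  simulateSpines(layout, params, times = times, ...)
}

#' Refit susceptibilities for a pharmacological condition
#'
#' Starting from a master fit, frees only the parameters the corresponding
#' inhibitor is modelled to affect, with direction-of-change constraints
#' enforced as bounds:
#' \describe{
#'   \item{FK506}{(calcineurin inhibition) `zeta1`, `zeta2` free with the
#'     `zeta1/zeta2` ratio increased: `zeta1` bounded below and `zeta2`
#'     bounded above by their master values.}
#'   \item{AIP}{(CaMKII inhibition) `zeta1`, `zeta2` and `nu` free with the
#'     ratio decreased and the threshold lowered: `zeta1`, `nu` bounded
#'     above and `zeta2` bounded below by their master values.}
#' }
#' All other parameters stay frozen at the master fit.
#'
#' @param x target data as in [fitModel()].
#' @param base master-fit [ModelParameters-class].
#' @param condition `"AIP"` or `"FK506"`.
#' @param layout the [SpineLayout-class] of the drug experiments (single
#'   spine in the original design).
#' @param config a [fitConfig()]; its `free` field is overridden.
#' @param times snapshot times when `x` is numeric.
#' @return A [FitResult-class].
#' @export
fitDrugVariant <- function(x, base, condition = c("AIP", "FK506"), layout,
                           config = fitConfig(), times = NULL) {
  condition <- match.arg(condition)
  vb <- paramValues(base)
  lo <- config$lower; up <- config$upper
  if (condition == "FK506") {
    free <- c("zeta1", "zeta2")
    lo["zeta1"] <- vb[["zeta1"]]; up["zeta2"] <- vb[["zeta2"]]
  } else {
    free <- c("zeta1", "zeta2", "nu")
    up["zeta1"] <- vb[["zeta1"]]; lo["zeta2"] <- vb[["zeta2"]]
    up["nu"] <- vb[["nu"]]
  }
  config$free <- free; config$lower <- lo; config$upper <- up
  fitModel(x, layout, config, times = times, start = base)
}
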