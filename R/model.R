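#' Build a simulation grid around a layout
#'
#' The domain extends `pad` um beyond the outermost spine on each side so
#' that the zero-flux boundaries sit several diffusion lengths away from
#' any stimulation site over a 40-min simulation.
#'
#' @param layout a [SpineLayout-class].
#' @param spacing grid spacing in um (default 0.125, eight nodes per 1-um
#'   kernel FWHM).
#' @param pad padding beyond the outermost spine, um (default 20).
#' @return A [SimGrid-class].
#' @export
makeGrid <- function(layout, spacing = 0.125, pad = 20) {
  lo <- min(layout@position) - pad
  hi <- max(layout@position) + pad
  n <- ceiling((hi - lo) / spacing) + 1L
  new("SimGrid", xMin = lo, xMax = lo + (n - 1L) * spacing,
      nPoints = as.integer(n))
}

#' @describeIn makeGrid grid node coordinates (um).
#' @param grid a `SimGrid`.
#' @export
gridPoints <- function(grid) {
  seq(grid@xMin, grid@xMax, length.out = grid@nPoints)
}

#' @describeIn makeGrid grid spacing (um).
#' @export
gridSpacing <- function(grid) {
  (grid@xMax - grid@xMin) / (grid@nPoints - 1L)
}

setMethod("show", "SimGrid", function(object) {
  cat(sprintf("SimGrid: [%.2f, %.2f] um, %d nodes (dx = %.4f um)\n",
              object@xMin, object@xMax, object@nPoints,
              gridSpacing(object)))
})

kernelFwhm <- function(g_eff) 2 * sqrt(log(2) / (-g_eff))

checkResolution <- function(grid, params) {
  fwhm <- kernelFwhm(paramValues(params)[["g_eff"]])
  if (gridSpacing(grid) > fwhm / 8 * (1 + 1e-9))
    stop(sprintf(paste("grid too coarse: spacing %.4f um exceeds 1/8 of the",
                       "kernel FWHM (%.3f um)"), gridSpacing(grid), fwhm))
  invisible(TRUE)
}

#' Initial fast-resource profile
#'
#' A sum of narrow Gaussians centred on the stimulation sites, each of
#' amplitude `C_s + C_d * D_i`: the uncontested spine store plus the
#' competition-weighted share of the shared dendritic pool.
#'
#' @param grid a [SimGrid-class] covering the layout.
#' @param layout a [SpineLayout-class].
#' @param params a [ModelParameters-class].
#' @param comp a [CompetitionFactors-class] for the layout (computed if
#'   missing).
#' @return Numeric concentration profile over the grid nodes.
#' @export
initialC <- function(grid, layout, params,
                     comp = competitionFactors(layout,
                                               paramValues(params)[["lam"]])) {
  checkResolution(grid, params)
  v <- paramValues(params)
  x <- gridPoints(grid)
  xs <- layout@position[layout@stimulated]
  prof <- numeric(length(x))
  for (k in seq_along(xs)) {
    amp <- v[["C_s"]] + v[["C_d"]] * comp@D[k]
    prof <- prof + amp * exp(v[["g_eff"]] * (x - xs[k])^2)
  }
  prof
}

#' Initial inactive slow-resource profile
#'
#' The baseline level `rho` depleted at each stimulation site by
#' `(1 - D_i)` times the same Gaussian kernel: the share of the inactive
#' pool claimed by competing spines. Overlapping depletions of tight
#' clusters can drive the raw expression negative; concentrations cannot
#' be negative, so the profile is clamped at zero from below.
#'
#' @inheritParams initialC
#' @return Numeric concentration profile over the grid nodes.
#' @export
initialPin <- function(grid, layout, params,
                       comp = competitionFactors(layout,
                                                 paramValues(params)[["lam"]])) {
  checkResolution(grid, params)
  v <- paramValues(params)
  if (v[["rho"]] < 0) stop("rho must be >= 0")
  x <- gridPoints(grid)
  xs <- layout@position[layout@stimulated]
  depl <- numeric(length(x))
  for (k in seq_along(xs))
    depl <- depl + (1 - comp@D[k]) * exp(v[["g_eff"]] * (x - xs[k])^2)
  pmax(0, v[["rho"]] * (1 - depl))
}

#' Growth/shrink decision function
#'
#' `F(S) = -tanh(phi * (S - nu))`: positive (growth-promoting) below the
#' size threshold `nu`, negative (shrinkage) above it, saturating at +/-1.
#' This smooth switch avoids an abrupt potentiation/depression border and
#' admits an intermediate regime with little net change near `S = nu`.
#'
#' @param S normalised spine size (baseline = 1).
#' @param phi switch steepness, > 0.
#' @param nu size threshold, > 0.
#' @return Value(s) in (-1, 1).
#' @examples
#' decisionF(1.0, phi = 2, nu = 1.4)  # tanh(0.8), growth
#' @export
decisionF <- function(S, phi, nu) {
  if (phi <= 0) stop("phi must be > 0")
  -tanh(phi * (S - nu))
}

#' Integrate the resource fields
#'
#' Advances the coupled system (fast resource: diffusion + degradation;
#' inactive/active slow resource: reaction-diffusion; spine-size field:
#' local ODE) with zero-flux boundaries, by Strang splitting with
#' Crank-Nicolson diffusion and explicit-midpoint reactions (second order
#' in `dt`).
#'
#' @param grid a [SimGrid-class].
#' @param C0,Pin0,P0,S0 initial profiles over the grid nodes (`S0` defaults
#'   to 1 everywhere).
#' @param params a [ModelParameters-class].
#' @param times snapshot times (min, > 0) at which to record; each must be
#'   an integer multiple of `dt`.
#' @param dt time step (min).
#' @param spineNodes integer grid-node indices at which to sample the
#'   per-spine outputs (default: all nodes... supply from [simulateSpines()]).
#' @param storeFields record full field snapshots.
#' @return List with per-node matrices `S`, `C`, `P`, `Pin`
#'   (`length(spineNodes)` x `length(times)`) and, if requested, full
#'   `field_*` matrices.
#' @export
integrateFields <- function(grid, C0, Pin0, P0 = NULL, S0 = NULL, params,
                            times, dt = 0.02,
                            spineNodes = seq_len(grid@nPoints),
                            storeFields = FALSE) {
  if (any(times <= 0)) stop("snapshot times must be > 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("snapshot times must be strictly increasing")
  steps <- times / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("every snapshot time must be an integer multiple of dt")
  steps <- as.integer(round(steps))
  n <- grid@nPoints
  if (is.null(P0)) P0 <- numeric(n)
  if (is.null(S0)) S0 <- rep(1, n)
  stopifnot(length(C0) == n, length(Pin0) == n, length(P0) == n,
            length(S0) == n)
  v <- paramValues(params)
  dyn <- v[c("alpha1", "alpha2", "beta1", "beta2", "gamma", "phi", "nu",
             "zeta1", "zeta2")]
  .rd_integrate(C0, Pin0, P0, S0, gridSpacing(grid), dt, max(steps), dyn,
                steps, as.integer(spineNodes) - 1L, storeFields)
}

nearestNodes <- function(grid, positions) {
  round((positions - grid@xMin) / gridSpacing(grid)) + 1L
}

#' Simulate spine-size trajectories for a layout
#'
#' Builds the competition factors and initial conditions for the layout,
#' integrates the fields, and samples the normalised size at the grid node
#' nearest each spine (optionally a +/- `window` um average). Sham layouts
#' carry no initial resources, whose exact solution is the baseline:
#' all trajectories are identically 1.
#'
#' @param layout a [SpineLayout-class].
#' @param params a [ModelParameters-class].
#' @param times snapshot times in min after the end of stimulation
#'   (default +2 to +40 every 2 min; the first 2 min lie inside the
#'   stimulation window and are not modelled).
#' @param dt integration step (min).
#' @param spacing,pad grid geometry, see [makeGrid()].
#' @param radius competing-unstimulated-spine radius (um).
#' @param window half-width (um) of an optional averaging window for the
#'   spine readout; 0 (default) reads the nearest node.
#' @param storeFields keep full field snapshots in the result.
#' @param allSpines sample trajectories at unstimulated spines too
#'   (default: stimulated spines only).
#' @return A [SimulationResult-class].
#' @examples
#' ly <- spineLayout(0, TRUE, paradigm = "single")
#' res <- simulateSpines(ly, referenceParameters(), times = c(2, 10))
#' spineSizes(res)
#' @export
simulateSpines <- function(layout, params, times = seq(2, 40, by = 2),
                           dt = 0.02, spacing = 0.125, pad = 20, radius = 2,
                           window = 0, storeFields = FALSE,
                           allSpines = FALSE) {
  if (any(times < 2))
    stop("snapshot times must be >= 2 min (the first post-stimulation frame)")
  keep <- if (allSpines) rep(TRUE, length(layout@position)) else
    layout@stimulated
  pos <- layout@position[keep]
  nm <- layout@spineId[keep]
  if (layout@paradigm == "sham") {
    ones <- matrix(1, length(pos), length(times),
                   dimnames = list(nm, NULL))
    zero <- matrix(0, length(pos), length(times),
                   dimnames = list(nm, NULL))
    return(newSimulationResult(as.numeric(times), ones, zero, zero, zero,
                               layout, list()))
  }
  v <- paramValues(params)
  grid <- makeGrid(layout, spacing = spacing, pad = pad)
  comp <- competitionFactors(layout, v[["lam"]], radius = radius)
  C0 <- initialC(grid, layout, params, comp)
  Pin0 <- initialPin(grid, layout, params, comp)
  nodes <- nearestNodes(grid, pos)
  res <- integrateFields(grid, C0, Pin0, params = params, times = times,
                         dt = dt, spineNodes = nodes,
                         storeFields = storeFields || window > 0)
  take <- function(m) {
    dimnames(m) <- list(nm, NULL)
    m
  }
  sizes <- take(res$S)
  if (window > 0) {
    x <- gridPoints(grid)
    for (k in seq_along(pos)) {
      sel <- abs(x - pos[k]) <= window
      sizes[k, ] <- colMeans(res$field_S[sel, , drop = FALSE])
    }
  }
  fields <- if (storeFields)
    list(x = gridPoints(grid), C = res$field_C, Pin = res$field_Pin,
         P = res$field_P, S = res$field_S) else list()
  newSimulationResult(as.numeric(times), sizes, take(res$C), take(res$P),
                      take(res$Pin), layout, fields)
}

# new() cannot take a slot literally named "C" (it would partially match
# its Class argument), so the resource slots are filled afterwards.
newSimulationResult <- function(times, sizes, C, P, Pin, layout, fields) {
  out <- new("SimulationResult", times = times, sizes = sizes,
             layout = layout, fields = fields)
  out@C <- C; out@P <- P; out@Pin <- Pin
  validObject(out)
  out
}

#' @describeIn simulateSpines matrix of normalised sizes (spines x times).
#' @param result a `SimulationResult`.
#' @export
spineSizes <- function(result) result@sizes

#' @describeIn simulateSpines snapshot times (min).
#' @export
snapshotTimes <- function(result) result@times

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d spines, %d snapshots (%.0f-%.0f min)\n",
              nrow(object@sizes), length(object@times), min(object@times),
              max(object@times)))
  cat(sprintf("  mean size at first/last snapshot: %.3f / %.3f\n",
              mean(object@sizes[, 1]), mean(object@sizes[, ncol(object@sizes)])))
})
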