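#' @import methods
#' @useDynLib SpineCompete, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx coef kruskal.test lm lm.fit median optim optimize
#'   p.adjust pnorm pt quantile rbeta rbinom rlnorm rnorm rpois runif sd
#'   setNames t.test var
#' @importFrom utils read.csv write.csv combn modifyList
NULL

PARADIGMS <- c("single", "three", "seven", "seven_distributed", "fifteen", "sham")

#' Spine geometry along a dendrite
#'
#' Positions (in micrometres) of spines along a 1-D dendritic segment,
#' together with a flag marking which spines were targeted for glutamate
#' uncaging. The layout is the geometric substrate of the resource
#' competition: all allocation factors are functions of the stimulated
#' positions and of the unstimulated spines interleaved between them.
#'
#' @slot position numeric, coordinate along the dendrite (um) per spine.
#' @slot stimulated logical per spine.
#' @slot spineId character label per spine.
#' @slot paradigm one of `"single"`, `"three"`, `"seven"`,
#'   `"seven_distributed"`, `"fifteen"`, `"sham"`.
#' @slot nHatOverride single numeric; if not `NA`, used verbatim as the
#'   count of competing unstimulated spines instead of counting them from
#'   the layout (used when a dataset records no unstimulated positions).
#'
#' @exportClass SpineLayout
setClass("SpineLayout",
  representation(position = "numeric", stimulated = "logical",
                 spineId = "character", paradigm = "character",
                 nHatOverride = "numeric"))

setValidity("SpineLayout", function(object) {
  msg <- character()
  n <- length(object@position)
  if (length(object@stimulated) != n || length(object@spineId) != n)
    msg <- c(msg, "position, stimulated and spineId must have equal length")
  if (any(!is.finite(object@position)))
    msg <- c(msg, "all positions must be finite")
  if (length(object@paradigm) != 1L || !object@paradigm %in% PARADIGMS)
    msg <- c(msg, sprintf("paradigm must be one of %s",
                          paste(PARADIGMS, collapse = ", ")))
  if (length(object@paradigm) == 1L && object@paradigm != "sham" &&
      sum(object@stimulated) < 1L)
    msg <- c(msg, "paradigms other than sham need >= 1 stimulated spine")
  if (length(object@nHatOverride) != 1L)
    msg <- c(msg, "nHatOverride must be a single value (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Competition factors for a layout
#'
#' Per stimulated spine: the proximity sum `d` and the allocation factor
#' `D = (1 + d) / (n_stim + n_hat)` that scales the shared dendritic
#' resource available at that stimulation site.
#'
#' @slot d numeric, dimensionless proximity sum per stimulated spine.
#' @slot D numeric, allocation factor per stimulated spine.
#' @slot nStim integer, number of stimulated spines.
#' @slot nHat integer, number of competing unstimulated spines.
#'
#' @exportClass CompetitionFactors
setClass("CompetitionFactors",
  representation(d = "numeric", D = "numeric",
                 nStim = "integer", nHat = "integer"))

setValidity("CompetitionFactors", function(object) {
  msg <- character()
  N <- object@nStim
  tol <- 1e-9
  if (any(object@d < -tol) || any(object@d > N - 1 + tol))
    msg <- c(msg, "d must lie in [0, N - 1]")
  lo <- 1 / (N + object@nHat)
  hi <- N / (N + object@nHat)
  if (any(object@D < lo - tol) || any(object@D > hi + tol))
    msg <- c(msg, "D must lie in [1/(N + Nhat), N/(N + Nhat)]")
  if (length(msg)) msg else TRUE
})

#' Model parameters
#'
#' The constants of the resource model, stored as a named vector:
#' \describe{
#'   \item{C_s}{spine-specific fast-resource amount (a.u.).}
#'   \item{C_d}{shared dendritic fast-resource amount (a.u.).}
#'   \item{lam}{competition exponent (dimensionless, > 0).}
#'   \item{g_eff}{Gaussian kernel coefficient (um^-2, < 0).}
#'   \item{alpha1}{fast-resource diffusion rate (um^2/min).}
#'   \item{alpha2}{fast-resource degradation rate (1/min).}
#'   \item{beta1}{slow-resource diffusion rate (um^2/min).}
#'   \item{beta2}{activation rate of the slow resource (1/(a.u. min)).}
#'   \item{gamma}{slow-resource degradation rate (1/min).}
#'   \item{rho}{baseline inactive slow-resource level (a.u.).}
#'   \item{phi}{steepness of the growth/shrink switch (> 0).}
#'   \item{nu}{normalised-size threshold of the switch (> 0).}
#'   \item{zeta1}{spine-size susceptibility to the fast resource.}
#'   \item{zeta2}{spine-size susceptibility to the slow resource.}
#' }
#'
#' @slot values named numeric of length 14 in the order above.
#'
#' @exportClass ModelParameters
setClass("ModelParameters", representation(values = "numeric"))

PARAM_NAMES <- c("C_s", "C_d", "lam", "g_eff", "alpha1", "alpha2",
                 "beta1", "beta2", "gamma", "rho", "phi", "nu",
                 "zeta1", "zeta2")
FIT_PARAM_NAMES <- setdiff(PARAM_NAMES, "g_eff")

setValidity("ModelParameters", function(object) {
  v <- object@values
  msg <- character()
  if (!identical(names(v), PARAM_NAMES))
    msg <- c(msg, sprintf("values must be named %s",
                          paste(PARAM_NAMES, collapse = ", ")))
  else {
    if (any(!is.finite(v))) msg <- c(msg, "all parameters must be finite")
    nonneg <- setdiff(PARAM_NAMES, "g_eff")
    if (any(v[nonneg] < 0))
      msg <- c(msg, "rates and amounts must be >= 0")
    if (any(v[c("lam", "phi", "nu")] <= 0))
      msg <- c(msg, "lam, phi and nu must be > 0")
    if (v["g_eff"] >= 0) msg <- c(msg, "g_eff must be < 0")
  }
  if (length(msg)) msg else TRUE
})

#' Uniform 1-D simulation grid
#'
#' @slot xMin,xMax numeric, domain edges (um).
#' @slot nPoints integer, number of grid nodes.
#'
#' @exportClass SimGrid
setClass("SimGrid",
  representation(xMin = "numeric", xMax = "numeric", nPoints = "integer"))

setValidity("SimGrid", function(object) {
  if (object@xMax <= object@xMin) return("xMax must exceed xMin")
  if (object@nPoints < 3L) return("need at least 3 grid points")
  TRUE
})

#' Result of a forward model simulation
#'
#' Per-spine time courses of the normalised size S sampled at the grid
#' nodes nearest each spine position, plus the local resource levels.
#'
#' @slot times numeric, snapshot times (min since end of stimulation).
#' @slot sizes matrix (spines x times) of normalised sizes.
#' @slot C,P,Pin matrices (spines x times) of local resource levels.
#' @slot layout the [SpineLayout-class] simulated.
#' @slot fields list of full field snapshots (empty unless requested):
#'   elements `x`, `C`, `Pin`, `P`, `S` with fields as (grid x times)
#'   matrices.
#'
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(times = "numeric", sizes = "matrix", C = "matrix",
                 P = "matrix", Pin = "matrix", layout = "SpineLayout",
                 fields = "list"))

setValidity("SimulationResult", function(object) {
  if (is.unsorted(object@times, strictly = TRUE))
    return("snapshot times must be strictly increasing")
  if (ncol(object@sizes) != length(object@times))
    return("sizes must have one column per snapshot time")
  TRUE
})

#' Cohort of spine trajectories
#'
#' A thin extension of
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one row per spine and one column per imaging snapshot. The
#' `"raw"` assay carries fluorescence-integrated volumes; after
#' [normaliseTrajectories()] the `"size"` assay carries sizes normalised
#' to each spine's pre-stimulation mean. Row metadata: `experiment_id`,
#' `spine_id`, `position_um`, `stimulated`, `paradigm`; column metadata:
#' `time_min` (negative = pre-stimulation).
#'
#' @exportClass SpineTrajectoryExperiment
setClass("SpineTrajectoryExperiment",
         contains = "SummarizedExperiment")

setValidity("SpineTrajectoryExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  need <- c("experiment_id", "spine_id", "position_um", "stimulated")
  if (!all(need %in% colnames(rd)))
    return(sprintf("rowData must contain %s", paste(need, collapse = ", ")))
  if (!"time_min" %in% colnames(cd))
    return("colData must contain time_min")
  if (is.unsorted(cd$time_min, strictly = TRUE))
    return("snapshot times must be strictly increasing")
  TRUE
})

#' Result of a model fit
#'
#' @slot par fitted [ModelParameters-class].
#' @slot cost best value of the squared-error cost.
#' @slot restarts data.frame with one row per restart: starting values,
#'   final cost, convergence code.
#' @slot seed integer seed that generated the restart starting points.
#' @slot gradientCheck data.frame comparing analytic (adjoint) and central
#'   finite-difference gradients at the optimum (empty if not requested).
#' @slot gof list with elements `nmse` and `r2w` against the fitted data
#'   (may be empty when the target has no replicate observations).
#' @slot trajectory matrix (spines x times) of the best-fit model output.
#' @slot times numeric snapshot times of `trajectory`.
#' @slot config list, the resolved fit configuration.
#'
#' @exportClass FitResult
setClass("FitResult",
  representation(par = "ModelParameters", cost = "numeric",
                 restarts = "data.frame", seed = "integer",
                 gradientCheck = "data.frame", gof = "list",
                 trajectory = "matrix", times = "numeric", config = "list"))

#' Exponential decay fit
#'
#' Least-squares fit of `a * exp(-b * t) + c` (with `b >= 0`) to a mean
#' spine-size time course, optionally with bootstrap replicate fits.
#'
#' @slot a,b,c numeric point estimates.
#' @slot identifiable logical; `FALSE` when the data do not constrain all
#'   three parameters (near-constant data or `b` at the zero bound).
#' @slot boot matrix of bootstrap replicate estimates (columns a, b, c);
#'   0 rows when no bootstrap was run.
#' @slot nBoot integer number of requested replicates.
#' @slot nFail integer number of failed replicate fits (excluded).
#' @slot seed integer RNG seed of the bootstrap.
#'
#' @exportClass ExpDecayFit
setClass("ExpDecayFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 identifiable = "logical", boot = "matrix",
                 nBoot = "integer", nFail = "integer", seed = "integer"))
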