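#' Construct a spine layout
#'
#' @param position numeric positions along the dendrite (um).
#' @param stimulated logical flag per spine.
#' @param spineId optional character labels (default `"sp1"`, `"sp2"`, ...).
#' @param paradigm stimulation paradigm; one of `"single"`, `"three"`,
#'   `"seven"`, `"seven_distributed"`, `"fifteen"`, `"sham"`.
#' @param nHat optional explicit count of competing unstimulated spines,
#'   used instead of counting from the layout (e.g. the estimate of about 7
#'   nearby heterosynaptic spines in the clustered 7-spine paradigm).
#' @return A [SpineLayout-class].
#' @examples
#' spineLayout(c(0, 1.6, 3.2), c(TRUE, TRUE, TRUE), paradigm = "three")
#' @export
spineLayout <- function(position, stimulated,
                        spineId = paste0("sp", seq_along(position)),
                        paradigm = "single", nHat = NA_real_) {
  new("SpineLayout", position = as.numeric(position),
      stimulated = as.logical(stimulated), spineId = as.character(spineId),
      paradigm = paradigm, nHatOverride = as.numeric(nHat))
}

#' @describeIn spineLayout spine positions (um).
#' @param object,x a `SpineLayout`.
#' @export
spinePositions <- function(object) object@position

#' @describeIn spineLayout logical stimulated flags.
#' @export
isStimulated <- function(object) object@stimulated

#' @describeIn spineLayout spine labels.
#' @export
spineIds <- function(object) object@spineId

#' @describeIn spineLayout the paradigm label.
#' @export
layoutParadigm <- function(object) object@paradigm

#' @describeIn spineLayout distance between outermost stimulated spines (um).
#' @export
clusterSpan <- function(object) {
  p <- object@position[object@stimulated]
  if (!length(p)) return(0)
  diff(range(p))
}

setMethod("show", "SpineLayout", function(object) {
  cat(sprintf("SpineLayout: %d spines (%d stimulated), paradigm '%s'\n",
              length(object@position), sum(object@stimulated),
              object@paradigm))
  cat(sprintf("  span of stimulated spines: %.2f um\n", clusterSpan(object)))
  if (!is.na(object@nHatOverride))
    cat(sprintf("  n_hat override: %g\n", object@nHatOverride))
})

#' Proximity sum of a stimulated spine
#'
#' For stimulated spine `i`, sums the bounded distance metric
#' `(|x_i - x_j| / (1 + |x_i - x_j|))^lam` over all other stimulated spines
#' `j`. Each summand lies in `[0, 1)`: the sum is 0 for co-located spines
#' (full competition) and approaches the number of competitors as
#' separations grow (no competition).
#'
#' @param layout a [SpineLayout-class].
#' @param lam competition exponent, > 0. Larger values discount all but the
#'   closest competitors.
#' @param i index (into the layout) of a stimulated spine.
#' @return Dimensionless scalar in `[0, n_stim - 1)`.
#' @export
proximitySum <- function(layout, lam, i) {
  if (lam <= 0) stop("lam must be > 0")
  if (i < 1 || i > length(layout@position) || !layout@stimulated[i])
    stop("spine ", i, " is not a stimulated spine of the layout")
  stim <- which(layout@stimulated)
  xi <- layout@position[i]
  r <- abs(xi - layout@position[setdiff(stim, i)])
  sum((r / (1 + r))^lam)
}

#' Count unstimulated spines competing for shared resources
#'
#' An unstimulated spine competes when it lies within `radius` of at least
#' two distinct stimulation sites, i.e. where resource profiles from
#' multiple stimulations overlap. The count is global: it enters every
#' allocation factor identically.
#'
#' @param layout a [SpineLayout-class].
#' @param radius distance threshold in um (default 2).
#' @return Non-negative integer count.
#' @export
countCompetingUnstim <- function(layout, radius = 2) {
  if (radius <= 0) stop("radius must be > 0")
  if (!is.na(layout@nHatOverride)) return(as.integer(layout@nHatOverride))
  xu <- layout@position[!layout@stimulated]
  xs <- layout@position[layout@stimulated]
  if (!length(xu) || length(xs) < 2L) return(0L)
  sum(vapply(xu, function(x) {
    sum(abs(x - xs) <= radius) >= 2L
  }, logical(1)))
}

#' Competition factors of a layout
#'
#' Computes, per stimulated spine, the allocation factor
#' `D_i = (1 + d_i) / (n_stim + n_hat)` where `d_i` is the
#' [proximitySum()] and `n_hat` the [countCompetingUnstim()] count.
#' `D_i` scales the share of the common dendritic resource the spine
#' receives: 1 for an isolated spine, `1/n_stim` for a co-located cluster
#' with no unstimulated competitors, and tending to 1 as separations grow.
#'
#' @inheritParams proximitySum
#' @param radius competing-unstimulated-spine radius in um (default 2).
#' @return A [CompetitionFactors-class].
#' @examples
#' ly <- spineLayout(c(0, 100), c(TRUE, TRUE), paradigm = "three")
#' competitionFactors(ly, lam = 1)@D  # close to 1: decoupled
#' @export
competitionFactors <- function(layout, lam, radius = 2) {
  stim <- which(layout@stimulated)
  if (!length(stim)) stop("layout has no stimulated spines")
  d <- vapply(stim, function(i) proximitySum(layout, lam, i), numeric(1))
  nhat <- countCompetingUnstim(layout, radius)
  N <- length(stim)
  new("CompetitionFactors", d = d, D = (1 + d) / (N + nhat),
      nStim = as.integer(N), nHat = as.integer(nhat))
}

setMethod("show", "CompetitionFactors", function(object) {
  cat(sprintf("CompetitionFactors: n_stim = %d, n_hat = %d\n",
              object@nStim, object@nHat))
  cat("  D:", paste(sprintf("%.4f", object@D), collapse = " "), "\n")
})

EDGE_PER_SIDE <- c(three = 1L, seven = 2L, fifteen = 4L)

#' Classify stimulated spines as edge or middle
#'
#' Labels the outermost stimulated spines of a cluster `"edge"` and the
#' inner ones `"middle"`, by sorted position: 1 spine per side for the
#' 3-spine paradigm, 2 for the 7-spine, 4 for the 15-spine. Ties from
#' duplicate positions are broken by spine id order.
#'
#' @param layout a [SpineLayout-class] with paradigm `"three"`, `"seven"` or
#'   `"fifteen"`, or any layout if `edgePerSide` is given.
#' @param edgePerSide explicit number of edge spines per side; required for
#'   paradigms without a published split.
#' @return Character vector (`"edge"`/`"middle"`) per stimulated spine, in
#'   layout order, named by spine id.
#' @export
classifyEdgeMiddle <- function(layout, edgePerSide = NULL) {
  if (is.null(edgePerSide)) {
    if (!layout@paradigm %in% names(EDGE_PER_SIDE))
      stop("no published edge/middle split for paradigm '", layout@paradigm,
           "'; supply edgePerSide explicitly")
    edgePerSide <- EDGE_PER_SIDE[[layout@paradigm]]
  }
  stim <- which(layout@stimulated)
  n <- length(stim)
  if (n < 2 * edgePerSide + 1)
    stop("need at least ", 2 * edgePerSide + 1, " stimulated spines")
  ord <- order(layout@position[stim], layout@spineId[stim])
  lab <- rep("middle", n)
  lab[ord[seq_len(edgePerSide)]] <- "edge"
  lab[ord[n + 1 - seq_len(edgePerSide)]] <- "edge"
  names(lab) <- layout@spineId[stim]
  lab
}

REFERENCE_NHAT <- c(single = 0, three = 2, seven = 7, fifteen = 13,
                    seven_distributed = 0, sham = 0)

#' Deterministic reference layout for a paradigm
#'
#' Evenly spaced stimulated spines spanning the mean reported cluster size
#' of the paradigm (3.2, 10.6 and 28.3 um for the 3-, 7- and 15-spine
#' paradigms; the distributed 7-spine layout uses 3x the clustered
#' spacing), with the count of competing unstimulated spines set by
#' override: 7 for the clustered 7-spine paradigm (the reported estimate of
#' nearby heterosynaptic spines) and values scaled with cluster length for
#' the others.
#'
#' @param paradigm stimulation paradigm.
#' @param nHat optional override of the competing-unstimulated-spine count.
#' @return A [SpineLayout-class].
#' @export
referenceLayout <- function(paradigm, nHat = REFERENCE_NHAT[[paradigm]]) {
  xs <- switch(paradigm,
    single = 0,
    three = seq(0, 3.2, length.out = 3),
    seven = seq(0, 10.6, length.out = 7),
    seven_distributed = seq(0, 6 * 3 * 10.6 / 6, length.out = 7),
    fifteen = seq(0, 28.3, length.out = 15),
    sham = seq(0, 3.2, length.out = 3),
    stop("unknown paradigm: ", paradigm))
  spineLayout(xs, rep(TRUE, length(xs)), paradigm = paradigm, nHat = nHat)
}
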