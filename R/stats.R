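# Normalisation, goodness-of-fit metrics, hypothesis tests and the
# bootstrap exponential-decay analysis.

#' Construct a spine-trajectory experiment
#'
#' @param raw numeric matrix (spines x snapshots) of raw fluorescence
#'   volumes.
#' @param times snapshot times in min (negative = pre-stimulation).
#' @param experiment_id,spine_id,position_um,stimulated per-spine metadata.
#' @param paradigm paradigm label (recycled).
#' @param size optional pre-normalised size matrix.
#' @return A [SpineTrajectoryExperiment-class].
#' @export
spineTrajectoryExperiment <- function(raw, times, experiment_id, spine_id,
                                      position_um, stimulated,
                                      paradigm = "single", size = NULL) {
  assays <- list(raw = raw)
  if (!is.null(size)) assays$size <- size
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(
      experiment_id = as.character(experiment_id),
      spine_id = as.character(spine_id),
      position_um = as.numeric(position_um),
      stimulated = as.logical(stimulated),
      paradigm = rep_len(paradigm, nrow(raw))),
    colData = S4Vectors::DataFrame(time_min = as.numeric(times)))
  new("SpineTrajectoryExperiment", se)
}

#' @describeIn spineTrajectoryExperiment snapshot times (min).
#' @param x a `SpineTrajectoryExperiment`.
#' @export
trajectoryTimes <- function(x) SummarizedExperiment::colData(x)$time_min

#' @describeIn spineTrajectoryExperiment normalised size matrix (errors if
#'   [normaliseTrajectories()] has not been applied and no size assay
#'   exists).
#' @export
normalisedSize <- function(x) {
  if (!"size" %in% SummarizedExperiment::assayNames(x))
    stop("no 'size' assay: run normaliseTrajectories() first")
  SummarizedExperiment::assay(x, "size")
}

#' Normalise trajectories to the pre-stimulation baseline
#'
#' Divides each spine's raw fluorescence by the mean of its `nPre`
#' pre-stimulation snapshots, so the pre-stimulation mean of the normalised
#' trajectory is exactly 1.
#'
#' @param x a [SpineTrajectoryExperiment-class] with a `raw` assay.
#' @param nPre number of pre-stimulation snapshots required (default 3).
#' @return The experiment with a `size` assay added.
#' @examples
#' # a spine with pre-stimulation values (1, 2, 3) and one post value 4:
#' ste <- spineTrajectoryExperiment(matrix(c(1, 2, 3, 4), 1),
#'                                  c(-6, -4, -2, 2), "e1", "sp1", 0, TRUE)
#' normalisedSize(normaliseTrajectories(ste))  # 0.5 1.0 1.5 2.0
#' @export
normaliseTrajectories <- function(x, nPre = 3) {
  tm <- trajectoryTimes(x)
  pre <- which(tm < 0)
  if (length(pre) != nPre)
    stop("expected ", nPre, " pre-stimulation snapshots, found ", length(pre))
  raw <- SummarizedExperiment::assay(x, "raw")
  base <- rowMeans(raw[, pre, drop = FALSE])
  bad <- which(!(base > 0))
  if (length(bad))
    stop("non-positive pre-stimulation mean for spine(s): ",
         paste(SummarizedExperiment::rowData(x)$spine_id[bad],
               collapse = ", "))
  SummarizedExperiment::assay(x, "size") <- raw / base
  x
}

obsAsMatrix <- function(obs) {
  if (is.list(obs)) {
    n <- max(lengths(obs))
    obs <- vapply(obs, function(o) c(o, rep(NA_real_, n - length(o))),
                  numeric(n))
  }
  as.matrix(obs)
}

#' Snapshot-averaged normalised mean squared error
#'
#' At each snapshot the squared prediction error summed over observations
#' is divided by the total squared deviation of the observations from their
#' snapshot mean; these ratios are averaged over snapshots. The metric
#' attains its minimum, exactly 1, when the prediction equals the
#' per-snapshot observation mean, so values near 1 indicate a fit that
#' tracks the mean dynamics.
#'
#' @param pred numeric vector, one prediction per snapshot.
#' @param obs matrix of observations (observations x snapshots; NAs
#'   allowed) or a list with one numeric vector per snapshot.
#' @param na.rm drop missing observations within snapshots.
#' @return Non-negative scalar.
#' @examples
#' obs <- cbind(c(0, 2), c(1, 3))
#' nmse(colMeans(obs), obs)  # exactly 1
#' nmse(c(0, 2), obs)        # 2: prediction at the low observation
#' @export
nmse <- function(pred, obs, na.rm = TRUE) {
  obs <- obsAsMatrix(obs)
  if (length(pred) != ncol(obs))
    stop("pred must have one value per snapshot (column of obs)")
  comp <- vapply(seq_along(pred), function(j) {
    o <- obs[, j]
    if (na.rm) o <- o[!is.na(o)]
    if (length(o) < 2) return(NA_real_)
    den <- sum((o - mean(o))^2)
    if (den == 0) return(NA_real_)
    sum((pred[j] - o)^2) / den
  }, numeric(1))
  if (anyNA(comp)) {
    warning(sum(is.na(comp)),
            " degenerate snapshot(s) with zero variance excluded from NMSE")
    comp <- comp[!is.na(comp)]
  }
  if (!length(comp)) stop("no snapshot with positive variance")
  mean(comp)
}

#' Variance-weighted R-squared of a trajectory prediction
#'
#' Compares predictions with per-snapshot observation means, weighting each
#' snapshot by the inverse of its observation variance, and normalises by
#' the weighted deviation of the snapshot means from the grand mean of all
#' observations. 1 is a perfect fit to the snapshot means; 0 matches a
#' constant predictor at the grand mean; negative values are worse than
#' that constant.
#'
#' @inheritParams nmse
#' @return Scalar <= 1.
#' @export
r2w <- function(pred, obs, na.rm = TRUE) {
  obs <- obsAsMatrix(obs)
  if (length(pred) != ncol(obs))
    stop("pred must have one value per snapshot (column of obs)")
  m <- numeric(length(pred)); w <- numeric(length(pred))
  for (j in seq_along(pred)) {
    o <- obs[, j]
    if (na.rm) o <- o[!is.na(o)]
    m[j] <- mean(o)
    v <- var(o)
    w[j] <- if (is.na(v) || v == 0) NA_real_ else 1 / v
  }
  if (anyNA(w)) {
    warning(sum(is.na(w)),
            " degenerate snapshot(s) with zero variance excluded from r2w")
    keep <- !is.na(w)
    pred <- pred[keep]; m <- m[keep]; w <- w[keep]; obs <- obs[, keep,
                                                               drop = FALSE]
  }
  grand <- mean(obs, na.rm = na.rm)
  den <- sum(w * (m - grand)^2)
  if (den == 0) stop("undefined metric: all snapshot means are equal")
  1 - sum(w * (pred - m)^2) / den
}

#' Pairwise Welch tests with false-discovery-rate adjustment
#'
#' Two-sided Welch (unequal variances) t tests for the requested group
#' pairs, with Benjamini-Hochberg adjustment across the comparison family.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param comparisons two-column matrix or list of length-2 vectors of
#'   group labels; default: all pairs.
#' @return data.frame: `group1`, `group2`, `t`, `df`, `p`, `p_adj`,
#'   `significant` (at 0.05).
#' @examples
#' welchFdr(c(rnorm(5), rnorm(5, 2)), rep(c("a", "b"), each = 5))
#' @export
welchFdr <- function(values, groups, comparisons = NULL) {
  groups <- as.character(groups)
  gs <- split(as.numeric(values), groups)
  if (is.null(comparisons)) {
    nm <- names(gs)
    comparisons <- t(combn(nm, 2))
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  res <- apply(comparisons, 1, function(pair) {
    a <- gs[[pair[1]]]; b <- gs[[pair[2]]]
    if (length(a) < 2 || length(b) < 2)
      stop("each group needs n >= 2: ", pair[1], " vs ", pair[2])
    if (var(a) == 0 && var(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) return(c(0, length(a) +
                                                          length(b) - 2, 1))
      stop("zero-variance groups with different means: ", pair[1], " vs ",
           pair[2])
    }
    tt <- t.test(a, b, var.equal = FALSE)
    c(unname(tt$statistic), unname(tt$parameter), tt$p.value)
  })
  out <- data.frame(group1 = comparisons[, 1], group2 = comparisons[, 2],
                    t = res[1, ], df = res[2, ], p = res[3, ])
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Studentised bootstrap confidence interval for a mean
#'
#' Bootstrap-t interval: each resample's t statistic
#' `(mean* - mean) / se*` forms the reference distribution whose quantiles
#' studentise the interval. Deterministic given the seed.
#'
#' @param values numeric sample (n >= 3).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return List: `mean`, `sem`, `lower`, `upper`, `nBoot`, `seed`.
#' @export
studentisedBootstrapCI <- function(values, nBoot = 1000, seed = 1,
                                   conf = 0.95) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  m <- mean(x); s <- sd(x); sem <- s / sqrt(n)
  if (s == 0) {
    warning("constant sample: zero-width interval")
    return(list(mean = m, sem = 0, lower = m, upper = m,
                nBoot = as.integer(nBoot), seed = as.integer(seed)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tstar <- replicate(nBoot, {
    xs <- sample(x, n, replace = TRUE)
    se <- sd(xs) / sqrt(n)
    if (se == 0) NA_real_ else (mean(xs) - m) / se
  })
  tstar <- tstar[is.finite(tstar)]
  alpha <- (1 - conf) / 2
  q <- quantile(tstar, c(1 - alpha, alpha), names = FALSE, type = 7)
  list(mean = m, sem = sem, lower = m - q[1] * sem, upper = m - q[2] * sem,
       nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Fit an exponential decay to a mean trajectory
#'
#' Least squares for `a * exp(-b * t) + c` with `b >= 0`. For fixed `b` the
#' model is linear in `(a, c)`, so the decay rate is profiled: an inner
#' linear solve gives the optimal amplitude and saturation for each `b`,
#' and the rate is found by a deterministic grid-plus-local search. No
#' random starting values are involved.
#'
#' @param times post-stimulation snapshot times (min).
#' @param values mean normalised sizes at `times`.
#' @param bMax upper bound for the decay rate (1/min).
#' @return An [ExpDecayFit-class]; `identifiable` is `FALSE` for
#'   near-constant data (`a` unidentifiable) or when `b` hits the zero
#'   bound (`a` and `c` confounded: only their sum is determined).
#' @examples
#' t <- c(2, 10, 20, 30, 40)
#' f <- fitExpDecay(t, 0.5 * exp(-0.1 * t) + 1.2)
#' c(f@a, f@b, f@c)  # recovers (0.5, 0.1, 1.2)
#' @export
fitExpDecay <- function(times, values, bMax = 5) {
  t <- as.numeric(times); y <- as.numeric(values)
  if (length(t) < 3) stop("need at least 3 snapshots to fit 3 parameters")
  if (sd(y) < 1e-12) {
    return(new("ExpDecayFit", a = 0, b = 0, c = mean(y),
               identifiable = FALSE, boot = matrix(numeric(), 0, 3),
               nBoot = 0L, nFail = 0L, seed = NA_integer_))
  }
  profile <- function(b) {
    X <- cbind(exp(-b * t), 1)
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  # deterministic profiled search over the decay rate
  bGrid <- c(0, 10^seq(-4, log10(bMax), length.out = 120))
  sse <- vapply(bGrid, profile, numeric(1))
  i <- which.min(sse)
  lo <- bGrid[max(1, i - 1)]; hi <- bGrid[min(length(bGrid), i + 1)]
  b <- if (lo == hi) lo else optimize(profile, c(lo, hi), tol = 1e-10)$minimum
  if (profile(0) <= profile(b)) b <- 0
  X <- cbind(exp(-b * t), 1)
  cf <- lm.fit(X, y)$coefficients
  a <- unname(cf[1]); cc <- unname(cf[2])
  ident <- TRUE
  if (b <= 1e-8) {  # a and c confounded; report the identified sum via c
    ident <- FALSE
    b <- 0; cc <- mean(y); a <- 0
  } else if (abs(a) < 1e-8) {
    ident <- FALSE
  }
  new("ExpDecayFit", a = a, b = b, c = cc, identifiable = ident,
      boot = matrix(numeric(), 0, 3), nBoot = 0L, nFail = 0L,
      seed = NA_integer_)
}

setMethod("show", "ExpDecayFit", function(object) {
  cat(sprintf("ExpDecayFit: a = %.4g, b = %.4g /min, c = %.4g%s\n",
              object@a, object@b, object@c,
              if (object@identifiable) "" else " (not identifiable)"))
  if (nrow(object@boot))
    cat(sprintf("  %d bootstrap replicates (%d failed), seed %d\n",
                nrow(object@boot), object@nFail, object@seed))
})

#' Bootstrap distribution of exponential-decay parameters over a cohort
#'
#' Each replicate draws half of the experiments (rounded up) with
#' replacement, averages their mean trajectories, and fits the exponential
#' decay; the replicate parameter sets form the bootstrap distributions
#' summarised by [expDecaySummary()].
#'
#' @param cohort matrix of per-experiment mean trajectories (experiments x
#'   snapshots).
#' @param times post-stimulation snapshot times (min).
#' @param nBoot replicates (default 1000).
#' @param seed RNG seed.
#' @param bMax upper bound for the decay rate.
#' @return An [ExpDecayFit-class] whose `boot` slot holds the replicate
#'   estimates; failed replicate fits are excluded and counted in `nFail`.
#' @export
bootstrapExpDecay <- function(cohort, times, nBoot = 1000, seed = 1,
                              bMax = 5) {
  cohort <- as.matrix(cohort)
  nExp <- nrow(cohort)
  if (nExp < 2) stop("need at least 2 experiments in the cohort")
  point <- fitExpDecay(times, colMeans(cohort), bMax = bMax)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  k <- ceiling(nExp / 2)
  draws <- matrix(sample.int(nExp, k * nBoot, replace = TRUE), nrow = nBoot)
  boot <- matrix(NA_real_, nBoot, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  nFail <- 0L
  for (r in seq_len(nBoot)) {
    m <- colMeans(cohort[draws[r, ], , drop = FALSE])
    f <- tryCatch(fitExpDecay(times, m, bMax = bMax), error = function(e) NULL)
    if (is.null(f)) nFail <- nFail + 1L else boot[r, ] <- c(f@a, f@b, f@c)
  }
  boot <- boot[!is.na(boot[, 1]), , drop = FALSE]
  new("ExpDecayFit", a = point@a, b = point@b, c = point@c,
      identifiable = point@identifiable, boot = boot,
      nBoot = as.integer(nBoot), nFail = nFail, seed = as.integer(seed))
}

#' Summarise a bootstrap exponential-decay fit
#'
#' @param fit an [ExpDecayFit-class] from [bootstrapExpDecay()].
#' @return data.frame with one row per parameter: point estimate, bootstrap
#'   mean/median, interquartile range and 95% confidence interval.
#' @export
expDecaySummary <- function(fit) {
  if (!nrow(fit@boot)) stop("fit carries no bootstrap replicates")
  point <- c(a = fit@a, b = fit@b, c = fit@c)
  do.call(rbind, lapply(colnames(fit@boot), function(p) {
    x <- fit@boot[, p]
    q <- quantile(x, c(0.25, 0.75, 0.025, 0.975), names = FALSE)
    data.frame(parameter = p, estimate = unname(point[p]),
               boot_mean = mean(x), boot_median = median(x),
               iqr_lower = q[1], iqr_upper = q[2],
               ci_lower = q[3], ci_upper = q[4])
  }))
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' Runs the Kruskal-Wallis rank-sum test across the groups and, when the
#' omnibus test is defined, Dunn's pairwise z tests on the joint ranks with
#' the tie correction, adjusted across pairs by Benjamini-Hochberg.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List: `omnibus_p`, `statistic`, and data.frame `pairwise`
#'   (`group1`, `group2`, `z`, `p`, `p_adj`), which is `NULL` when all
#'   values are tied.
#' @export
kruskalDunnFdr <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L)
    return(list(omnibus_p = 1, statistic = 0, pairwise = NULL))
  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- t(combn(names(groups), 2))
  z <- apply(pairs, 1, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2], z = z,
                   p = 2 * pnorm(-abs(z)))
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  list(omnibus_p = unname(kw$p.value), statistic = unname(kw$statistic),
       pairwise = pw)
}
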