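# Plain-text interchange: layout CSV, trajectory CSV, fit JSON.
# All numeric columns round-trip at full double precision.

fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a spine layout as CSV
#'
#' Columns: `experiment_id`, `spine_id`, `position_um`, `stimulated` (0/1),
#' `paradigm`.
#'
#' @param layout a [SpineLayout-class].
#' @param path file path.
#' @param experiment id written to the `experiment_id` column.
#' @return `readLayoutCsv` returns a named list of [SpineLayout-class]
#'   (one per `experiment_id`); `writeLayoutCsv` returns `path`
#'   invisibly.
#' @export
writeLayoutCsv <- function(layout, path, experiment = "e1") {
  df <- data.frame(experiment_id = experiment,
                   spine_id = layout@spineId,
                   position_um = fmt(layout@position),
                   stimulated = as.integer(layout@stimulated),
                   paradigm = layout@paradigm)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLayoutCsv
#' @export
readLayoutCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "spine_id", "position_um", "stimulated",
            "paradigm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("layout CSV is missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$experiment_id), function(d) {
    spineLayout(as.numeric(d$position_um), d$stimulated == 1,
                d$spine_id, paradigm = d$paradigm[1])
  })
}

#' Write / read spine trajectories as CSV
#'
#' Long format, one row per (spine, snapshot): `experiment_id`,
#' `spine_id`, `position_um`, `stimulated`, `paradigm`, `time_min`,
#' `raw_fluorescence`, `norm_size` (empty before normalisation).
#'
#' @param x a [SpineTrajectoryExperiment-class].
#' @param path file path.
#' @return `readTrajectoryCsv` returns a [SpineTrajectoryExperiment-class];
#'   `writeTrajectoryCsv` returns `path` invisibly.
#' @export
writeTrajectoryCsv <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  tm <- trajectoryTimes(x)
  raw <- SummarizedExperiment::assay(x, "raw")
  hasSize <- "size" %in% SummarizedExperiment::assayNames(x)
  size <- if (hasSize) SummarizedExperiment::assay(x, "size")
  n <- nrow(raw); k <- length(tm)
  df <- data.frame(
    experiment_id = rep(rd$experiment_id, k),
    spine_id = rep(rd$spine_id, k),
    position_um = fmt(rep(rd$position_um, k)),
    stimulated = rep(as.integer(rd$stimulated), k),
    paradigm = rep(rd$paradigm, k),
    time_min = fmt(rep(tm, each = n)),
    raw_fluorescence = fmt(as.vector(raw)),
    norm_size = if (hasSize) fmt(as.vector(size)) else "")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "spine_id", "position_um", "stimulated",
            "time_min", "raw_fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  times <- sort(unique(as.numeric(df$time_min)))
  key <- paste(df$experiment_id, df$spine_id, sep = "\r")
  spines <- unique(key)
  idx <- cbind(match(key, spines), match(as.numeric(df$time_min), times))
  raw <- matrix(NA_real_, length(spines), length(times))
  raw[idx] <- as.numeric(df$raw_fluorescence)
  size <- NULL
  if ("norm_size" %in% names(df) && !all(is.na(df$norm_size)) &&
      !all(df$norm_size == "")) {
    size <- matrix(NA_real_, length(spines), length(times))
    size[idx] <- as.numeric(df$norm_size)
  }
  first <- match(spines, key)
  spineTrajectoryExperiment(
    raw = raw, times = times,
    experiment_id = df$experiment_id[first],
    spine_id = df$spine_id[first],
    position_um = as.numeric(df$position_um[first]),
    stimulated = df$stimulated[first] == 1,
    paradigm = if ("paradigm" %in% names(df)) df$paradigm[first] else
      "single",
    size = size)
}

#' Write / read a simulation result as CSV
#'
#' Columns: `experiment_id`, `spine_id`, `position_um`, `time_min`,
#' `model_size`.
#'
#' @param result a [SimulationResult-class].
#' @param path file path.
#' @param experiment id for the `experiment_id` column.
#' @return `path`, invisibly.
#' @export
writeSimulationCsv <- function(result, path, experiment = "e1") {
  keep <- result@layout@spineId %in% rownames(result@sizes)
  pos <- result@layout@position[keep]
  n <- nrow(result@sizes); k <- length(result@times)
  df <- data.frame(
    experiment_id = experiment,
    spine_id = rep(rownames(result@sizes), k),
    position_um = fmt(rep(pos, k)),
    time_min = fmt(rep(result@times, each = n)),
    model_size = fmt(as.vector(result@sizes)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise / restore a fit result as JSON
#'
#' The JSON object carries the fitted parameters, best cost, per-restart
#' diagnostics, seed, solver and optimiser settings, and the
#' goodness-of-fit block.
#'
#' @param fit a [FitResult-class].
#' @param path file path.
#' @return `readFitJson` returns a list with a `parameters` element
#'   restored as [ModelParameters-class]; `writeFitJson` returns `path`
#'   invisibly.
#' @export
writeFitJson <- function(fit, path) {
  obj <- list(parameters = as.list(paramValues(fit@par)),
              cost = fit@cost,
              seed = fit@seed,
              restarts = fit@restarts,
              times = fit@times,
              gof = fit@gof,
              config = fit@config[c("nRestarts", "gradient", "free",
                                    "maxit", "factr", "dt", "spacing",
                                    "pad", "radius")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeFitJson
#' @export
readFitJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- do.call(modelParameters, obj$parameters)
  obj
}
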