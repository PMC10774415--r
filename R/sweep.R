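## Parameter sweeps over cleavage, R2/R1 and HDR rates, and smoothing of the
## extinction response with local polynomial regression (tricube-weighted
## local least squares on standardised axes, via stats::loess).

#' Define a parameter sweep grid
#'
#' @param axes Named list over a subset of `"cleavage"`, `"r2"`, `"hdr"`;
#'   each element a numeric vector of values to sweep. Non-swept parameters
#'   are taken from `baseConfig`'s params.
#' @param replicates Replicate simulations per grid point.
#' @param baseConfig A [simConfig()] providing the design, fixed parameters
#'   and population scenario.
#' @return A `SweepGrid`. The total number of simulations is the product of
#'   the axis lengths times `replicates`.
#' @export
#' @examples
#' base <- simConfig(driveDesign("SSC"), driveParams(0.9, 0.95, 0.99))
#' g <- sweepGrid(list(cleavage = c(0.8, 1), r2 = c(0.5, 1)),
#'                replicates = 2, baseConfig = base)
sweepGrid <- function(axes, replicates, baseConfig) {
  new("SweepGrid", axes = axes, replicates = as.integer(replicates),
      baseConfig = baseConfig)
}

setMethod("show", "SweepGrid", function(object) {
  dims <- vapply(object@axes, length, integer(1))
  cat("SweepGrid:", paste(sprintf("%s(%d)", names(dims), dims),
                          collapse = " x "),
      "x", object@replicates, "replicates =",
      prod(dims) * object@replicates, "simulations\n")
})

#' Sweep presets
#'
#' Two shipped sweep dialects over a 6 x 6 grid with 10 replicates per
#' point (360 simulations):
#'
#' * `"extinction"` — cleavage rate x R2 fraction at fixed HDR 0.95; the
#'   response of interest is the extinction fraction over the 20-generation
#'   horizon.
#' * `"duration"` — cleavage rate x HDR rate at fixed R2/R1 = 0.99/0.01; the
#'   response of interest is the mean duration to extinction.
#'
#' @param name Preset name.
#' @param design A [driveDesign()].
#' @param replicates Replicates per grid point (default 10).
#' @param populationSize,generations Scenario size and horizon.
#' @return A `SweepGrid`.
#' @export
sweepPreset <- function(name = c("extinction", "duration"), design,
                        replicates = 10, populationSize = 1000,
                        generations = 20) {
  name <- match.arg(name)
  if (name == "extinction") {
    axes <- list(cleavage = seq(0.5, 1, length.out = 6),
                 r2 = seq(0, 1, length.out = 6))
    params <- driveParams(cleavage = 0.95, hdr = 0.95, r2 = 0.99)
  } else {
    axes <- list(cleavage = seq(0.5, 1, length.out = 6),
                 hdr = seq(0.5, 1, length.out = 6))
    params <- driveParams(cleavage = 0.95, hdr = 0.95, r2 = 0.99)
  }
  sweepGrid(axes, replicates,
            simConfig(design, params, populationSize = populationSize,
                      generations = generations))
}

#' Execute a parameter sweep
#'
#' Runs [runSimulation()] for every grid point and replicate, each under an
#' independent sub-seed drawn deterministically from the master seed, and
#' summarises each grid point with [summarizeReplicates()]. Row order and
#' results are fully deterministic given the grid and seed.
#'
#' @param grid A [sweepGrid()] or [sweepPreset()].
#' @param seed Master seed for the whole sweep.
#' @param design Optional [driveDesign()] overriding the grid's base config.
#' @param time Passed to [summarizeReplicates()].
#' @return A data.frame with one row per grid point: `design`, the full
#'   parameter set, `extinction_fraction`, `mean_time_to_extinction`,
#'   `n_replicates`. Attributes `axes` (swept axis names) and `config`
#'   (scenario echo) are attached.
#' @export
runSweep <- function(grid, seed, design = NULL,
                     time = c("extinct_only", "censored")) {
  stopifnot(is(grid, "SweepGrid"))
  validObject(grid)
  time <- match.arg(time)
  base <- grid@baseConfig
  if (!is.null(design)) base@design <- design
  points <- expand.grid(grid@axes, KEEP.OUT.ATTRS = FALSE)
  reps <- grid@replicates
  seeds <- matrix(replicateSeeds(seed, nrow(points) * reps), nrow = reps)

  rows <- lapply(seq_len(nrow(points)), function(i) {
    p <- base@params
    for (ax in names(points)) slot(p, ax) <- points[[ax]][i]
    results <- lapply(seq_len(reps), function(r) {
      cfg <- base
      cfg@params <- p
      cfg@seed <- seeds[r, i]
      tryCatch(runSimulation(cfg), error = function(e)
        stop("sweep failed at grid point ", i, " (",
             paste(sprintf("%s=%g", names(points), unlist(points[i, ])),
                   collapse = ", "), "): ", conditionMessage(e)))
    })
    s <- summarizeReplicates(results, time = time)
    data.frame(design = designName(base@design),
               cleavage = p@cleavage, hdr = p@hdr, r2 = p@r2,
               maternal_factor = p@maternalFactor,
               extinction_fraction = s$extinction_fraction,
               mean_time_to_extinction = s$mean_time_to_extinction,
               n_replicates = s$n_replicates)
  })
  out <- do.call(rbind, rows)
  attr(out, "axes") <- names(grid@axes)
  attr(out, "config") <- list(
    design = designName(base@design), population_size = base@populationSize,
    generations = base@generations, replicates = reps, seed = seed,
    axes = grid@axes,
    fixed_params = list(cleavage = base@params@cleavage,
                        hdr = base@params@hdr, r2 = base@params@r2,
                        maternal_factor = base@params@maternalFactor))
  out
}

#' Write / read sweep results as TSV
#'
#' The writer embeds the full sweep configuration as `#`-prefixed header
#' comments for provenance; the reader skips them and re-infers the swept
#' axes from the varying parameter columns.
#'
#' @param result A [runSweep()] data.frame.
#' @param path TSV path.
#' @return `writeSweepResult()` returns `path` invisibly;
#'   `readSweepResult()` the data.frame with an `axes` attribute.
#' @export
writeSweepResult <- function(result, path) {
  cfg <- attr(result, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(paste0("# ", jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                             digits = NA)), con)
  writeLines(paste0("# axes: ", paste(attr(result, "axes"), collapse = ",")),
             con)
  write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSweepResult
#' @export
readSweepResult <- function(path) {
  out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  varying <- c("cleavage", "hdr", "r2")[vapply(c("cleavage", "hdr", "r2"),
    function(cn) length(unique(out[[cn]])) > 1, logical(1))]
  header <- grep("^# axes:", readLines(path, n = 5), value = TRUE)
  attr(out, "axes") <- if (length(header))
    strsplit(sub("^# axes: *", "", header[1]), ",")[[1]] else varying
  out
}

#' Smooth a two-axis extinction response surface
#'
#' Fits a local polynomial regression (tricube distance weights on
#' standardised axes; `stats::loess` with direct surface evaluation) to the
#' per-grid-point response of a two-axis sweep, and evaluates it on a dense
#' regular grid. Extinction fractions are clamped to `[0, 1]` after fitting.
#'
#' @param result A [runSweep()] data.frame whose grid swept exactly two
#'   axes.
#' @param span Smoothing span: the fraction of grid points entering each
#'   local fit (default 0.75).
#' @param degree Local polynomial degree, 0, 1 or 2 (default 2).
#' @param response Response column to smooth, default
#'   `"extinction_fraction"`.
#' @param n Dense output grid resolution per axis (default 40).
#' @param clamp Clamp the fitted surface to `[0, 1]` (default `TRUE` for
#'   the extinction fraction; durations are never clamped).
#' @return Data.frame with the two axis columns and `fitted`.
#' @export
smoothExtinctionSurface <- function(result, span = 0.75, degree = 2,
                                    response = "extinction_fraction",
                                    n = 40,
                                    clamp = response == "extinction_fraction") {
  axes <- attr(result, "axes")
  if (is.null(axes) || length(axes) != 2)
    stop("smoothing requires a sweep over exactly two axes")
  if (!response %in% names(result)) stop("no response column '", response, "'")
  dat <- data.frame(x = result[[axes[1]]], y = result[[axes[2]]],
                    z = result[[response]])
  dat <- dat[is.finite(dat$z), ]
  npar <- switch(as.character(degree), "0" = 1, "1" = 3, "2" = 6,
                 stop("degree must be 0, 1 or 2"))
  if (floor(span * nrow(dat)) < npar)
    stop(sprintf(
      "local window of %d points is too small for a degree-%d fit (needs >= %d)",
      floor(span * nrow(dat)), degree, npar))
  fit <- stats::loess(z ~ x + y, data = dat, span = span, degree = degree,
                      family = "gaussian", normalize = TRUE,
                      surface = "direct")
  gx <- seq(min(dat$x), max(dat$x), length.out = n)
  gy <- seq(min(dat$y), max(dat$y), length.out = n)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  fitted <- as.vector(predict(fit, newdata = grid))
  if (clamp) fitted <- pmin(1, pmax(0, fitted))
  out <- data.frame(grid$x, grid$y, fitted)
  names(out) <- c(axes, "fitted")
  out
}
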