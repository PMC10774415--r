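## Config and result I/O: JSON/YAML scenario files, per-generation TSV
## trajectories, JSON summaries.

#' Read a simulation scenario file
#'
#' Reads a JSON or YAML scenario (dispatch on file extension) with keys
#' mirroring [simConfig()]: `design`, `params` (with `cleavage`, `hdr`,
#' `r2`, optional `maternal_factor`), and optional `population_size`,
#' `generations`, `n_wt_females`, `n_wt_males`, `n_drive_males`, `seed`.
#' Unknown keys, missing required keys and inconsistent compositions are
#' rejected with explicit messages.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `SimConfig`.
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("design", "params", "population_size", "generations",
             "n_wt_females", "n_wt_males", "n_drive_males", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown scenario keys: ", paste(bad, collapse = ", "),
         " (expected a subset of: ", paste(known, collapse = ", "), ")")
  for (key in c("design", "params"))
    if (is.null(raw[[key]])) stop("scenario is missing required key '", key, "'")
  pk <- raw$params
  for (key in c("cleavage", "hdr", "r2"))
    if (is.null(pk[[key]])) stop("params is missing required key '", key, "'")
  params <- driveParams(pk$cleavage, pk$hdr, pk$r2,
                        maternalFactor = pk$maternal_factor %||% 1)
  N <- as.integer(raw$population_size %||% 1000L)
  args <- list(design = driveDesign(raw$design), params = params,
               populationSize = N,
               generations = as.integer(raw$generations %||% 20L),
               seed = as.integer(raw$seed %||% 1L))
  for (nm in c("n_wt_females", "n_wt_males", "n_drive_males"))
    if (!is.null(raw[[nm]])) {
      camel <- c(n_wt_females = "nWtFemales", n_wt_males = "nWtMales",
                 n_drive_males = "nDriveMales")[[nm]]
      args[[camel]] <- as.integer(raw[[nm]])
    }
  cfg <- do.call(simConfig, args)
  validObject(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write replicate trajectories as TSV
#'
#' One row per generation per replicate: replicate index, generation, size,
#' fertile females/males and per-locus allele-class counts.
#'
#' @param results List of `SimResult` objects.
#' @param path Output TSV path.
#' @return The combined data.frame, invisibly.
#' @export
writeTrajectories <- function(results, path) {
  tabs <- lapply(seq_along(results), function(i) {
    tr <- trajectory(results[[i]])
    cbind(replicate = i, tr)
  })
  out <- do.call(rbind, tabs)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a replicate summary as JSON
#'
#' Writes [summarizeReplicates()] output together with an echo of the
#' scenario configuration.
#'
#' @param summary Output of [summarizeReplicates()].
#' @param config The `SimConfig` the replicates were run under.
#' @param path Output JSON path.
#' @export
writeSummary <- function(summary, config, path) {
  out <- c(summary, list(config = list(
    design = designName(config@design),
    population_size = config@populationSize,
    generations = config@generations,
    n_wt_females = config@nWtFemales,
    n_wt_males = config@nWtMales,
    n_drive_males = config@nDriveMales,
    params = list(cleavage = cleavageRate(config@params),
                  hdr = hdrRate(config@params),
                  r2 = r2Fraction(config@params),
                  maternal_factor = maternalFactor(config@params)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(out)
}
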