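#' @import methods
#' @importFrom stats runif rbinom setNames loess predict chisq.test prop.test
#'   pchisq aggregate
#' @importFrom utils read.delim write.table modifyList
NULL

## Allele state codes. Integers internally (population tables), characters at
## the user surface. WILD is the only cleavable state; DRIVE and R2 abolish
## target-gene function, R1 retains it.
.ALLELES <- c(WILD = 1L, DRIVE = 2L, R1 = 3L, R2 = 4L)
.LOCI <- c("FERTILITY_1", "TRA", "FERTILITY_2")
.DESIGNS <- c("FEMALE_FERTILITY", "TRA_HOMING", "SSC", "DUAL_FERTILITY")

#' Allele states of a drive target locus
#'
#' The four per-chromosome states a modelled locus can take: `WILD` (intact,
#' cleavable target site), `DRIVE` (the homing construct, disrupting the
#' gene), `R1` (cleavage-resistant indel retaining gene function) and `R2`
#' (cleavage-resistant indel abolishing gene function).
#'
#' @return Character vector of the four state names.
#' @export
#' @examples
#' alleleStates()
alleleStates <- function() names(.ALLELES)

#' Locus identifiers of the drive architectures
#'
#' `FERTILITY_1` and `FERTILITY_2` are recessive female-fertility genes;
#' `TRA` is the medfly master female-determining gene *transformer*.
#'
#' @return Character vector of locus names.
#' @export
locusIds <- function() .LOCI

#' @rdname driveDesign
#' @export
designNames <- function() .DESIGNS

setClass("DriveDesign",
  representation(name = "character", homeLocus = "character",
                 transTarget = "character"))

setValidity("DriveDesign", function(object) {
  msg <- character()
  if (!object@name %in% .DESIGNS)
    msg <- c(msg, sprintf("unknown design '%s'", object@name))
  archetype <- switch(object@name,
    FEMALE_FERTILITY = c("FERTILITY_1", NA),
    TRA_HOMING       = c("TRA", NA),
    SSC              = c("FERTILITY_1", "TRA"),
    DUAL_FERTILITY   = c("FERTILITY_1", "FERTILITY_2"),
    NULL)
  if (!is.null(archetype)) {
    if (!identical(object@homeLocus, archetype[[1]]))
      msg <- c(msg, sprintf("%s must home into %s", object@name, archetype[[1]]))
    if (!identical(object@transTarget, archetype[[2]]))
      msg <- c(msg, sprintf("%s trans target must be %s", object@name,
                            ifelse(is.na(archetype[[2]]), "absent", archetype[[2]])))
  }
  if (length(msg)) msg else TRUE
})

setClass("DriveParams",
  representation(cleavage = "numeric", hdr = "numeric", r2 = "numeric",
                 maternalFactor = "numeric"))

setValidity("DriveParams", function(object) {
  msg <- character()
  for (s in c("cleavage", "hdr", "r2")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a single probability in [0, 1]", s))
  }
  k <- object@maternalFactor
  if (length(k) != 1 || is.na(k) || k < 0)
    msg <- c(msg, "'maternalFactor' must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

setClass("SimConfig",
  representation(populationSize = "integer", generations = "integer",
                 nWtFemales = "integer", nWtMales = "integer",
                 nDriveMales = "integer", design = "DriveDesign",
                 params = "DriveParams", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  for (s in c("populationSize", "generations")) {
    if (slot(object, s) < 1L)
      msg <- c(msg, sprintf("'%s' must be positive", s))
  }
  counts <- c(object@nWtFemales, object@nWtMales, object@nDriveMales)
  if (any(counts < 0L))
    msg <- c(msg, "initial class counts must be nonnegative")
  if (sum(counts) != object@populationSize)
    msg <- c(msg, sprintf(
      "initial composition (%d + %d + %d) must sum to populationSize (%d)",
      counts[1], counts[2], counts[3], object@populationSize))
  if (length(msg)) msg else TRUE
})

setClass("SimResult",
  representation(trajectory = "data.frame", extinct = "logical",
                 extinctionGeneration = "integer", config = "SimConfig"))

setValidity("SimResult", function(object) {
  msg <- character()
  if (object@extinct && is.na(object@extinctionGeneration))
    msg <- c(msg, "extinct runs must record an extinction generation")
  if (!object@extinct && !is.na(object@extinctionGeneration))
    msg <- c(msg, "non-extinct runs must not record an extinction generation")
  if (length(msg)) msg else TRUE
})

setClass("CrossCounts",
  representation(counts = "data.frame", parentSex = "character",
                 mateType = "character", trueParams = "ANY",
                 design = "ANY"))

setValidity("CrossCounts", function(object) {
  msg <- character()
  needed <- c("replicate", "marker", "sex_phenotype", "eye_phenotype", "count")
  if (!all(needed %in% names(object@counts)))
    msg <- c(msg, paste("counts table must have columns:",
                        paste(needed, collapse = ", ")))
  else {
    if (any(object@counts$count < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (!all(object@counts$marker %in% c("POSITIVE", "NEGATIVE")))
      msg <- c(msg, "marker must be POSITIVE or NEGATIVE")
    if (!all(is.na(object@counts$sex_phenotype) |
             object@counts$sex_phenotype %in% c("MALE", "FEMALE", "INTERSEX")))
      msg <- c(msg, "sex_phenotype must be MALE, FEMALE, INTERSEX or NA")
    if (!all(is.na(object@counts$eye_phenotype) |
             object@counts$eye_phenotype %in% c("RED", "MOSAIC", "WHITE")))
      msg <- c(msg, "eye_phenotype must be RED, MOSAIC, WHITE or NA")
  }
  if (!object@parentSex %in% c("female", "male"))
    msg <- c(msg, "parentSex must be 'female' or 'male'")
  if (!object@mateType %in% c("WILD_TYPE", "EYE_MUTANT"))
    msg <- c(msg, "mateType must be WILD_TYPE or EYE_MUTANT")
  if (length(msg)) msg else TRUE
})

setClass("SweepGrid",
  representation(axes = "list", replicates = "integer",
                 baseConfig = "SimConfig"))

setValidity("SweepGrid", function(object) {
  msg <- character()
  ok <- c("cleavage", "r2", "hdr")
  if (length(object@axes) < 1 || is.null(names(object@axes)) ||
      !all(names(object@axes) %in% ok))
    msg <- c(msg, paste("axes must be a named list over a subset of:",
                        paste(ok, collapse = ", ")))
  if (anyDuplicated(names(object@axes)))
    msg <- c(msg, "duplicate axis names")
  for (ax in object@axes) {
    if (!is.numeric(ax) || length(ax) < 1 || any(ax < 0) || any(ax > 1))
      msg <- c(msg, "each axis must be a numeric vector of probabilities")
  }
  if (object@replicates < 1L)
    msg <- c(msg, "'replicates' must be positive")
  if (length(msg)) msg else TRUE
})
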