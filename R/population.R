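## Discrete-generation stochastic population model. A population is a
## data.frame with one row per fly: integer allele codes for the three loci
## (maternal/paternal columns), karyotype, maternal tra provision flag, and
## the derived sex and fertility. Generations are produced with fully
## vectorised draws (one vector operation per locus per generation), which
## keeps 20-generation runs at N = 1000 in the low milliseconds.

.locusCols <- list(FERTILITY_1 = c("f1_m", "f1_p"),
                   TRA         = c("tra_m", "tra_p"),
                   FERTILITY_2 = c("f2_m", "f2_p"))

## derive sex/fertility columns from genotype columns, vectorised
.classify <- function(pop, design) {
  pop$sex <- determineSex(pop$karyotype, pop$tra_m, pop$tra_p,
                          pop$maternalTraIntact)
  geno <- lapply(.locusCols, function(cols) cbind(pop[[cols[1]]], pop[[cols[2]]]))
  pop$fertile <- determineFertility(pop$sex, geno, design)
  pop
}

.emptyPopulation <- function() {
  data.frame(karyotype = character(0), f1_m = integer(0), f1_p = integer(0),
             tra_m = integer(0), tra_p = integer(0), f2_m = integer(0),
             f2_p = integer(0), maternalTraIntact = logical(0),
             sex = character(0), fertile = logical(0))
}

#' Simulation configuration
#'
#' Bundles the release scenario: a population of `populationSize` flies with
#' discrete generations, initialised as `nWtFemales` wild-type females,
#' `nWtMales` wild-type males and `nDriveMales` males hemizygous for the
#' construct at the design's home locus. The defaults (500/250/250 in a
#' population of 1000, 20 generations) give a starting drive allele
#' frequency of 12.5%.
#'
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @param populationSize Constant population size N.
#' @param generations Run horizon G.
#' @param nWtFemales,nWtMales,nDriveMales Initial composition; must sum to
#'   `populationSize`.
#' @param seed Integer seed making the run reproducible.
#' @return A `SimConfig` object.
#' @export
#' @examples
#' cfg <- simConfig(driveDesign("SSC"), driveParams(0.95, 0.95, 0.99),
#'                  seed = 1)
simConfig <- function(design, params, populationSize = 1000L,
                      generations = 20L, nWtFemales = populationSize %/% 2L,
                      nWtMales = populationSize %/% 4L,
                      nDriveMales = populationSize - nWtFemales - nWtMales,
                      seed = 1L) {
  new("SimConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      nWtFemales = as.integer(nWtFemales), nWtMales = as.integer(nWtMales),
      nDriveMales = as.integer(nDriveMales), design = design, params = params,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@design@name, "\n")
  cat(sprintf("  N=%d, G=%d, init %d WT females / %d WT males / %d drive males\n",
              object@populationSize, object@generations, object@nWtFemales,
              object@nWtMales, object@nDriveMales))
  cat(sprintf("  c=%.3g h=%.3g r2=%.3g k=%.3g, seed=%d\n",
              object@params@cleavage, object@params@hdr, object@params@r2,
              object@params@maternalFactor, object@seed))
})

#' Initial release population
#'
#' Builds the starting population of a run: wild-type females and males plus
#' hemizygous drive males carrying `(DRIVE, WILD)` at the design's home
#' locus (all other loci wild type, maternal *tra* provision intact).
#'
#' @param config A [simConfig()].
#' @return A population data.frame (one row per fly).
#' @export
#' @examples
#' cfg <- simConfig(driveDesign("SSC"), driveParams(0.95, 0.95, 0.99))
#' pop <- makeInitialPopulation(cfg)
#' driveAlleleFrequency(pop, homeLocus(driveDesign("SSC")))  # 0.125
makeInitialPopulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@populationSize
  pop <- data.frame(
    karyotype = rep(c("XX", "XY"), c(config@nWtFemales,
                                     config@nWtMales + config@nDriveMales)),
    f1_m = rep(.WILD, n), f1_p = rep(.WILD, n),
    tra_m = rep(.WILD, n), tra_p = rep(.WILD, n),
    f2_m = rep(.WILD, n), f2_p = rep(.WILD, n),
    maternalTraIntact = rep(TRUE, n))
  if (config@nDriveMales > 0) {
    rows <- seq(n - config@nDriveMales + 1L, n)
    matCol <- .locusCols[[homeLocus(config@design)]][1]
    pop[rows, matCol] <- .DRIVE
  }
  .classify(pop, config@design)
}

#' Allele frequency in a population
#'
#' @param population A population data.frame.
#' @param locus A locus id (see [locusIds()]).
#' @param allele Allele state to count (default `"DRIVE"`).
#' @return Frequency among the 2N allele copies at the locus (NaN for an
#'   empty population).
#' @export
driveAlleleFrequency <- function(population, locus, allele = "DRIVE") {
  cols <- .locusCols[[locus]]
  if (is.null(cols)) stop("unknown locus '", locus, "'")
  code <- .ALLELES[[allele]]
  mean(c(population[[cols[1]]], population[[cols[2]]]) == code)
}

## one-generation vectorised gamete draw for a parent column set; germline
## Cas9 activity only occurs in parents that carry the construct
.drawParentGametes <- function(pop, parents, design, params) {
  n <- length(parents)
  homeCols <- .locusCols[[homeLocus(design)]]
  carrier <- pop[[homeCols[1]]][parents] == .DRIVE |
    pop[[homeCols[2]]][parents] == .DRIVE
  out <- list()
  for (locus in .LOCI) {
    cols <- .locusCols[[locus]]
    a1 <- pop[[cols[1]]][parents]
    a2 <- pop[[cols[2]]][parents]
    resolved <- cbind(a1, a2, deparse.level = 0)
    if (locus %in% targetedLoci(design) && any(carrier)) {
      resolved[carrier, ] <- .resolveGermlineVec(
        a1[carrier], a2[carrier], locus == homeLocus(design),
        params@cleavage, params@hdr, params@r2)
    }
    pickFirst <- runif(n) < 0.5
    out[[locus]] <- ifelse(pickFirst, resolved[, 1], resolved[, 2])
  }
  out
}

#' Advance the population one generation
#'
#' If the population has no fertile female or no fertile male it collapses
#' (an empty population is returned). Otherwise exactly N offspring are
#' produced; each offspring independently draws a mother uniformly from the
#' fertile females and a father uniformly from the fertile males (with
#' replacement), one gamete from each parent (an independent meiosis per
#' offspring), takes its karyotype from the paternal sex chromosome, is
#' subjected to maternal Cas9 deposition, draws its maternal *tra* provision
#' from its mother, and is then classified for sex and fertility.
#'
#' @param population A population data.frame.
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @param n Number of offspring; defaults to the current population size.
#' @return The offspring population data.frame.
#' @export
stepGeneration <- function(population, design, params,
                           n = nrow(population)) {
  stopifnot(is(design, "DriveDesign"), is(params, "DriveParams"))
  femIdx <- which(population$sex == "FEMALE" & population$fertile)
  malIdx <- which(population$sex == "MALE" & population$fertile)
  if (length(femIdx) == 0 || length(malIdx) == 0 || n == 0)
    return(.emptyPopulation())

  mothers <- femIdx[sample.int(length(femIdx), n, replace = TRUE)]
  fathers <- malIdx[sample.int(length(malIdx), n, replace = TRUE)]

  mg <- .drawParentGametes(population, mothers, design, params)
  fg <- .drawParentGametes(population, fathers, design, params)

  pop <- data.frame(
    karyotype = ifelse(runif(n) < 0.5, "XY", "XX"),
    f1_m = mg$FERTILITY_1, f1_p = fg$FERTILITY_1,
    tra_m = mg$TRA, tra_p = fg$TRA,
    f2_m = mg$FERTILITY_2, f2_p = fg$FERTILITY_2)

  ## maternal Cas9 deposition: NHEJ-only embryonic cleavage of WILD alleles
  ## at targeted loci in offspring of construct-carrying mothers
  homeCols <- .locusCols[[homeLocus(design)]]
  motherCarries <- population[[homeCols[1]]][mothers] == .DRIVE |
    population[[homeCols[2]]][mothers] == .DRIVE
  mc <- min(1, params@maternalFactor * params@cleavage)
  if (mc > 0 && any(motherCarries)) {
    for (locus in targetedLoci(design)) {
      cols <- .locusCols[[locus]]
      pop[[cols[1]]] <- .depositAllele(pop[[cols[1]]], motherCarries, mc,
                                       params@r2)
      pop[[cols[2]]] <- .depositAllele(pop[[cols[2]]], motherCarries, mc,
                                       params@r2)
    }
  }

  ## maternal tra provision: lost iff every functional maternal tra allele
  ## is disrupted in the ovary, each independently with probability c
  if (targetsTra(design)) {
    nFunc <- isFunctional(population$tra_m[mothers]) +
      isFunctional(population$tra_p[mothers])
    pLost <- ifelse(motherCarries, params@cleavage^nFunc, 0)
    pop$maternalTraIntact <- runif(n) >= pLost
  } else {
    pop$maternalTraIntact <- rep(TRUE, n)
  }

  .classify(pop, design)
}

## per-generation trajectory record
.trajectoryRow <- function(pop, generation) {
  row <- data.frame(generation = generation, size = nrow(pop),
                    fertile_females = sum(pop$sex == "FEMALE" & pop$fertile),
                    fertile_males = sum(pop$sex == "MALE" & pop$fertile))
  for (locus in .LOCI) {
    cols <- .locusCols[[locus]]
    counts <- tabulate(c(pop[[cols[1]]], pop[[cols[2]]]), nbins = 4L)
    for (s in seq_along(.ALLELES))
      row[[paste(locus, names(.ALLELES)[s], sep = "_")]] <- counts[s]
  }
  row
}

#' Run one drive-release simulation
#'
#' Iterates [stepGeneration()] from the initial release population for up to
#' `generations(config)` generations, or until extinction — the first
#' generation whose cohort contains no fertile female or no fertile male.
#' The run is fully reproducible: the same config (including seed) yields an
#' identical trajectory. The caller's RNG state is left untouched.
#'
#' @param config A [simConfig()].
#' @return A `SimResult`; see [trajectory()], [isExtinct()],
#'   [extinctionGeneration()].
#' @export
#' @examples
#' cfg <- simConfig(driveDesign("SSC"), driveParams(1, 1, 1),
#'                  populationSize = 200, seed = 7)
#' res <- runSimulation(cfg)
#' isExtinct(res)
runSimulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  design <- config@design
  params <- config@params
  withr::with_seed(config@seed, {
    pop <- makeInitialPopulation(config)
    rows <- list(.trajectoryRow(pop, 0L))
    extinct <- FALSE
    extGen <- NA_integer_
    collapsed <- function(p) !any(p$sex == "FEMALE" & p$fertile) ||
      !any(p$sex == "MALE" & p$fertile)
    if (collapsed(pop)) {
      extinct <- TRUE
      extGen <- 0L
    } else {
      for (g in seq_len(config@generations)) {
        pop <- stepGeneration(pop, design, params, n = config@populationSize)
        rows[[length(rows) + 1L]] <- .trajectoryRow(pop, g)
        if (nrow(pop) == 0 || collapsed(pop)) {
          extinct <- TRUE
          extGen <- g
          break
        }
      }
    }
    new("SimResult", trajectory = do.call(rbind, rows), extinct = extinct,
        extinctionGeneration = extGen, config = config)
  })
}

#' @rdname simResult
#' @export
setMethod("trajectory", "SimResult", function(x) x@trajectory)
#' @rdname simResult
#' @export
setMethod("isExtinct", "SimResult", function(x) x@extinct)
#' @rdname simResult
#' @export
setMethod("extinctionGeneration", "SimResult", function(x) x@extinctionGeneration)

#' Simulation results
#'
#' A `SimResult` records the per-generation trajectory of one run
#' (population size, fertile females/males, and per-locus allele-class
#' counts), whether the population went extinct within the horizon, and the
#' extinction generation.
#'
#' @param x A `SimResult`.
#' @name simResult
NULL

setMethod("show", "SimResult", function(object) {
  tr <- object@trajectory
  cat("SimResult:", object@config@design@name, "\n")
  cat(sprintf("  %d generations recorded; %s\n", max(tr$generation),
              if (object@extinct)
                sprintf("EXTINCT at generation %d", object@extinctionGeneration)
              else "population persisted"))
  last <- tr[nrow(tr), ]
  cat(sprintf("  final: size=%d fertile females=%d fertile males=%d\n",
              last$size, last$fertile_females, last$fertile_males))
})

#' Independent replicate seeds from a master seed
#'
#' Deterministically expands a master seed into one sub-seed per replicate,
#' so that replicate r can be re-run reproducibly in isolation.
#'
#' @param masterSeed Integer master seed.
#' @param n Number of replicates.
#' @return Integer vector of length `n`.
#' @export
replicateSeeds <- function(masterSeed, n) {
  withr::with_seed(as.integer(masterSeed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Run replicate simulations
#'
#' Runs `replicates` independent copies of a scenario, each under its own
#' sub-seed derived from `seed` via [replicateSeeds()].
#'
#' @param config A [simConfig()]; its own seed slot is ignored.
#' @param replicates Number of replicate runs.
#' @param seed Master seed.
#' @return List of `SimResult` objects.
#' @export
runReplicates <- function(config, replicates, seed) {
  seeds <- replicateSeeds(seed, replicates)
  lapply(seeds, function(s) {
    config@seed <- as.integer(s)
    runSimulation(config)
  })
}

#' Summarise replicate outcomes
#'
#' @param results List of `SimResult` objects.
#' @param time How to average the duration to extinction:
#'   `"extinct_only"` (default) averages the extinction generation over
#'   extinct runs only (NA when none went extinct); `"censored"` counts each
#'   persisting run at its horizon G.
#' @return List with `extinction_fraction`, `mean_time_to_extinction`,
#'   `n_replicates`, `n_extinct`.
#' @export
summarizeReplicates <- function(results, time = c("extinct_only", "censored")) {
  time <- match.arg(time)
  stopifnot(length(results) >= 1)
  ext <- vapply(results, isExtinct, logical(1))
  gen <- vapply(results, extinctionGeneration, integer(1))
  mtte <- if (time == "extinct_only") {
    if (any(ext)) mean(gen[ext]) else NA_real_
  } else {
    horizon <- vapply(results, function(r) r@config@generations, integer(1))
    mean(ifelse(ext, gen, horizon))
  }
  list(extinction_fraction = mean(ext), mean_time_to_extinction = mtte,
       n_replicates = length(results), n_extinct = sum(ext))
}
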