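## Synthetic cross-progeny generator: emulates the homing-assay crosses
## (transgenic hemizygote x wild-type or eye-mutant mate), classifying each
## offspring by marker, sex phenotype and recessive eye phenotype, so the
## cross statistics and the germline model are testable end to end without
## external data.

#' Specify a synthetic cross
#'
#' Defines one cross of a transgenic hemizygote (carrying `(DRIVE, WILD)`
#' at the design's home locus) to a non-transgenic mate. The home-locus
#' gene doubles as the scored recessive visible marker (the construct homes
#' into it and disrupts it, as with a drive inserted in an eye-pigmentation
#' gene): `EYE_MUTANT` mates are homozygous for a disrupted, uncleavable
#' allele there, `WILD_TYPE` mates contribute intact alleles. Eye phenotype
#' is scored whenever the home locus is not `TRA`; mosaic phenotypes are
#' never generated (no somatic-expression model). Sex phenotype is derived
#' through the sex-determination rules when the design targets `TRA`, else
#' from the karyotype.
#'
#' @param parentSex `"female"` or `"male"`: which parent is transgenic.
#' @param mateType `"WILD_TYPE"` or `"EYE_MUTANT"`.
#' @param params A [driveParams()]. Note that with `maternalFactor > 0`,
#'   maternal Cas9 deposition in crosses of transgenic mothers adds
#'   embryonic cleavage on top of germline activity.
#' @param nProgeny Progeny per replicate.
#' @param design A [driveDesign()] (default `FEMALE_FERTILITY`, the
#'   single-gRNA homing construct of the pilot crosses).
#' @param replicates Number of replicate crosses (default 1).
#' @param seed Integer seed.
#' @return An object of class `"CrossSpec"`.
#' @export
crossSpec <- function(parentSex = c("female", "male"),
                      mateType = c("EYE_MUTANT", "WILD_TYPE"),
                      params, nProgeny,
                      design = driveDesign("FEMALE_FERTILITY"),
                      replicates = 1, seed = 1) {
  parentSex <- match.arg(parentSex)
  mateType <- match.arg(mateType)
  stopifnot(is(params, "DriveParams"), is(design, "DriveDesign"),
            nProgeny >= 1, replicates >= 1)
  structure(list(parentSex = parentSex, mateType = mateType, params = params,
                 nProgeny = as.integer(nProgeny), design = design,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "CrossSpec")
}

#' @export
print.CrossSpec <- function(x, ...) {
  cat(sprintf("CrossSpec: transgenic %s (%s) x %s, %d x %d progeny, seed %d\n",
              x$parentSex, designName(x$design), tolower(x$mateType),
              x$replicates, x$nProgeny, x$seed))
  invisible(x)
}

#' Simulate a cross experiment
#'
#' Draws the progeny of one [crossSpec()]: the transgenic parent's gametes
#' come from the full germline model ([sampleGametes()]), the mate's
#' gametes are Mendelian; karyotype follows the paternal sex chromosome;
#' maternal Cas9 deposition is applied when the transgenic parent is the
#' mother; maternal *tra* provision is drawn per offspring for
#' `TRA`-targeting designs. Each offspring is classified by marker status
#' (carries the construct), eye phenotype (`WHITE` iff both home-locus
#' alleles are non-functional, else `RED`) and sex phenotype.
#'
#' @param spec A [crossSpec()].
#' @return A [crossCounts()] object carrying the generating parameters in
#'   its `trueParams` slot.
#' @export
#' @examples
#' p <- driveParams(0.9, 0.8, 1, maternalFactor = 0)
#' cc <- simulateCross(crossSpec("male", "EYE_MUTANT", p, 2000, seed = 3))
#' crossSummary(cc)$pooled$transmission  # about (1 + 0.72) / 2
simulateCross <- function(spec) {
  stopifnot(inherits(spec, "CrossSpec"))
  design <- spec$design
  params <- spec$params
  home <- homeLocus(design)
  transKaryo <- if (spec$parentSex == "female") "XX" else "XY"
  transgenic <- individual(transKaryo,
                           setNames(list(c("DRIVE", "WILD")), home),
                           design = design)
  wantSex <- toupper(spec$parentSex)
  if (transgenic$sex != wantSex)
    stop("inconsistent spec: a hemizygous ", designName(design),
         " carrier with karyotype ", transKaryo, " develops as ",
         tolower(transgenic$sex), ", not as a ", spec$parentSex)
  if (!transgenic$fertile)
    stop("inconsistent spec: the transgenic parent is sterile")
  mateAllele <- if (spec$mateType == "EYE_MUTANT") .R2 else .WILD
  scoreEye <- home != "TRA"

  withr::with_seed(spec$seed, {
    tabs <- lapply(seq_len(spec$replicates), function(rep) {
      n <- spec$nProgeny
      tg <- sampleGametes(transgenic, design, params, n = n)

      alle <- list()  # per locus: 2-column (maternal, paternal) codes
      for (locus in .LOCI) {
        tgAllele <- .alleleCode(tg[[locus]])
        mate <- rep(if (locus == home) mateAllele else .WILD, n)
        alle[[locus]] <- if (spec$parentSex == "female")
          cbind(tgAllele, mate, deparse.level = 0)
        else cbind(mate, tgAllele, deparse.level = 0)
      }
      karyo <- if (spec$parentSex == "female")
        ifelse(runif(n) < 0.5, "XY", "XX")    # wild-type father
      else ifelse(tg$sexChromosome == "Y", "XY", "XX")

      if (spec$parentSex == "female") {
        mc <- min(1, params@maternalFactor * params@cleavage)
        if (mc > 0) {
          for (locus in targetedLoci(design)) {
            alle[[locus]][, 1] <- .depositAllele(alle[[locus]][, 1], TRUE,
                                                 mc, params@r2)
            alle[[locus]][, 2] <- .depositAllele(alle[[locus]][, 2], TRUE,
                                                 mc, params@r2)
          }
        }
      }

      provision <- if (spec$parentSex == "female" && targetsTra(design)) {
        nFunc <- sum(isFunctional(transgenic$alleles$TRA))
        runif(n) >= params@cleavage^nFunc
      } else rep(TRUE, n)

      marker <- ifelse(alle[[home]][, 1] == .DRIVE |
                         alle[[home]][, 2] == .DRIVE, "POSITIVE", "NEGATIVE")
      sexPhen <- if (targetsTra(design))
        determineSex(karyo, alle$TRA[, 1], alle$TRA[, 2], provision)
      else ifelse(karyo == "XY", "MALE", "FEMALE")
      eyePhen <- if (scoreEye)
        ifelse(!isFunctional(alle[[home]][, 1]) &
                 !isFunctional(alle[[home]][, 2]), "WHITE", "RED")
      else rep(NA_character_, n)

      key <- paste(marker, sexPhen, eyePhen, sep = "\r")
      counts <- table(key)
      parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
      data.frame(replicate = rep, marker = parts[, 1],
                 sex_phenotype = parts[, 2],
                 eye_phenotype = ifelse(parts[, 3] == "NA", NA, parts[, 3]),
                 count = as.integer(counts), row.names = NULL)
    })
    tab <- do.call(rbind, tabs)
    tab <- tab[order(tab$replicate, tab$marker, tab$sex_phenotype,
                     tab$eye_phenotype, method = "radix"), ]
    rownames(tab) <- NULL
    crossCounts(tab, parentSex = spec$parentSex, mateType = spec$mateType,
                trueParams = params, design = design)
  })
}

#' Generate a deterministic fixture suite of synthetic crosses
#'
#' Writes a fixed set of cross count tables spanning the experimental
#' regimes — high and low germline activity, transgenic mothers and
#' fathers, eye-mutant and wild-type mates, a maternal-deposition cross and
#' sex-ratio crosses of `TRA`-targeting designs — plus a JSON manifest of
#' the generating parameters per file. Byte-identical across runs for a
#' fixed seed. The manifest flags (`inference_valid`) the crosses that
#' satisfy the assumptions of [inferCleavageHdr()] (eye-mutant mate, r2 = 1,
#' no embryonic deposition confounding the mutant fraction).
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param nProgeny Progeny per cross (default 2000).
#' @return Invisibly, the manifest as a list.
#' @export
generateFixtureSuite <- function(seed, dir, nProgeny = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## k = 0 where the mutant fraction must reflect germline repair alone
  specs <- list(
    mother_high_activity = list(parentSex = "female", mateType = "EYE_MUTANT",
      params = driveParams(0.93, 0.77, 1, maternalFactor = 0)),
    father_balanced = list(parentSex = "male", mateType = "EYE_MUTANT",
      params = driveParams(0.72, 0.78, 1)),
    mother_near_perfect = list(parentSex = "female", mateType = "EYE_MUTANT",
      params = driveParams(0.95, 0.95, 1, maternalFactor = 0)),
    father_low_activity = list(parentSex = "male", mateType = "EYE_MUTANT",
      params = driveParams(0.3, 0.5, 1)),
    mother_deposition = list(parentSex = "female", mateType = "WILD_TYPE",
      params = driveParams(0.9, 0.8, 1, maternalFactor = 1)),
    ssc_mother_sex_ratio = list(parentSex = "female", mateType = "WILD_TYPE",
      params = driveParams(1, 1, 1), design = driveDesign("SSC")),
    tra_homing_father = list(parentSex = "male", mateType = "WILD_TYPE",
      params = driveParams(0.9, 0.9, 0.99), design = driveDesign("TRA_HOMING")))

  seeds <- replicateSeeds(seed, length(specs))
  manifest <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    s <- specs[[i]]
    design <- s$design %||% driveDesign("FEMALE_FERTILITY")
    cs <- crossSpec(s$parentSex, s$mateType, s$params, nProgeny,
                    design = design, seed = seeds[i])
    cc <- simulateCross(cs)
    file <- file.path(dir, paste0(nm, ".tsv"))
    writeCrossCounts(cc, file)
    p <- s$params
    manifest[[nm]] <- list(
      file = basename(file), parent_sex = s$parentSex, mate_type = s$mateType,
      design = designName(design), n_progeny = nProgeny, seed = seeds[i],
      cleavage = p@cleavage, hdr = p@hdr, r2 = p@r2,
      maternal_factor = p@maternalFactor,
      inference_valid = s$mateType == "EYE_MUTANT" && p@r2 == 1 &&
        (s$parentSex == "male" || p@maternalFactor == 0))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
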