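## Core medfly drive genetics: architectures, allele function, sex
## determination (MoY dominance, zygotic tra + maternal tra provision) and
## recessive female sterility.

#' Drive architectures
#'
#' Construct one of the four modelled suppression-drive architectures:
#'
#' * `FEMALE_FERTILITY` — homes into a recessive female-fertility gene
#'   (`FERTILITY_1`), no trans-acting gRNA.
#' * `TRA_HOMING` — homes directly into the medfly *transformer* gene (`TRA`).
#' * `SSC` — sterilising sex conversion: homes into `FERTILITY_1` while a
#'   second gRNA cuts `TRA` in trans.
#' * `DUAL_FERTILITY` — homes into `FERTILITY_1` while cutting a second,
#'   independent female-fertility gene (`FERTILITY_2`) in trans.
#'
#' @param name Design name, one of `designNames()` (case-insensitive).
#' @param x A `DriveDesign`.
#' @return `driveDesign()` returns a `DriveDesign` object. `homeLocus()` and
#'   `transTarget()` return a locus id (`transTarget()` is `NA` when the
#'   design has no trans-acting gRNA); `targetedLoci()` the loci the
#'   construct cuts; `fertilityLoci()` the female-fertility loci whose joint
#'   loss sterilises a female; `targetsTra()` whether any gRNA cuts `TRA`.
#' @export
#' @examples
#' d <- driveDesign("SSC")
#' homeLocus(d)      # "FERTILITY_1"
#' transTarget(d)    # "TRA"
#' targetsTra(d)     # TRUE
driveDesign <- function(name) {
  name <- toupper(gsub("[- ]", "_", as.character(name)[1]))
  if (!name %in% .DESIGNS)
    stop("unknown design '", name, "'; expected one of: ",
         paste(.DESIGNS, collapse = ", "))
  spec <- switch(name,
    FEMALE_FERTILITY = c("FERTILITY_1", NA_character_),
    TRA_HOMING       = c("TRA", NA_character_),
    SSC              = c("FERTILITY_1", "TRA"),
    DUAL_FERTILITY   = c("FERTILITY_1", "FERTILITY_2"))
  new("DriveDesign", name = name, homeLocus = spec[[1]], transTarget = spec[[2]])
}

#' @rdname driveDesign
#' @export
setMethod("designName", "DriveDesign", function(x) x@name)
#' @rdname driveDesign
#' @export
setMethod("homeLocus", "DriveDesign", function(x) x@homeLocus)
#' @rdname driveDesign
#' @export
setMethod("transTarget", "DriveDesign", function(x) x@transTarget)
#' @rdname driveDesign
#' @export
setMethod("targetedLoci", "DriveDesign", function(x) {
  loci <- x@homeLocus
  if (!is.na(x@transTarget)) loci <- c(loci, x@transTarget)
  loci
})
#' @rdname driveDesign
#' @export
setMethod("fertilityLoci", "DriveDesign", function(x) {
  if (identical(x@name, "DUAL_FERTILITY")) c("FERTILITY_1", "FERTILITY_2")
  else "FERTILITY_1"
})
#' @rdname driveDesign
#' @export
setMethod("targetsTra", "DriveDesign", function(x) "TRA" %in% targetedLoci(x))

setMethod("show", "DriveDesign", function(object) {
  cat("DriveDesign:", object@name, "\n")
  cat("  homes into:", object@homeLocus, "\n")
  cat("  trans target:",
      if (is.na(object@transTarget)) "none" else object@transTarget, "\n")
})

#' Germline drive activity parameters
#'
#' The swept quantities of the drive model: `cleavage` is the per-allele
#' probability c that Cas9 cuts a wild-type target site in the germline;
#' `hdr` the probability h that a cut is repaired by homology-directed
#' repair (homing of the construct, or copying of the homologous R allele);
#' `r2` the probability that an NHEJ repair produces a non-functional R2
#' allele rather than a functional R1; `maternalFactor` the proportionality
#' constant k relating maternal (embryonic) Cas9 activity to germline
#' activity — the embryonic cleavage probability is `min(1, k * cleavage)`.
#'
#' @param cleavage,hdr,r2 Probabilities in `[0, 1]`.
#' @param maternalFactor Nonnegative scalar; default 1 (maternal activity
#'   equals germline activity).
#' @param x A `DriveParams`.
#' @return A `DriveParams` object; accessors return the stored scalars.
#' @export
#' @examples
#' p <- driveParams(cleavage = 0.95, hdr = 0.95, r2 = 0.99)
#' cleavageRate(p)
driveParams <- function(cleavage, hdr, r2, maternalFactor = 1) {
  new("DriveParams", cleavage = as.numeric(cleavage), hdr = as.numeric(hdr),
      r2 = as.numeric(r2), maternalFactor = as.numeric(maternalFactor))
}

#' @rdname driveParams
#' @export
setMethod("cleavageRate", "DriveParams", function(x) x@cleavage)
#' @rdname driveParams
#' @export
setMethod("hdrRate", "DriveParams", function(x) x@hdr)
#' @rdname driveParams
#' @export
setMethod("r2Fraction", "DriveParams", function(x) x@r2)
#' @rdname driveParams
#' @export
setMethod("maternalFactor", "DriveParams", function(x) x@maternalFactor)

setMethod("show", "DriveParams", function(object) {
  cat(sprintf(
    "DriveParams: cleavage=%.4g hdr=%.4g r2=%.4g maternalFactor=%.4g\n",
    object@cleavage, object@hdr, object@r2, object@maternalFactor))
})

## internal: map character allele states to integer codes (integers pass
## through) with validation
.alleleCode <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L) || any(x > 4L))
      stop("allele codes must be in 1:4")
    return(x)
  }
  code <- .ALLELES[as.character(x)]
  if (any(is.na(code)))
    stop("unknown allele state; expected one of: ",
         paste(names(.ALLELES), collapse = ", "))
  unname(code)
}

.alleleName <- function(code) names(.ALLELES)[code]

#' Does an allele retain target-gene function?
#'
#' `WILD` and `R1` retain gene function; the drive insertion (`DRIVE`)
#' disrupts the gene it sits in, and `R2` indels abolish function.
#' Vectorised.
#'
#' @param allele Character vector of allele states (see [alleleStates()]),
#'   or the package's integer codes.
#' @return Logical vector.
#' @export
#' @examples
#' isFunctional(c("WILD", "R1", "R2", "DRIVE"))
isFunctional <- function(allele) {
  code <- .alleleCode(allele)
  code == .ALLELES[["WILD"]] | code == .ALLELES[["R1"]]
}

#' Medfly sex determination
#'
#' XY individuals are male regardless of *tra* genotype (the Y-linked
#' maleness factor MoY is dominant). An XX individual develops female only
#' if it inherited intact maternal *tra* provision **and** carries at least
#' one functional zygotic *tra* allele; otherwise it defaults to the male
#' pathway (genetic sex conversion). Conversions are treated as complete —
#' there is no intersex class in the model. Vectorised; all arguments are
#' recycled to a common length.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param traMaternal,traPaternal Allele states at the `TRA` locus. Designs
#'   that do not model `TRA` should pass a fixed functional pair
#'   (the default, `"WILD"`).
#' @param maternalTraIntact Logical: was maternal *tra* provision intact?
#' @return Character vector, `"MALE"` or `"FEMALE"`.
#' @export
#' @examples
#' determineSex("XX", "WILD", "DRIVE", TRUE)    # FEMALE
#' determineSex("XX", "WILD", "WILD", FALSE)    # MALE: no maternal provision
#' determineSex("XX", "DRIVE", "R2", TRUE)      # MALE: no functional tra
determineSex <- function(karyotype, traMaternal = "WILD",
                         traPaternal = "WILD", maternalTraIntact = TRUE) {
  if (!all(karyotype %in% c("XX", "XY")))
    stop("karyotype must be 'XX' or 'XY'")
  n <- max(length(karyotype), length(traMaternal), length(traPaternal),
           length(maternalTraIntact))
  karyotype <- rep_len(karyotype, n)
  fm <- rep_len(isFunctional(traMaternal), n)
  fp <- rep_len(isFunctional(traPaternal), n)
  intact <- rep_len(as.logical(maternalTraIntact), n)
  female <- karyotype == "XX" & intact & (fm | fp)
  ifelse(female, "FEMALE", "MALE")
}

#' Female fertility under a drive design
#'
#' Males are always fertile in the model (XX males are viable and fertile;
#' intersex phenotypes are out of model scope). A female is sterile iff,
#' at any female-fertility locus of the design (`FERTILITY_1`, plus
#' `FERTILITY_2` for `DUAL_FERTILITY`), both of her alleles are
#' non-functional — female sterility is recessive. Vectorised over
#' individuals.
#'
#' @param sex `"MALE"` or `"FEMALE"` (as computed by [determineSex()]).
#' @param genotype A named list mapping locus ids to a two-column matrix (or
#'   length-2 vector for a single individual) of allele states
#'   (maternal, paternal).
#' @param design A [driveDesign()].
#' @return Logical vector: fertile?
#' @export
#' @examples
#' d <- driveDesign("FEMALE_FERTILITY")
#' determineFertility("FEMALE", list(FERTILITY_1 = c("DRIVE", "R2")), d)  # FALSE
#' determineFertility("FEMALE", list(FERTILITY_1 = c("DRIVE", "R1")), d)  # TRUE
determineFertility <- function(sex, genotype, design) {
  stopifnot(is(design, "DriveDesign"))
  if (!all(sex %in% c("MALE", "FEMALE")))
    stop("sex must be 'MALE' or 'FEMALE'")
  n <- length(sex)
  sterile <- rep(FALSE, n)
  for (locus in fertilityLoci(design)) {
    pair <- genotype[[locus]]
    if (is.null(pair)) next  # locus untouched by the design: functional
    if (is.null(dim(pair))) pair <- matrix(pair, ncol = 2)
    bothDead <- !isFunctional(pair[, 1]) & !isFunctional(pair[, 2])
    sterile <- sterile | rep_len(bothDead, n)
  }
  sex == "MALE" | !sterile
}
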