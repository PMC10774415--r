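## Germline Cas9 activity: cleavage of wild-type target sites, repair by HDR
## (homing of the construct or copying of the homologous R allele) or by NHEJ
## (R2 with probability r2, else R1), maternal deposition in the embryo, and
## maternal tra provision. All stochastic paths have an exact enumeration
## counterpart (gameteDistribution) used as an oracle in the test suite.

.WILD  <- 1L
.DRIVE <- 2L
.R1    <- 3L
.R2    <- 4L

## vectorised NHEJ repair product
.nhej <- function(n, r2) ifelse(runif(n) < r2, .R2, .R1)

## Vectorised germline resolution of one locus for many independent meioses.
## a1, a2: integer allele codes (one element per meiosis). Returns a 2-column
## integer matrix. Each WILD allele is cleaved independently with probability
## c; cleaved alleles are resolved in uniformly random order. A cleaved
## allele repairs by HDR with probability h, copying the homolog's *current*
## state (a simultaneously cleaved, still-unresolved homolog cannot serve as
## template, so the first of two cuts always repairs by NHEJ); the construct
## is only copied where canHome. Non-WILD alleles are never altered.
.resolveGermlineVec <- function(a1, a2, canHome, c, h, r2) {
  n <- length(a1)
  cl1 <- a1 == .WILD & runif(n) < c
  cl2 <- a2 == .WILD & runif(n) < c
  out1 <- a1
  out2 <- a2

  both <- which(cl1 & cl2)
  if (length(both)) {
    nb <- length(both)
    firstIs1 <- runif(nb) < 0.5
    repFirst <- .nhej(nb, r2)                     # no template available
    repSecond <- ifelse(runif(nb) < h, repFirst, .nhej(nb, r2))
    out1[both] <- ifelse(firstIs1, repFirst, repSecond)
    out2[both] <- ifelse(firstIs1, repSecond, repFirst)
  }
  solo1 <- which(cl1 & !cl2)
  if (length(solo1))
    out1[solo1] <- .repairAgainstTemplate(a2[solo1], canHome, h, r2)
  solo2 <- which(cl2 & !cl1)
  if (length(solo2))
    out2[solo2] <- .repairAgainstTemplate(a1[solo2], canHome, h, r2)

  cbind(out1, out2, deparse.level = 0)
}

## repair of a single cut with an intact homolog as potential HDR template
.repairAgainstTemplate <- function(homolog, canHome, h, r2) {
  n <- length(homolog)
  copyable <- homolog != .DRIVE | canHome
  hdr <- runif(n) < h & copyable
  ifelse(hdr, homolog, .nhej(n, r2))
}

#' Resolve germline Cas9 activity at one locus
#'
#' Applies one meiosis worth of germline cleavage and repair to an allele
#' pair: each `WILD` allele is cleaved independently with probability
#' `cleavageRate(params)` and the cuts are resolved in uniformly random
#' order. A cut repairs by HDR with probability `hdrRate(params)`, copying
#' the homolog's current state — the drive construct (homing) only when
#' `canHome`, an R allele likewise, and `WILD` restoring `WILD`; a homolog
#' that is itself cut and not yet repaired cannot act as template, in which
#' case (and on NHEJ generally) the cut becomes `R2` with probability
#' `r2Fraction(params)`, else `R1`. Non-`WILD` alleles are never altered.
#'
#' @param pair Length-2 character vector of allele states
#'   (maternal, paternal).
#' @param canHome `TRUE` iff this locus is the design's home locus, so the
#'   construct on the homolog can be copied in.
#' @param params A [driveParams()].
#' @return Length-2 character vector: the pair after germline activity.
#' @seealso [gameteDistribution()] for the exact distribution over outcomes.
#' @export
#' @examples
#' p <- driveParams(1, 1, 0.5)
#' resolveGermline(c("DRIVE", "WILD"), canHome = TRUE, p)  # both DRIVE
resolveGermline <- function(pair, canHome, params) {
  stopifnot(length(pair) == 2, is(params, "DriveParams"))
  code <- .alleleCode(pair)
  out <- .resolveGermlineVec(code[1], code[2], isTRUE(canHome),
                             params@cleavage, params@hdr, params@r2)
  .alleleName(as.vector(out))
}

## ---------------------------------------------------------------------------
## Individuals (single-organism surface; the population simulator uses the
## vectorised internals directly)

#' Construct an individual fly
#'
#' Builds an individual from its karyotype and diploid genotype, deriving
#' sex and fertility from the model's rules ([determineSex()],
#' [determineFertility()]); neither is free state. Loci not supplied are
#' wild-type homozygous.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param alleles Named list mapping locus ids (see [locusIds()]) to
#'   length-2 character vectors (maternal allele, paternal allele).
#' @param maternalTraIntact Did the individual's mother provide intact
#'   maternal *tra* product?
#' @param design The active [driveDesign()]; the drive construct may only
#'   occur at its home locus.
#' @return An object of class `"Individual"`: a list with elements
#'   `karyotype`, `alleles` (all three loci), `maternalTraIntact`, `sex`,
#'   `fertile`.
#' @export
#' @examples
#' d <- driveDesign("SSC")
#' m <- individual("XY", list(FERTILITY_1 = c("DRIVE", "WILD")), design = d)
#' m$sex      # "MALE"
#' m$fertile  # TRUE
individual <- function(karyotype, alleles = list(), maternalTraIntact = TRUE,
                       design) {
  stopifnot(karyotype %in% c("XX", "XY"), is(design, "DriveDesign"))
  full <- setNames(rep(list(c("WILD", "WILD")), length(.LOCI)), .LOCI)
  for (locus in names(alleles)) {
    if (!locus %in% .LOCI) stop("unknown locus '", locus, "'")
    pair <- as.character(alleles[[locus]])
    if (length(pair) != 2) stop("exactly two alleles required at ", locus)
    .alleleCode(pair)  # validates states
    if (any(pair == "DRIVE") && locus != homeLocus(design))
      stop("the drive construct may only occur at the design's home locus (",
           homeLocus(design), ")")
    full[[locus]] <- pair
  }
  sex <- determineSex(karyotype, full$TRA[1], full$TRA[2], maternalTraIntact)
  fertile <- determineFertility(sex, full, design)
  structure(list(karyotype = karyotype, alleles = full,
                 maternalTraIntact = maternalTraIntact,
                 sex = sex, fertile = fertile),
            class = "Individual")
}

#' @export
print.Individual <- function(x, ...) {
  cat("Individual:", x$karyotype, x$sex,
      if (x$fertile) "fertile" else "sterile", "\n")
  for (locus in names(x$alleles))
    cat(sprintf("  %-12s %s / %s\n", locus,
                x$alleles[[locus]][1], x$alleles[[locus]][2]))
  cat("  maternal tra provision:",
      if (x$maternalTraIntact) "intact" else "lost", "\n")
  invisible(x)
}

.carriesDrive <- function(ind) any(unlist(ind$alleles) == "DRIVE")

#' Sample gametes from a parent
#'
#' Draws `n` independent meioses. In a construct-carrying parent (Cas9 is
#' encoded on the construct), germline resolution ([resolveGermline()]) is
#' applied at every targeted locus (the home locus with homing enabled; any
#' trans target without, so cuts there resolve only by R-allele copying or
#' NHEJ); construct-free parents transmit all loci Mendelian. One allele per
#' locus is then sampled uniformly. Gametes of a male parent carry `X` or `Y` with probability 1/2
#' each; female gametes always carry `X`. Each meiosis is independent — the
#' parent is never modified.
#'
#' `formGamete()` is the single-gamete convenience wrapper.
#'
#' @param parent An [individual()]; must be fertile.
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @param n Number of gametes to draw.
#' @return `sampleGametes()`: a data.frame with one row per gamete, one
#'   character column per locus plus `sexChromosome`. `formGamete()`: a list
#'   with elements `alleles` (named character vector) and `sexChromosome`.
#' @export
#' @examples
#' d <- driveDesign("FEMALE_FERTILITY")
#' p <- driveParams(0.95, 0.95, 0.99)
#' dad <- individual("XY", list(FERTILITY_1 = c("DRIVE", "WILD")), design = d)
#' g <- sampleGametes(dad, d, p, n = 1000)
#' mean(g$FERTILITY_1 == "DRIVE")  # about (1 + c*h)/2 = 0.95125
sampleGametes <- function(parent, design, params, n = 1) {
  stopifnot(inherits(parent, "Individual"), is(design, "DriveDesign"),
            is(params, "DriveParams"), n >= 1)
  if (!parent$fertile)
    stop("cannot draw gametes from a sterile parent")
  ## Cas9 is encoded on the construct: non-carriers transmit Mendelian
  targeted <- if (.carriesDrive(parent)) targetedLoci(design) else character(0)
  out <- list()
  for (locus in .LOCI) {
    pair <- .alleleCode(parent$alleles[[locus]])
    if (locus %in% targeted) {
      resolved <- .resolveGermlineVec(rep(pair[1], n), rep(pair[2], n),
                                      canHome = locus == homeLocus(design),
                                      params@cleavage, params@hdr, params@r2)
    } else {
      resolved <- cbind(rep(pair[1], n), rep(pair[2], n))
    }
    pickFirst <- runif(n) < 0.5
    out[[locus]] <- .alleleName(ifelse(pickFirst, resolved[, 1], resolved[, 2]))
  }
  out$sexChromosome <- if (parent$karyotype == "XY")
    ifelse(runif(n) < 0.5, "Y", "X") else rep("X", n)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @rdname sampleGametes
#' @export
formGamete <- function(parent, design, params) {
  g <- sampleGametes(parent, design, params, n = 1)
  list(alleles = setNames(as.character(g[1, .LOCI]), .LOCI),
       sexChromosome = g$sexChromosome[1])
}

## ---------------------------------------------------------------------------
## Exact enumeration oracle

## Exact post-germline distribution over ordered pairs at one locus.
## Enumerates cleavage of each WILD allele, both resolution orders at weight
## 1/2, and every repair branch. Returns a data.frame (a1, a2, prob).
.pairDistribution <- function(pair, canHome, c, h, r2) {
  acc <- new.env(parent = emptyenv())
  add <- function(a1, a2, p) {
    if (p <= 0) return()
    key <- paste0(a1, ":", a2)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  nhejBranch <- function(p) list(list(state = .R2, p = p * r2),
                                 list(state = .R1, p = p * (1 - r2)))
  ## repair of one cut given a fixed template state (template not cut)
  repairBranch <- function(template, p) {
    copyable <- template != .DRIVE || canHome
    ph <- if (copyable) h else 0
    c(if (ph > 0) list(list(state = template, p = p * ph)),
      nhejBranch(p * (1 - ph)))
  }
  p1 <- if (pair[1] == .WILD) c else 0   # P(allele 1 cleaved)
  p2 <- if (pair[2] == .WILD) c else 0
  for (cl1 in c(FALSE, TRUE)) for (cl2 in c(FALSE, TRUE)) {
    pc <- (if (cl1) p1 else 1 - p1) * (if (cl2) p2 else 1 - p2)
    if (pc == 0) next
    if (!cl1 && !cl2) {
      add(pair[1], pair[2], pc)
    } else if (cl1 && !cl2) {
      for (b in repairBranch(pair[2], pc)) add(b$state, pair[2], b$p)
    } else if (!cl1 && cl2) {
      for (b in repairBranch(pair[1], pc)) add(pair[1], b$state, b$p)
    } else {
      ## both cut: random order; first resolves by NHEJ (no template), the
      ## second sees the first's product as template with probability h
      for (firstIs1 in c(TRUE, FALSE)) {
        po <- pc / 2
        for (bf in nhejBranch(po)) {
          branches <- c(list(list(state = bf$state, p = bf$p * h)),
                        nhejBranch(bf$p * (1 - h)))
          for (bs in branches) {
            if (firstIs1) add(bf$state, bs$state, bs$p)
            else add(bs$state, bf$state, bs$p)
          }
        }
      }
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  data.frame(a1 = as.integer(parts[, 1]), a2 = as.integer(parts[, 2]),
             prob = vapply(keys, function(k) acc[[k]], numeric(1)),
             row.names = NULL)
}

#' Exact gamete allele distribution
#'
#' Enumerates every germline cleavage/repair outcome at each modelled locus
#' — including both resolution orders of a double cut at weight 1/2 — and
#' marginalises the uniform pick of one allele per gamete. This is the
#' closed-form counterpart of [sampleGametes()] and is used as its oracle;
#' for a hemizygous drive parent it reduces to the classic transmission rate
#' (1 + c h) / 2.
#'
#' @param genotype Named list mapping locus ids to length-2 character allele
#'   pairs; missing loci are taken as `c("WILD", "WILD")`. An
#'   [individual()]'s `alleles` element can be passed directly.
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @param carriesConstruct Is the germline Cas9-active? Defaults to whether
#'   the genotype carries `DRIVE` at the home locus; pass `TRUE` to
#'   enumerate a single targeted pair in isolation, or `FALSE` for a plain
#'   Mendelian germline.
#' @return Named list with one element per locus: a named probability vector
#'   over `alleleStates()`, summing to 1.
#' @export
#' @examples
#' d <- driveDesign("FEMALE_FERTILITY")
#' p <- driveParams(0.95, 0.95, 0.99)
#' gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD")), d, p)$FERTILITY_1
gameteDistribution <- function(genotype, design, params,
                               carriesConstruct = NULL) {
  stopifnot(is(design, "DriveDesign"), is(params, "DriveParams"))
  if (inherits(genotype, "Individual")) genotype <- genotype$alleles
  if (is.null(carriesConstruct)) {
    home <- genotype[[homeLocus(design)]]
    carriesConstruct <- !is.null(home) && any(home == "DRIVE")
  }
  active <- if (carriesConstruct) targetedLoci(design) else character(0)
  out <- list()
  for (locus in .LOCI) {
    pair <- genotype[[locus]]
    if (is.null(pair)) pair <- c("WILD", "WILD")
    code <- .alleleCode(pair)
    dist <- setNames(numeric(4), names(.ALLELES))
    if (locus %in% active) {
      pd <- .pairDistribution(code, locus == homeLocus(design),
                              params@cleavage, params@hdr, params@r2)
      for (i in seq_len(nrow(pd))) {
        dist[pd$a1[i]] <- dist[pd$a1[i]] + pd$prob[i] / 2
        dist[pd$a2[i]] <- dist[pd$a2[i]] + pd$prob[i] / 2
      }
    } else {
      dist[code[1]] <- dist[code[1]] + 0.5
      dist[code[2]] <- dist[code[2]] + 0.5
    }
    out[[locus]] <- dist
  }
  out
}

## ---------------------------------------------------------------------------
## Embryonic (maternal) effects

## vectorised embryonic cleavage of one allele column; NHEJ only — maternal
## deposition cannot home (no construct template in a WILD/WILD embryo cell)
.depositAllele <- function(a, apply, cleaveProb, r2) {
  hit <- apply & a == .WILD & runif(length(a)) < cleaveProb
  ifelse(hit, .nhej(length(a), r2), a)
}

#' Maternal Cas9 deposition in the embryo
#'
#' If the mother carries at least one copy of the construct, Cas9/gRNA
#' deposited in the egg cleaves each `WILD` allele of the zygote at every
#' targeted locus (home and trans) independently with probability
#' `min(1, maternalFactor * cleavage)`. Repair in the embryo is NHEJ only —
#' `R2` with probability `r2`, else `R1`; deposition can never create a
#' `DRIVE` allele. Zygotes of construct-free mothers are unchanged.
#'
#' @param zygote Named list mapping locus ids to length-2 character allele
#'   pairs (missing loci taken as wild type).
#' @param motherCarriesConstruct Logical.
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @return The zygote's allele list (all three loci) after deposition.
#' @export
#' @examples
#' d <- driveDesign("FEMALE_FERTILITY")
#' p <- driveParams(1, 1, r2 = 0, maternalFactor = 1)
#' applyMaternalDeposition(list(FERTILITY_1 = c("WILD", "WILD")),
#'                         TRUE, d, p)$FERTILITY_1   # both R1
applyMaternalDeposition <- function(zygote, motherCarriesConstruct, design,
                                    params) {
  stopifnot(is(design, "DriveDesign"), is(params, "DriveParams"))
  full <- setNames(rep(list(c("WILD", "WILD")), length(.LOCI)), .LOCI)
  for (locus in names(zygote)) full[[locus]] <- zygote[[locus]]
  if (!isTRUE(motherCarriesConstruct)) return(full)
  mc <- min(1, params@maternalFactor * params@cleavage)
  for (locus in targetedLoci(design)) {
    code <- .alleleCode(full[[locus]])
    code <- c(.depositAllele(code[1], TRUE, mc, params@r2),
              .depositAllele(code[2], TRUE, mc, params@r2))
    full[[locus]] <- .alleleName(code)
  }
  full
}

#' Maternal tra provision
#'
#' Medfly female development requires maternally deposited *tra* product.
#' In a mother carrying a `TRA`-targeting construct (`TRA_HOMING` or `SSC`),
#' Cas9 activity in the nurse cells and oocyte disrupts each of her
#' functional *tra* alleles independently with probability
#' `cleavageRate(params)`; the provision for one offspring is lost iff no
#' functional allele escapes. The draw is made fresh for every offspring
#' (ovarian mosaicism). Mothers without a `TRA`-targeting construct always
#' provide intact *tra*.
#'
#' @param mother A fertile female [individual()].
#' @param design A [driveDesign()].
#' @param params A [driveParams()].
#' @return Logical: is the maternal provision intact for this offspring?
#' @export
maternalTraProvision <- function(mother, design, params) {
  stopifnot(inherits(mother, "Individual"), is(design, "DriveDesign"),
            is(params, "DriveParams"))
  if (mother$sex != "FEMALE")
    stop("maternal tra provision is defined for mothers only")
  if (!targetsTra(design) || !.carriesDrive(mother)) return(TRUE)
  functional <- isFunctional(mother$alleles$TRA)
  nf <- sum(functional)
  if (nf == 0) return(FALSE)  # unreachable for a FEMALE, kept total
  any(runif(nf) >= params@cleavage)
}
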