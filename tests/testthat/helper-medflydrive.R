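# shared fixtures and small oracles

ffDesign <- driveDesign("FEMALE_FERTILITY")
sscDesign <- driveDesign("SSC")
traDesign <- driveDesign("TRA_HOMING")
dualDesign <- driveDesign("DUAL_FERTILITY")

binomSE <- function(p, n) sqrt(p * (1 - p) / n)

# closed-form hemizygote cross fractions (independent algebra, not the
# package's enumeration): transmission T = (1+ch)/2, mutant fraction among
# non-carriers m = c(1-h)/(1-ch)
forwardCrossModel <- function(c, h) {
  list(transmission = (1 + c * h) / 2,
       mutantFraction = c * (1 - h) / (1 - c * h))
}

# hemizygous drive father, all other loci wild type
hemizygousFather <- function(design = ffDesign) {
  individual("XY", setNames(list(c("DRIVE", "WILD")), homeLocus(design)),
             design = design)
}

randomParams <- function(k = 1) {
  driveParams(runif(1), runif(1), runif(1), maternalFactor = k)
}

# tiny wild-type + drive-male population for step tests
smallConfig <- function(design, params, N = 200, G = 20, seed = 1) {
  simConfig(design, params, populationSize = N, generations = G,
            nWtFemales = N / 2, nWtMales = N / 4, nDriveMales = N / 4,
            seed = seed)
}
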