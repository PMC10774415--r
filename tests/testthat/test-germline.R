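test_that("germline resolution obeys the forced-outcome cases", {
  withr::with_seed(1, {
    expect_identical(resolveGermline(c("DRIVE", "WILD"), TRUE,
                                     driveParams(1, 1, 0.5)),
                     c("DRIVE", "DRIVE"))              # perfect homing
    expect_identical(resolveGermline(c("DRIVE", "WILD"), TRUE,
                                     driveParams(0, 1, 0.5)),
                     c("DRIVE", "WILD"))               # no activity
    expect_identical(resolveGermline(c("DRIVE", "WILD"), TRUE,
                                     driveParams(1, 0, 1)),
                     c("DRIVE", "R2"))                 # forced NHEJ, forced R2
    expect_identical(resolveGermline(c("R1", "WILD"), TRUE,
                                     driveParams(1, 1, 0.5)),
                     c("R1", "R1"))                    # R-allele homing
    # non-WILD alleles are never altered
    for (pair in list(c("R1", "R2"), c("DRIVE", "R2"), c("R2", "R2")))
      expect_identical(resolveGermline(pair, TRUE, driveParams(1, 0.5, 0.5)),
                       pair)
  })
})

test_that("exact gamete distribution matches closed forms", {
  p <- driveParams(0.95, 0.95, 0.99)
  d <- gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD")), ffDesign,
                          p)$FERTILITY_1
  # hemizygote: P(DRIVE)=(1+ch)/2, P(WILD)=(1-c)/2, P(R_i)=c(1-h) w_i / 2
  expect_equal(unname(d["DRIVE"]), (1 + 0.95 * 0.95) / 2, tolerance = 1e-12)
  expect_equal(unname(d["WILD"]), 0.025, tolerance = 1e-12)
  expect_equal(unname(d["R2"]), 0.95 * 0.05 * 0.99 / 2, tolerance = 1e-12)
  expect_equal(unname(d["R1"]), 0.95 * 0.05 * 0.01 / 2, tolerance = 1e-12)

  # Mendelian with no activity
  d0 <- gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD")), ffDesign,
                           driveParams(0, 1, 0.5))$FERTILITY_1
  expect_equal(unname(d0[c("DRIVE", "WILD")]), c(0.5, 0.5), tolerance = 1e-12)

  # trans-target WILD/WILD pair with h=0: P(R2 gamete) = c * r2
  ph0 <- driveParams(0.7, 0, 0.6)
  dt <- gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD"),
                                TRA = c("WILD", "WILD")), sscDesign, ph0)$TRA
  expect_equal(unname(dt["R2"]), 0.7 * 0.6, tolerance = 1e-12)
  expect_equal(unname(dt["DRIVE"]), 0)   # no homing at a trans target
})

test_that("gamete distributions are proper and properly conditioned", {
  withr::with_seed(7, {
    states <- alleleStates()
    for (i in 1:25) {
      p <- randomParams()
      pair <- sample(c("WILD", "R1", "R2"), 2, replace = TRUE)
      g <- list(FERTILITY_1 = c("DRIVE", "WILD"), TRA = pair)
      dists <- gameteDistribution(g, sscDesign, p)
      for (d in dists) expect_equal(sum(d), 1, tolerance = 1e-12)
    }
  })
  # a construct-free germline has no Cas9: transmission is Mendelian
  p <- driveParams(1, 1, 1)
  dwt <- gameteDistribution(list(FERTILITY_1 = c("WILD", "WILD")), ffDesign,
                            p)$FERTILITY_1
  expect_equal(unname(dwt["WILD"]), 1)
})

test_that("hemizygote transmission is (1+ch)/2 and monotone in c and h", {
  grid <- seq(0, 1, by = 0.25)
  tr <- outer(grid, grid, Vectorize(function(c, h) {
    p <- driveParams(c, h, 0.5)
    unname(gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD")),
                              ffDesign, p)$FERTILITY_1["DRIVE"])
  }))
  expect_equal(tr, outer(grid, grid, function(c, h) (1 + c * h) / 2),
               tolerance = 1e-12)
  expect_true(all(diff(tr) >= 0))      # rows: increasing c
  expect_true(all(t(diff(t(tr))) >= 0))  # cols: increasing h
})

test_that("with h=1 a single cut never creates an R allele", {
  for (c in c(0.3, 0.7, 1)) {
    p <- driveParams(c, 1, 1)
    d <- gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD")), ffDesign,
                            p)$FERTILITY_1
    expect_equal(unname(d["R1"] + d["R2"]), 0)
  }
  # ... but a double cut can (the first of two cuts has no template)
  p <- driveParams(1, 1, 1)
  d2 <- gameteDistribution(list(FERTILITY_1 = c("DRIVE", "WILD"),
                                TRA = c("WILD", "WILD")), sscDesign, p)$TRA
  expect_equal(unname(d2["R2"]), 1)
})

test_that("sampled gametes match the exact enumeration (oracle equivalence)", {
  withr::with_seed(11, {
    n <- 20000
    for (i in 1:6) {
      p <- randomParams()
      parent <- hemizygousFather(sscDesign)
      parent$alleles$TRA <- sample(c("WILD", "R1", "R2"), 2, replace = TRUE)
      emp <- sampleGametes(parent, sscDesign, p, n = n)
      exact <- gameteDistribution(parent, sscDesign, p)
      for (locus in c("FERTILITY_1", "TRA")) {
        for (s in alleleStates()) {
          pe <- exact[[locus]][s]
          expect_lt(abs(mean(emp[[locus]] == s) - pe),
                    3 * binomSE(pe, n) + 1 / n)
        }
      }
    }
  })
})

test_that("each meiosis is independent and sex chromosomes segregate", {
  withr::with_seed(3, {
    dad <- hemizygousFather()
    g <- sampleGametes(dad, ffDesign, driveParams(0, 1, 0.5), n = 4000)
    expect_lt(abs(mean(g$sexChromosome == "Y") - 0.5), 3 * binomSE(0.5, 4000))
    expect_lt(abs(mean(g$FERTILITY_1 == "DRIVE") - 0.5),
              3 * binomSE(0.5, 4000))
    # parent unchanged
    expect_identical(dad$alleles$FERTILITY_1, c("DRIVE", "WILD"))
    mom <- individual("XX", list(FERTILITY_1 = c("DRIVE", "WILD")),
                      design = ffDesign)
    gm <- sampleGametes(mom, ffDesign, driveParams(0, 1, 0.5), n = 100)
    expect_true(all(gm$sexChromosome == "X"))
    sterile <- individual("XX", list(FERTILITY_1 = c("DRIVE", "R2")),
                          design = ffDesign)
    expect_error(sampleGametes(sterile, ffDesign, driveParams(0, 1, 0.5)),
                 "sterile")
  })
})

test_that("maternal deposition is NHEJ-only and conditional on the construct", {
  withr::with_seed(5, {
    d <- ffDesign
    # construct-free mother: unchanged
    z <- applyMaternalDeposition(list(FERTILITY_1 = c("WILD", "WILD")),
                                 FALSE, d, driveParams(1, 1, 1))
    expect_identical(z$FERTILITY_1, c("WILD", "WILD"))
    # k = 0: unchanged
    z <- applyMaternalDeposition(list(FERTILITY_1 = c("WILD", "WILD")),
                                 TRUE, d, driveParams(1, 1, 1, maternalFactor = 0))
    expect_identical(z$FERTILITY_1, c("WILD", "WILD"))
    # saturated deposition with r2=0 turns every WILD into R1
    z <- applyMaternalDeposition(list(FERTILITY_1 = c("WILD", "WILD")),
                                 TRUE, d, driveParams(1, 1, 0))
    expect_identical(z$FERTILITY_1, c("R1", "R1"))
    # deposition never creates DRIVE and never touches non-targeted loci
    for (i in 1:20) {
      p <- randomParams(k = runif(1, 0, 2))
      z <- applyMaternalDeposition(list(FERTILITY_1 = c("WILD", "R1"),
                                        TRA = c("WILD", "WILD")),
                                   TRUE, sscDesign, p)
      expect_false(any(unlist(z) == "DRIVE"))
      expect_identical(z$FERTILITY_2, c("WILD", "WILD"))
      expect_identical(z$FERTILITY_1[2], "R1")
    }
  })
})

test_that("maternal tra provision follows ovarian disruption rules", {
  withr::with_seed(9, {
    wt <- individual("XX", design = sscDesign)
    expect_true(maternalTraProvision(wt, sscDesign, driveParams(1, 1, 1)))
    # SSC mother, tra (WILD, WILD), c=1: both copies disrupted, provision lost
    sscMom <- individual("XX", list(FERTILITY_1 = c("DRIVE", "WILD")),
                         design = sscDesign)
    expect_false(maternalTraProvision(sscMom, sscDesign, driveParams(1, 1, 1)))
    # tra-homing mother, c=0: no cleavage
    traMom <- individual("XX", list(TRA = c("DRIVE", "WILD")),
                         design = traDesign)
    expect_true(maternalTraProvision(traMom, traDesign, driveParams(0, 1, 0.5)))
    # a fertility-only design never disrupts provision
    ffMom <- individual("XX", list(FERTILITY_1 = c("DRIVE", "WILD")),
                        design = ffDesign)
    expect_true(maternalTraProvision(ffMom, ffDesign, driveParams(1, 1, 1)))
    dad <- hemizygousFather()
    expect_error(maternalTraProvision(dad, ffDesign, driveParams(1, 1, 1)),
                 "mothers only")
    # per-offspring Bernoulli: a tra-homing hemizygous mother at c loses
    # provision with probability c (one functional allele)
    draws <- replicate(2000, maternalTraProvision(traMom, traDesign,
                                                  driveParams(0.7, 1, 0.5)))
    expect_lt(abs(mean(!draws) - 0.7), 3 * binomSE(0.7, 2000))
  })
})
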