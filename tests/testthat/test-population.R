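test_that("the initial release has the stated composition and frequency", {
  cfg <- simConfig(sscDesign, driveParams(0.95, 0.95, 0.99), seed = 1)
  pop <- makeInitialPopulation(cfg)
  expect_equal(nrow(pop), 1000)
  expect_equal(sum(pop$sex == "FEMALE"), 500)
  expect_equal(sum(pop$sex == "MALE"), 500)
  expect_true(all(pop$fertile))
  expect_equal(driveAlleleFrequency(pop, "FERTILITY_1"), 0.125)
  expect_equal(driveAlleleFrequency(pop, "TRA"), 0)

  # scaling: N=8 with (4,2,2) gives the same 12.5%
  small <- simConfig(ffDesign, driveParams(0.5, 0.5, 0.5), populationSize = 8,
                     nWtFemales = 4, nWtMales = 2, nDriveMales = 2, seed = 1)
  expect_equal(driveAlleleFrequency(makeInitialPopulation(small),
                                    "FERTILITY_1"), 0.125)
  # no drive males, no drive alleles
  none <- simConfig(ffDesign, driveParams(0.5, 0.5, 0.5), populationSize = 8,
                    nWtFemales = 4, nWtMales = 4, nDriveMales = 0, seed = 1)
  expect_equal(driveAlleleFrequency(makeInitialPopulation(none),
                                    "FERTILITY_1"), 0)
  # inconsistent composition is rejected
  expect_error(simConfig(ffDesign, driveParams(0.5, 0.5, 0.5),
                         populationSize = 10, nWtFemales = 4, nWtMales = 4,
                         nDriveMales = 4, seed = 1),
               "sum to populationSize")
})

test_that("a generation step regulates size and collapses without a fertile pair", {
  withr::with_seed(21, {
    cfg <- smallConfig(ffDesign, driveParams(0.9, 0.9, 0.99))
    pop <- makeInitialPopulation(cfg)
    off <- stepGeneration(pop, ffDesign, cfg@params)
    expect_equal(nrow(off), nrow(pop))
    # all-male population collapses to empty
    males <- pop[pop$sex == "MALE", ]
    expect_equal(nrow(stepGeneration(males, ffDesign, cfg@params)), 0)
    # wild-type-only population: all offspring wild type, ~50% female
    wt <- makeInitialPopulation(
      simConfig(ffDesign, driveParams(1, 1, 1), populationSize = 400,
                nWtFemales = 200, nWtMales = 200, nDriveMales = 0, seed = 1))
    woff <- stepGeneration(wt, ffDesign, driveParams(1, 1, 1))
    expect_equal(driveAlleleFrequency(woff, "FERTILITY_1", "WILD"), 1)
    expect_lt(abs(mean(woff$sex == "FEMALE") - 0.5), 3 * binomSE(0.5, 400))
  })
})

test_that("every offspring of an SSC drive mother is male at c=1", {
  withr::with_seed(22, {
    p <- driveParams(1, 1, 1)
    n <- 60
    pop <- do.call(rbind, c(
      replicate(n, {
        i <- individual("XX", list(FERTILITY_1 = c("DRIVE", "WILD")),
                        design = sscDesign)
        data.frame(karyotype = i$karyotype, f1_m = 2L, f1_p = 1L,
                   tra_m = 1L, tra_p = 1L, f2_m = 1L, f2_p = 1L,
                   maternalTraIntact = TRUE, sex = i$sex, fertile = i$fertile)
      }, simplify = FALSE),
      replicate(n, {
        data.frame(karyotype = "XY", f1_m = 1L, f1_p = 1L, tra_m = 1L,
                   tra_p = 1L, f2_m = 1L, f2_p = 1L,
                   maternalTraIntact = TRUE, sex = "MALE", fertile = TRUE)
      }, simplify = FALSE)))
    off <- stepGeneration(pop, sscDesign, p, n = 500)
    expect_true(all(off$sex == "MALE"))
    expect_true(all(off$fertile))
  })
})

test_that("runs are reproducible and respect the horizon", {
  cfg <- smallConfig(sscDesign, driveParams(0.9, 0.9, 0.99), N = 200, G = 8,
                     seed = 33)
  r1 <- runSimulation(cfg)
  r2 <- runSimulation(cfg)
  expect_identical(trajectory(r1), trajectory(r2))
  expect_identical(isExtinct(r1), isExtinct(r2))
  expect_lte(max(trajectory(r1)$generation), 8)
  # replicate substreams differ but are reproducible in isolation
  reps <- runReplicates(cfg, 3, seed = 5)
  seeds <- replicateSeeds(5, 3)
  cfg@seed <- seeds[2]
  expect_identical(trajectory(reps[[2]]), trajectory(runSimulation(cfg)))
})

test_that("population size is exactly N every generation until extinction", {
  withr::with_seed(1, {
    for (design in list(sscDesign, dualDesign)) {
      cfg <- smallConfig(design, driveParams(1, 1, 1), N = 200, G = 20,
                         seed = sample.int(1e6, 1))
      tr <- trajectory(runSimulation(cfg))
      expect_true(all(tr$size == 200))
      # allele counts bounded by 2N at every locus
      for (locus in locusIds()) {
        tot <- rowSums(tr[, paste(locus, alleleStates(), sep = "_")])
        expect_true(all(tot == 2 * tr$size))
      }
    }
  })
})

test_that("simulated individuals never violate the genetics invariants", {
  cfg <- smallConfig(sscDesign, driveParams(0.8, 0.8, 0.8), N = 300, G = 6,
                     seed = 12)
  withr::with_seed(cfg@seed, {
    pop <- makeInitialPopulation(cfg)
    for (g in 1:6) {
      pop <- stepGeneration(pop, sscDesign, cfg@params)
      if (nrow(pop) == 0) break
      # no female without maternal provision and a functional tra allele
      fem <- pop[pop$sex == "FEMALE", ]
      expect_true(all(fem$maternalTraIntact))
      expect_true(all(isFunctional(fem$tra_m) | isFunctional(fem$tra_p)))
      # XY implies male
      expect_true(all(pop$sex[pop$karyotype == "XY"] == "MALE"))
      # DRIVE only at the home locus
      expect_true(all(pop$tra_m != 2 & pop$tra_p != 2))
      expect_true(all(pop$f2_m != 2 & pop$f2_p != 2))
      # sex/fertility are consistent with a recomputation from genotype
      expect_identical(pop$sex, determineSex(pop$karyotype, pop$tra_m,
                                             pop$tra_p, pop$maternalTraIntact))
    }
  })
})

test_that("generation-1 drive frequency matches the infinite-population recursion", {
  # random union of gametes: half the fathers are hemizygous, so the
  # expected offspring drive frequency is P(DRIVE gamete)/4 = (1+ch)/8
  withr::with_seed(14, {
    for (i in 1:5) {
      p <- randomParams()
      expected <- (1 + cleavageRate(p) * hdrRate(p)) / 8
      cfg <- smallConfig(ffDesign, p, N = 400)
      pop <- makeInitialPopulation(cfg)
      freqs <- replicate(120, driveAlleleFrequency(
        stepGeneration(pop, ffDesign, p), "FERTILITY_1"))
      se <- sd(freqs) / sqrt(length(freqs))
      expect_lt(abs(mean(freqs) - expected), 3 * se + 1e-6)
    }
  })
})

test_that("female fraction is non-increasing in cleavage for tra-targeting drives", {
  withr::with_seed(15, {
    for (design in list(traDesign, sscDesign)) {
      femFrac <- sapply(c(0.2, 0.6, 1), function(cl) {
        reps <- runReplicates(
          smallConfig(design, driveParams(cl, 0.9, 0.99), N = 200, G = 5),
          40, seed = 100 + round(100 * cl))
        f <- vapply(reps, function(r) {
          tr <- trajectory(r)
          last <- tr[nrow(tr), ]
          if (last$size == 0) 0 else last$fertile_females / last$size
        }, numeric(1))
        c(mean = mean(f), se = sd(f) / sqrt(length(f)))
      })
      for (j in 1:2)
        expect_lt(femFrac["mean", j + 1],
                  femFrac["mean", j] +
                    3 * sqrt(femFrac["se", j]^2 + femFrac["se", j + 1]^2))
    }
  })
})

test_that("replicate summaries follow the stated arithmetic", {
  mk <- function(extinct, gen, G = 20) {
    cfg <- smallConfig(ffDesign, driveParams(0, 0, 0), N = 8, G = G, seed = 1)
    new("SimResult", trajectory = data.frame(generation = 0L, size = 8L),
        extinct = extinct,
        extinctionGeneration = if (extinct) as.integer(gen) else NA_integer_,
        config = cfg)
  }
  res <- c(replicate(7, mk(TRUE, 5), simplify = FALSE),
           replicate(3, mk(FALSE, NA), simplify = FALSE))
  s <- summarizeReplicates(res)
  expect_equal(s$extinction_fraction, 0.7)
  expect_equal(s$mean_time_to_extinction, 5)
  none <- summarizeReplicates(replicate(4, mk(FALSE, NA), simplify = FALSE))
  expect_equal(none$extinction_fraction, 0)
  expect_true(is.na(none$mean_time_to_extinction))
  two <- summarizeReplicates(list(mk(TRUE, 4), mk(TRUE, 6)))
  expect_equal(two$mean_time_to_extinction, 5)
  # censored alternative counts survivors at the horizon
  cens <- summarizeReplicates(list(mk(TRUE, 4), mk(FALSE, NA)),
                              time = "censored")
  expect_equal(cens$mean_time_to_extinction, 12)
})

test_that("scenario files round-trip through the JSON/YAML reader", {
  tmp <- withr::local_tempdir()
  json <- file.path(tmp, "scenario.json")
  writeLines(jsonlite::toJSON(list(
    design = "ssc", generations = 10, population_size = 200,
    n_wt_females = 100, n_wt_males = 50, n_drive_males = 50, seed = 9,
    params = list(cleavage = 0.9, hdr = 0.8, r2 = 0.7, maternal_factor = 0.5)),
    auto_unbox = TRUE), json)
  cfg <- readSimConfig(json)
  expect_identical(designName(cfg@design), "SSC")
  expect_equal(maternalFactor(cfg@params), 0.5)
  expect_equal(cfg@generations, 10L)
  yamlFile <- file.path(tmp, "scenario.yaml")
  writeLines(c("design: female_fertility", "params:", "  cleavage: 1",
               "  hdr: 1", "  r2: 1"), yamlFile)
  cfg2 <- readSimConfig(yamlFile)
  expect_identical(designName(cfg2@design), "FEMALE_FERTILITY")
  expect_equal(cfg2@populationSize, 1000L)
  writeLines('{"design": "ssc", "params": {"cleavage": 0.5}}',
             file.path(tmp, "bad.json"))
  expect_error(readSimConfig(file.path(tmp, "bad.json")), "missing required")
  writeLines('{"design": "ssc", "bogus": 1, "params": {"cleavage": 1, "hdr": 1, "r2": 1}}',
             file.path(tmp, "unk.json"))
  expect_error(readSimConfig(file.path(tmp, "unk.json")), "unknown scenario keys")
  # trajectory TSV writer: one row per generation per replicate
  res <- runReplicates(smallConfig(ffDesign, driveParams(0, 0, 0), N = 20,
                                   G = 3), 2, seed = 4)
  out <- file.path(tmp, "traj.tsv")
  writeTrajectories(res, out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), sum(vapply(res, function(r) nrow(trajectory(r)),
                                     integer(1))))
  expect_true(all(c("replicate", "generation", "fertile_females") %in%
                    names(tab)))
})
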