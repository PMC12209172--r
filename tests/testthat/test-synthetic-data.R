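test_that("noise-free bursts return the drawn proximity ratio exactly", {
    # fixed-width species: every burst gives exactly the center
    b <- simulateBursts(singleSpeciesConfig(0.8, eWidth = 0, n = 200))
    expect_true(all(abs(computeEpr(b$I3, b$I5) - 0.8) < 1e-9))
    # dispersed species: round-trip to the recorded truth per burst
    b <- simulateBursts(singleSpeciesConfig(0.4, eWidth = 0.1, n = 2000,
                                            seed = 7))
    expect_lt(max(abs(computeEpr(b$I3, b$I5) - b$true_e)), 1e-9)
})

test_that("donor-only species yields pure crosstalk in the acceptor channel", {
    b <- simulateBursts(singleSpeciesConfig(0, eWidth = 0, n = 100))
    expect_equal(b$I5, 0.19 * b$I3, tolerance = 1e-12)
    expect_true(all(abs(computeEpr(b$I3, b$I5)) < 1e-12))
})

test_that("species are sampled at their configured fractions", {
    n <- 10000L
    cfg <- scenarioConfig(
        species = list(speciesSpec("a", 0.8, 0.05, 0.7),
                       speciesSpec("b", 0.03, 0.05, 0.3)),
        nBursts = n, noise = TRUE, seed = 11)
    b <- simulateBursts(cfg)
    nA <- sum(b$true_species == "a")
    bound <- 3 * sqrt(n * 0.7 * 0.3)
    expect_lt(abs(nA - n * 0.7), bound)
})

test_that("identical configuration and seed reproduce identical tables", {
    cfg <- twoSpeciesConfig(n = 1000, seed = 99, noise = TRUE)
    expect_identical(simulateBursts(cfg), simulateBursts(cfg))
    # and a different seed does not
    cfg2 <- twoSpeciesConfig(n = 1000, seed = 100, noise = TRUE)
    expect_false(identical(simulateBursts(cfg), simulateBursts(cfg2)))
})

test_that("scenario validation names the offending field", {
    expect_error(scenarioConfig(list(speciesSpec("a", 0.8, 0.05, 0.5)),
                                nBursts = 100),
                 "fractions")
    expect_error(scenarioConfig(list(speciesSpec("a", 1.4, 0.05, 1)),
                                nBursts = 100),
                 "eCenter")
    expect_error(scenarioConfig(list(speciesSpec("a", 0.8, 0.05, 1)),
                                nBursts = 0),
                 "nBursts")
    # aggregates may sit outside the non-aggregate center constraint
    expect_s4_class(
        scenarioConfig(list(speciesSpec("a", 0.8, 0.05, 0.9),
                            speciesSpec("agg", 0.8, 0.05, 0.1,
                                        isAggregate = TRUE)),
                       nBursts = 10),
        "ScenarioConfig")
})

test_that("aggregate species are brighter and slower by the configured factors", {
    cfg <- scenarioConfig(
        species = list(speciesSpec("normal", 0.8, 0, 0.5),
                       speciesSpec("agg", 0.8, 0, 0.5, isAggregate = TRUE)),
        nBursts = 4000, noise = FALSE, seed = 5)
    b <- simulateBursts(cfg)
    tot <- b$I3 + b$I5
    ratioBright <- mean(tot[b$true_species == "agg"]) /
        mean(tot[b$true_species == "normal"])
    expect_gt(ratioBright, 5)   # x10 in expectation, exponential spread
    expect_equal(unique(b$duration_ms[b$true_species == "agg"]) /
                 unique(b$duration_ms[b$true_species == "normal"]), 10)
})

test_that("titration generator obeys the one-site identities", {
    ladder <- c(0, 0.5, 2, 8, 32, 128)
    tt <- simulateTitration(kd = 2, im = 100, ifl0 = 10, ladder)
    # half-saturation identity at C = kd and the zero-ligand intercept
    expect_equal(tt$intensity[tt$concentration == 2], 100 / 2 + 10)
    expect_equal(tt$intensity[tt$concentration == 0], 10)
    # noise off: intensity strictly increases with concentration
    expect_true(all(diff(tt$intensity[order(tt$concentration)]) > 0))
    expect_error(simulateTitration(-1, 100, 10, ladder), "kd")
    expect_error(simulateTitration(2, 100, 10, c(0, 1, 2, 2)), "5 distinct")
})

test_that("binding-series generator obeys the Hill identities", {
    conc <- c(12.5, 25, 50, 100, 200)
    bs <- simulateBindingSeries(40, 1, c(0, conc))
    expect_equal(bs$fraction_free[bs$concentration == 0], 1)
    bs2 <- simulateBindingSeries(40, 1, c(40, conc))
    expect_equal(bs2$fraction_free[bs2$concentration == 40], 0.5)
    expect_true(all(diff(bs$fraction_free[order(bs$concentration)]) <= 0))
    expect_true(all(bs$fraction_free >= 0 & bs$fraction_free <= 1))
    expect_error(simulateBindingSeries(0, 1, conc), "halfSat")
    expect_error(simulateBindingSeries(40, 0, conc), "steepness")
})

test_that("gel intensity units sum as expected", {
    # cv -> 0 limit: doubling the unit count exactly doubles the intensity
    one <- simulateGelIntensities(1, 10, 100, 0, seed = 1)
    two <- simulateGelIntensities(2, 10, 100, 0, seed = 1)
    expect_equal(mean(two) / mean(one), 2)
    expect_length(simulateGelIntensities(1, 0, 100, 0.3), 0)
    # CLT bound on the sample mean at cv = 0.3
    x <- simulateGelIntensities(1, 5000, 100, 0.3, seed = 3)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 100), 3 * se)
})

test_that("scenario YAML round-trips through read/write", {
    cfg <- npScenario(nBursts = 250, seed = 42)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeScenario(cfg, path)
    cfg2 <- readScenario(path)
    expect_identical(simulateBursts(cfg), simulateBursts(cfg2))
})
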