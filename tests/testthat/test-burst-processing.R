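test_that("aggregate rejection handles empty and trivial inputs", {
    empty <- data.frame(burst_id = integer(), I3 = numeric(),
                        I5 = numeric(), duration_ms = numeric())
    cfgAbs <- filterConfig(intensityAbs = 1000, durationAbs = 5,
                           minTotal = 20)
    out <- rejectAggregates(empty, cfgAbs)
    expect_equal(nrow(out), 0)
    expect_equal(attr(out, "rejection")$nIntensity, 0)
    # percentile limits are undefined on an empty table
    expect_error(rejectAggregates(empty, filterConfig()), "absolute")
    # one burst at 10x the absolute duration cut is rejected for duration
    one <- data.frame(burst_id = 1L, I3 = 50, I5 = 50, duration_ms = 50)
    out <- rejectAggregates(one, cfgAbs)
    expect_equal(nrow(out), 0)
    expect_equal(attr(out, "rejection")$nDuration, 1)
    expect_equal(attr(out, "rejection")$nIntensity, 0)
})

test_that("aggregate rejection is idempotent with absolute limits", {
    b <- simulateBursts(npScenario(nBursts = 2000, seed = 8))
    cfgAbs <- filterConfig(intensityAbs = 500, durationAbs = 4,
                           minTotal = 20)
    once <- rejectAggregates(b, cfgAbs)
    twice <- rejectAggregates(once, cfgAbs)
    attr(once, "rejection") <- NULL
    attr(twice, "rejection") <- NULL
    expect_identical(once, twice)
})

test_that("percentile filter removes labelled aggregates, keeps normal bursts", {
    b <- simulateBursts(npScenario(nBursts = 10000, seed = 21))
    kept <- rejectAggregates(b)
    isAgg <- b$true_species == "aggregate"
    aggKept <- sum(kept$true_species == "aggregate")
    sensitivity <- 1 - aggKept / sum(isAgg)
    expect_gte(sensitivity, 0.90)
    # false rejection among sufficiently bright normal bursts; the dim-burst
    # floor is a separate, intended cut
    normBright <- !isAgg & (b$I3 + b$I5) >= 20
    keptNorm <- sum(!kept$true_species == "aggregate")
    falseRej <- 1 - keptNorm / sum(normBright)
    expect_lte(falseRej, 0.05)
})

test_that("profiles are normalised, clipped values are reported", {
    p <- buildProfile(rep(0.8, 3000))
    expect_equal(sum(binFrequencies(p)), 1, tolerance = 1e-12)
    expect_equal(max(binFrequencies(p)), 1)
    expect_equal(binCenters(p)[which.max(binFrequencies(p))], 0.825)
    # clipping keeps normalisation and counts the clipped values
    vals <- c(rep(0.5, 2500), rep(-0.7, 30), rep(1.5, 20))
    p2 <- buildProfile(vals)
    expect_equal(sum(binFrequencies(p2)), 1, tolerance = 1e-12)
    expect_equal(unname(p2@clipped), c(30L, 20L))
    expect_error(buildProfile(rep(0.5, 2500), binWidth = 0), "binWidth")
    expect_error(buildProfile(rep(0.5, 50)), "at least 100")
    expect_warning(buildProfile(rep(0.5, 500)), "2000")
})

test_that("uniform values fill bins at multinomial rates", {
    set.seed(31)
    vals <- runif(1e5, 0, 1)
    p <- suppressWarnings(buildProfile(vals))
    inRange <- binCenters(p) > 0.025 & binCenters(p) < 0.975
    expected <- 0.05  # bin width / support width
    semax <- 3 * sqrt(expected * (1 - expected) / 1e5)
    expect_true(all(abs(binFrequencies(p)[inRange] -
                        expected * 1.0) < 5 * semax + 0.003))
    expect_equal(sum(binFrequencies(p)), 1, tolerance = 1e-12)
})

test_that("two-species scenario produces modes at both centers", {
    epr <- eprFromScenario(twoSpeciesConfig(n = 5000, seed = 13,
                                            noise = TRUE))
    p <- buildProfile(epr)
    freq <- binFrequencies(p)
    ctr <- binCenters(p)
    # modal bin of the high region near 0.8, of the low region near 0.03
    hi <- ctr > 0.5
    lo <- ctr < 0.3
    expect_lt(abs(ctr[hi][which.max(freq[hi])] - 0.8), 0.06)
    expect_lt(abs(ctr[lo][which.max(freq[lo])] - 0.03), 0.06)
})

test_that("replicate averaging yields mean and SEM per bin", {
    p <- buildProfile(rep(c(0.2, 0.8), 1500))
    same <- aggregateReplicates(list(p, p, p))
    expect_equal(binFrequencies(same), binFrequencies(p))
    expect_true(all(binSEM(same) == 0))
    # replicates with different seeds: SEM > 0, mean close to each replicate
    profs <- lapply(1:3, function(s)
        buildProfile(eprFromScenario(twoSpeciesConfig(n = 3000, seed = s,
                                                      noise = TRUE))))
    agg <- aggregateReplicates(profs)
    expect_gt(max(binSEM(agg)), 0)
    expect_equal(sum(binFrequencies(agg)), 1, tolerance = 1e-12)
    dev <- abs(binFrequencies(agg) - binFrequencies(profs[[1]]))
    expect_true(all(dev <= 3 * binSEM(agg) + 1e-3))
    # mismatched grids are refused
    q <- buildProfile(rep(c(0.2, 0.8), 1500), binWidth = 0.1)
    expect_error(aggregateReplicates(list(p, q)), "grid")
})

test_that("burst tables and profiles round-trip through CSV", {
    b <- simulateBursts(npScenario(nBursts = 300, seed = 2))
    f <- withr::local_tempfile(fileext = ".csv")
    writeBurstTable(b, f)
    b2 <- readBurstTable(f)
    expect_equal(b2$I3, b$I3)
    expect_equal(b2$true_e, b$true_e, tolerance = 1e-12)
    p <- suppressWarnings(buildProfile(rep(0.8, 150)))
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeProfile(p, f2)
    pf <- read.csv(f2)
    expect_equal(pf$frequency, binFrequencies(p))
})
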