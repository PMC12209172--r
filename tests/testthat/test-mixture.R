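test_that("single-Gaussian data is recovered as one component", {
    set.seed(101)
    x <- rnorm(5000, 0.8, 0.05)
    fit <- fitMixture(x, seed = 101)
    cmp <- components(fit)
    expect_equal(nrow(cmp), 1)
    expect_lt(abs(cmp$center - 0.8), 0.01)
    expect_true(isConverged(fit))
})

test_that("two-component mixtures are recovered with weights and centers", {
    set.seed(202)
    x <- c(rnorm(3500, 0.8, 0.07), rnorm(1500, 0.03, 0.05))
    fit <- fitMixture(x, seed = 202)
    cmp <- components(fit)
    expect_equal(nrow(cmp), 2)
    expect_lt(abs(cmp$center[1] - 0.03), 0.02)
    expect_lt(abs(cmp$center[2] - 0.80), 0.02)
    expect_lt(abs(cmp$weight[1] - 0.3), 0.05)
    expect_lt(abs(cmp$weight[2] - 0.7), 0.05)
    expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
})

test_that("degenerate input returns a single floor-width component", {
    fit <- fitMixture(rep(0.5, 300))
    cmp <- components(fit)
    expect_equal(nrow(cmp), 1)
    expect_equal(cmp$center, 0.5)
    expect_equal(cmp$width, 0.01)
    expect_true(isConverged(fit))
})

test_that("input below the size floor and bad k candidates are refused", {
    expect_error(fitMixture(rnorm(100)), "at least 200")
    expect_error(fitMixture(rnorm(500), kCandidates = c(1, 5)), "1..4")
})

test_that("every EM restart improves on its starting log-likelihood", {
    set.seed(7)
    x <- c(rnorm(1500, 0.8, 0.07), rnorm(500, 0.03, 0.05))
    fit <- fitMixture(x, seed = 7)
    d <- fit@restarts
    expect_gt(nrow(d), 0)
    expect_true(all(d$logLik >= d$logLik0 - 1e-8))
})

test_that("component labelling is invariant to input order", {
    set.seed(55)
    x <- c(rnorm(2000, 0.8, 0.07), rnorm(1000, 0.03, 0.05))
    fitA <- fitMixture(x, seed = 9)
    fitB <- fitMixture(sample(x), seed = 9)
    expect_equal(components(fitA)$center, components(fitB)$center,
                 tolerance = 1e-6)
    expect_equal(components(fitA)$weight, components(fitB)$weight,
                 tolerance = 1e-6)
})

test_that("1-3 well-separated components are recovered over a seed grid", {
    # centers separated by >= 0.2, n = 5000: selected k must equal true k
    # and centers must be within 0.02
    cases <- list(
        list(centers = 0.5, weights = 1, sds = 0.06),
        list(centers = c(0.1, 0.7), weights = c(0.4, 0.6),
             sds = c(0.05, 0.07)),
        list(centers = c(0.03, 0.4, 0.8), weights = c(0.25, 0.45, 0.30),
             sds = c(0.05, 0.07, 0.07)))
    for (seed in c(1, 2)) {
        for (cs in cases) {
            set.seed(seed)
            n <- 5000
            idx <- sample.int(length(cs$centers), n, TRUE, prob = cs$weights)
            x <- rnorm(n, cs$centers[idx], cs$sds[idx])
            fit <- fitMixture(x, seed = seed)
            cmp <- components(fit)
            expect_equal(nrow(cmp), length(cs$centers),
                         info = sprintf("seed %d, true k %d", seed,
                                        length(cs$centers)))
            expect_true(all(abs(cmp$center - sort(cs$centers)) < 0.02))
        }
    }
})

test_that("mixture decomposition agrees with an independent EM implementation", {
    skip_if_not_installed("mclust")
    suppressPackageStartupMessages(library(mclust))
    set.seed(404)
    x <- c(rnorm(3000, 0.8, 0.07), rnorm(2000, 0.03, 0.05))
    ours <- fitMixture(x, seed = 404)
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(components(ours)$center),
                 sort(unname(mc$parameters$mean)), tolerance = 0.01)
    expect_equal(ours@logLik, mc$loglik, tolerance = 1e-3)
})

test_that("state fractions sum component weights inside windows", {
    mkFit <- function(weights, centers, widths = 0.05) {
        new("MixtureFit",
            components = data.frame(weight = weights, center = centers,
                                    width = rep(widths,
                                                length.out = length(weights))),
            nPoints = 1000L, logLik = 0, bic = 0,
            bicTable = data.frame(k = length(weights), logLik = 0,
                                  bic = 0, icl = 0),
            converged = TRUE, seed = 1L,
            restarts = data.frame(k = integer(), restart = integer(),
                                  logLik0 = numeric(), logLik = numeric()))
    }
    f1 <- mkFit(1, 0.8)
    fr <- subpopulationFractions(f1, list(intact = c(0.6, 1.0)))
    expect_equal(unname(fr["intact"]), 1)
    expect_equal(unname(fr["other"]), 0)
    f2 <- mkFit(c(0.4, 0.6), c(0.4, 0.8))
    fr2 <- subpopulationFractions(f2,
        list(intact = c(0.6, 1.0), reorganized = c(0.25, 0.55)))
    expect_equal(unname(fr2["intact"]), 0.6)
    expect_equal(unname(fr2["reorganized"]), 0.4)
    expect_equal(sum(fr2), 1, tolerance = 1e-12)
    # overlapping windows are a configuration error
    expect_error(subpopulationFractions(f2,
        list(a = c(0, 0.5), b = c(0.4, 1))), "disjoint")
})

test_that("state fractions recover the generating weights on simulated data", {
    sc <- znScenario(nBursts = 8000, seed = 17, aggregateFraction = 0)
    res <- processBursts(simulateBursts(sc), seed = 17)
    fr <- subpopulationFractions(res$fit)
    expect_lt(abs(fr[["open"]] - 0.25), 0.05)
    expect_lt(abs(fr[["reorganized"]] - 0.45), 0.05)
    expect_lt(abs(fr[["intact"]] - 0.30), 0.05)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("condition comparison reports shifts, appearances, disappearances", {
    mk <- function(weights, centers) new("MixtureFit",
        components = data.frame(weight = weights, center = centers,
                                width = 0.05),
        nPoints = 1000L, logLik = 0, bic = 0,
        bicTable = data.frame(k = length(weights), logLik = 0, bic = 0,
                              icl = 0),
        converged = TRUE, seed = 1L,
        restarts = data.frame(k = integer(), restart = integer(),
                              logLik0 = numeric(), logLik = numeric()))
    fA <- mk(1, 0.8)
    # identical fits: one matched pair, nothing appears or disappears
    same <- compareConditions(fA, fA)
    expect_equal(nrow(same$matched), 1)
    expect_equal(same$matched$shift, 0)
    expect_equal(nrow(same$appeared), 0)
    expect_equal(nrow(same$disappeared), 0)
    # a new 0.4 peak appears in condition B
    fB <- mk(c(0.4, 0.6), c(0.4, 0.8))
    rep <- compareConditions(fA, fB)
    expect_equal(nrow(rep$appeared), 1)
    expect_equal(rep$appeared$center, 0.4)
    # reversed: the 0.4 peak disappears
    rep2 <- compareConditions(fB, fA)
    expect_equal(nrow(rep2$disappeared), 1)
    notConv <- mk(1, 0.8); notConv@converged <- FALSE
    expect_error(compareConditions(fA, notConv), "converged")
})

test_that("reorganized weight rises monotonically along a Zn titration", {
    # emulate increasing Zn: reorganized fraction growing at the expense
    # of the intact state
    reorgW <- c(0, 0.25, 0.5, 0.75, 1)
    trend <- vapply(seq_along(reorgW), function(i) {
        w <- reorgW[i]
        species <- list()
        if (w < 1) species <- c(species, list(
            speciesSpec("intact", 0.8, 0.07, 1 - w)))
        if (w > 0) species <- c(species, list(
            speciesSpec("reorganized", 0.4, 0.07, w)))
        cfg <- scenarioConfig(species, nBursts = 4000, noise = TRUE,
                              seed = 300 + i)
        res <- processBursts(simulateBursts(cfg),
                             filter = filterConfig(), seed = 300 + i)
        subpopulationFractions(res$fit)[["reorganized"]]
    }, numeric(1))
    expect_true(all(diff(trend) > 0))
    expect_lt(trend[1], 0.05)
    expect_gt(trend[5], 0.95)
})

test_that("mixture fits serialise to JSON", {
    set.seed(1)
    fit <- fitMixture(rnorm(500, 0.5, 0.05), seed = 1)
    f <- withr::local_tempfile(fileext = ".json")
    writeMixtureFit(fit, f)
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(j$components$center, components(fit)$center,
                 tolerance = 1e-9)
    expect_true(j$converged)
})
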