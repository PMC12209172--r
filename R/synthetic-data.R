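# Synthetic-data generators. These emulate, at the per-burst / per-point
# granularity the analysis actually consumes, the four measurement types
# the pipeline handles: diffusing-particle burst tables, fluorescence
# titrations, gel-shift binding series, and in-gel single-complex
# acceptor intensities. Ground truth (species label, true proximity
# ratio, pre-noise intensity) is carried alongside so every downstream
# stage can be tested against it.

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Truncated-normal draw by resampling until all values fall in [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
}

#' Simulate a two-channel burst table
#'
#' Generates per-particle donor/acceptor intensities for a mixture of
#' species. For each burst a species is drawn by its mixing fraction, a
#' true proximity ratio \eqn{e} is drawn from a normal distribution
#' truncated to the attainable range \eqn{[-\alpha/\beta, 1]}, and total
#' signal photons \eqn{N} from an exponential with the species' mean
#' brightness. Donor and acceptor emissions are \eqn{D = N(1 - e)} and
#' \eqn{A = N e}; channel expectations are \eqn{I_3 = D + b_3} and
#' \eqn{I_5 = A + \alpha D + b_5} (the acceptor channel receives the
#' crosstalk share of the donor emission). With noise on, observed counts
#' are Poisson around these expectations; with noise off the expectations
#' are returned exactly, so the crosstalk-corrected proximity ratio
#' recovers \eqn{e} to machine precision at zero background. Species
#' flagged \code{isAggregate} get the scenario's brightness and duration
#' multipliers, reproducing the slow/bright contaminant signature.
#'
#' @param config a [ScenarioConfig-class].
#' @return A \code{data.frame} with columns \code{burst_id}, \code{I3},
#'   \code{I5}, \code{duration_ms}, \code{true_species}, \code{true_e}.
#' @examples
#' sc <- scenarioConfig(
#'     species = list(speciesSpec("intact", 0.8, 0, 1)),
#'     nBursts = 5, noise = FALSE)
#' b <- simulateBursts(sc)
#' computeEpr(b$I3, b$I5)   # exactly 0.8 for every burst
#' @export
simulateBursts <- function(config) {
    stopifnot(is(config, "ScenarioConfig"))
    validObject(config)
    n <- config@nBursts
    sp <- config@species
    a <- config@crosstalk@alpha
    rng <- eprRange(config@crosstalk)
    fractions <- vapply(sp, slot, numeric(1), "fraction")

    withSeed(config@seed, {
        idx <- sample.int(length(sp), n, replace = TRUE, prob = fractions)
        e <- numeric(n)
        N <- numeric(n)
        dur <- numeric(n)
        for (j in seq_along(sp)) {
            rows <- which(idx == j)
            if (!length(rows)) next
            s <- sp[[j]]
            bright <- s@brightness *
                (if (s@isAggregate) config@aggBrightnessMult else 1)
            dscale <- s@durationScale *
                (if (s@isAggregate) config@aggDurationMult else 1)
            e[rows] <- rtruncnorm(length(rows), s@eCenter, s@eWidth,
                                  rng[1], rng[2])
            N[rows] <- stats::rexp(length(rows), rate = 1 / bright)
            # transit times through the confocal volume are peaked around
            # their mean, not memoryless: lognormal with cv 0.3
            dur[rows] <- if (config@noise) {
                sdlog <- sqrt(log(1 + 0.3^2))
                stats::rlnorm(length(rows), log(dscale) - sdlog^2 / 2,
                              sdlog)
            } else rep(dscale, length(rows))
        }
        D <- N * (1 - e)
        A <- N * e
        lam3 <- D + config@background3
        lam5 <- A + a * D + config@background5  # >= 0 on the attainable range
        if (config@noise) {
            i3 <- stats::rpois(n, lam3)
            i5 <- stats::rpois(n, lam5)
        } else {
            i3 <- lam3
            i5 <- lam5
        }
        data.frame(
            burst_id = seq_len(n),
            I3 = i3, I5 = i5,
            duration_ms = dur,
            true_species = vapply(sp, slot, character(1), "name")[idx],
            true_e = e,
            stringsAsFactors = FALSE)
    })
}

#' Simulate a one-site saturation titration
#'
#' Generates integral fluorescence intensities along a ligand
#' concentration ladder from the one-site isotherm
#' \eqn{I_{fl}(C) = I_m C / (K_d + C) + I_{fl0}} with multiplicative
#' Gaussian noise. If per-step dilution factors are supplied, the emitted
#' intensities are the *diluted* (as-measured) values and the factors are
#' recorded so [correctDilution()] can be exercised against the recorded
#' pre-dilution truth.
#'
#' @param kd dissociation constant (uM, > 0).
#' @param im maximal intensity increase (a.u.).
#' @param ifl0 intensity at zero ligand (a.u.).
#' @param concentrations ligand concentrations (uM), at least 5 distinct.
#' @param cvNoise multiplicative noise coefficient of variation (0 = none).
#' @param seed integer RNG seed.
#' @param replicates number of replicate series.
#' @param dilutionFactors optional numeric in (0, 1], recycled along the
#'   ladder; default 1 (no dilution).
#' @return A \code{data.frame} with columns \code{concentration},
#'   \code{intensity}, \code{dilution_factor}, \code{replicate},
#'   \code{true_intensity} (pre-noise, pre-dilution model value), with
#'   attribute \code{units = "uM"}.
#' @examples
#' tt <- simulateTitration(2, 100, 10, c(0, 0.5, 2, 8, 32, 128))
#' subset(tt, concentration == 2)$true_intensity  # im/2 + ifl0 = 60
#' @export
simulateTitration <- function(kd, im, ifl0, concentrations, cvNoise = 0,
                              seed = 1L, replicates = 1L,
                              dilutionFactors = 1) {
    if (kd <= 0) stop("'kd' must be > 0")
    if (any(concentrations < 0)) stop("concentrations must be >= 0")
    if (length(unique(concentrations)) < 5)
        stop("at least 5 distinct concentrations are required")
    if (any(dilutionFactors <= 0 | dilutionFactors > 1))
        stop("'dilutionFactors' must lie in (0, 1]")
    dil <- rep_len(dilutionFactors, length(concentrations))
    withSeed(seed, {
        out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
            truth <- im * concentrations / (kd + concentrations) + ifl0
            noise <- if (cvNoise > 0)
                1 + stats::rnorm(length(truth), 0, cvNoise) else 1
            data.frame(
                concentration = concentrations,
                intensity = truth * noise * dil,
                dilution_factor = dil,
                replicate = r,
                true_intensity = truth)
        }))
        attr(out, "units") <- "uM"
        out
    })
}

#' Simulate a gel-shift binding series
#'
#' Generates the fraction of free (unshifted) nucleosomes versus titrant
#' concentration from a Hill-form depletion curve
#' \eqn{f(C) = 1 / (1 + (C/c_{50})^h)} with multiplicative noise, clipped
#' to [0, 1].
#'
#' @param halfSat concentration at 50\% depletion (nM, > 0).
#' @param steepness Hill steepness (> 0, default 1).
#' @param concentrations titrant concentrations (nM).
#' @param cvNoise multiplicative noise coefficient of variation.
#' @param seed integer RNG seed.
#' @param replicates number of replicate series.
#' @return A \code{data.frame} with columns \code{concentration},
#'   \code{fraction_free}, \code{replicate}, \code{true_fraction}, with
#'   attribute \code{units = "nM"}.
#' @examples
#' simulateBindingSeries(40, 1, c(12.5, 25, 50, 100, 200))
#' @export
simulateBindingSeries <- function(halfSat, steepness = 1, concentrations,
                                  cvNoise = 0, seed = 1L, replicates = 1L) {
    if (halfSat <= 0) stop("'halfSat' must be > 0")
    if (steepness <= 0) stop("'steepness' must be > 0")
    if (any(concentrations < 0)) stop("concentrations must be >= 0")
    withSeed(seed, {
        out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
            truth <- 1 / (1 + (concentrations / halfSat)^steepness)
            noise <- if (cvNoise > 0)
                1 + stats::rnorm(length(truth), 0, cvNoise) else 1
            data.frame(
                concentration = concentrations,
                fraction_free = pmin(pmax(truth * noise, 0), 1),
                replicate = r,
                true_fraction = truth)
        }))
        attr(out, "units") <- "nM"
        out
    })
}

#' Simulate single-complex acceptor intensities for one gel band
#'
#' Each particle's acceptor intensity is the sum of
#' \code{nNucleosomesPerParticle} independent lognormal unit intensities
#' with mean \code{unitMean} and coefficient of variation \code{unitCV},
#' so a band of 2:1 complexes is on average twice as bright per particle
#' as a 1:1 band. With \code{unitCV = 0} the units are exactly
#' \code{unitMean}. An optional dropout fraction removes (dark-acceptor)
#' units for sensitivity checks; it defaults to 0.
#'
#' @param nNucleosomesPerParticle integer >= 1, nucleosomes per complex.
#' @param nParticles number of particles to draw (0 gives an empty vector).
#' @param unitMean mean intensity of one nucleosome unit (counts).
#' @param unitCV coefficient of variation of one unit.
#' @param seed integer RNG seed.
#' @param dropout probability that a unit contributes no signal.
#' @return Numeric vector of per-particle intensities.
#' @examples
#' x <- simulateGelIntensities(1, 1000, 100, 0.3, seed = 7)
#' @export
simulateGelIntensities <- function(nNucleosomesPerParticle, nParticles,
                                   unitMean, unitCV, seed = 1L,
                                   dropout = 0) {
    if (nNucleosomesPerParticle < 1)
        stop("'nNucleosomesPerParticle' must be >= 1")
    if (nParticles < 0) stop("'nParticles' must be >= 0")
    if (unitMean <= 0) stop("'unitMean' must be > 0")
    if (unitCV < 0) stop("'unitCV' must be >= 0")
    if (dropout < 0 || dropout >= 1) stop("'dropout' must lie in [0, 1)")
    if (nParticles == 0) return(numeric(0))
    k <- as.integer(nNucleosomesPerParticle)
    withSeed(seed, {
        if (unitCV == 0) {
            units <- matrix(unitMean, nrow = nParticles, ncol = k)
        } else {
            sdlog <- sqrt(log(1 + unitCV^2))
            meanlog <- log(unitMean) - sdlog^2 / 2
            units <- matrix(stats::rlnorm(nParticles * k, meanlog, sdlog),
                            nrow = nParticles, ncol = k)
        }
        if (dropout > 0)
            units <- units *
                matrix(stats::rbinom(nParticles * k, 1, 1 - dropout),
                       nrow = nParticles, ncol = k)
        rowSums(units)
    })
}

#' Read or write a burst scenario as YAML
#'
#' Serialises a [ScenarioConfig-class] to a YAML file (and back) so
#' simulation scenarios can be version-controlled and replayed from the
#' command line.
#'
#' @param path YAML file path.
#' @param config a [ScenarioConfig-class] (for writing).
#' @return \code{readScenario} returns a [ScenarioConfig-class];
#'   \code{writeScenario} returns \code{path} invisibly.
#' @export
readScenario <- function(path) {
    y <- yaml::read_yaml(path)
    species <- lapply(y$species, function(s)
        speciesSpec(
            name = s$name, eCenter = s$e_center, eWidth = s$e_width,
            fraction = s$fraction,
            brightness = if (is.null(s$brightness)) 100 else s$brightness,
            durationScale = if (is.null(s$duration_scale)) 1
                else s$duration_scale,
            isAggregate = isTRUE(s$is_aggregate)))
    getd <- function(nm, default) if (is.null(y[[nm]])) default else y[[nm]]
    scenarioConfig(
        species = species,
        nBursts = getd("n_bursts", 1000L),
        background3 = getd("background3", 0),
        background5 = getd("background5", 0),
        crosstalk = crosstalkModel(getd("crosstalk_alpha", 0.19)),
        noise = getd("noise", TRUE),
        aggBrightnessMult = getd("agg_brightness_mult", 10),
        aggDurationMult = getd("agg_duration_mult", 10),
        seed = getd("seed", 1L))
}

#' @rdname readScenario
#' @export
writeScenario <- function(config, path) {
    stopifnot(is(config, "ScenarioConfig"))
    y <- list(
        species = lapply(config@species, function(s) list(
            name = s@name, e_center = s@eCenter, e_width = s@eWidth,
            fraction = s@fraction, brightness = s@brightness,
            duration_scale = s@durationScale,
            is_aggregate = s@isAggregate)),
        n_bursts = config@nBursts,
        background3 = config@background3,
        background5 = config@background5,
        crosstalk_alpha = config@crosstalk@alpha,
        noise = config@noise,
        agg_brightness_mult = config@aggBrightnessMult,
        agg_duration_mult = config@aggDurationMult,
        seed = config@seed)
    yaml::write_yaml(y, path)
    invisible(path)
}
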