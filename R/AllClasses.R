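#' @import methods
NULL

#' Spectral crosstalk model for two-channel proximity ratios
#'
#' Holds the donor-to-acceptor leakage fraction \code{alpha} and the
#' complementary donor coefficient \code{beta} used in the proximity-ratio
#' formula \eqn{E_{PR} = (I_5 - \alpha I_3)/(I_5 + \beta I_3)}. The defaults
#' 0.19/0.81 correct for Cy3 emission bleeding into the Cy5 detection
#' channel on the instrument configuration the pipeline was designed for.
#' \code{beta} is always \code{1 - alpha} so the formula keeps its structure
#' under reconfiguration.
#'
#' @slot alpha numeric(1), donor-to-acceptor crosstalk fraction in [0, 1).
#' @slot beta numeric(1), complementary donor coefficient, \code{1 - alpha}.
#'
#' @seealso [crosstalkModel()], [computeEpr()]
#' @export
setClass("CrosstalkModel",
    representation(alpha = "numeric", beta = "numeric"),
    prototype(alpha = 0.19, beta = 0.81))

setValidity("CrosstalkModel", function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || length(object@beta) != 1L)
        msg <- c(msg, "'alpha' and 'beta' must be scalars")
    else {
        if (!is.finite(object@alpha) || object@alpha < 0 || object@alpha >= 1)
            msg <- c(msg, "'alpha' must lie in [0, 1)")
        if (abs(object@alpha + object@beta - 1) > 1e-12)
            msg <- c(msg, "'alpha' + 'beta' must equal 1 (within 1e-12)")
    }
    if (length(msg)) msg else TRUE
})

#' Constructor for a CrosstalkModel
#'
#' @param alpha donor-to-acceptor crosstalk fraction; \code{beta} is derived
#'   as \code{1 - alpha}.
#' @return A [CrosstalkModel-class] object.
#' @examples
#' crosstalkModel()        # instrument default, alpha = 0.19
#' crosstalkModel(0.05)    # a cleaner filter set
#' @export
crosstalkModel <- function(alpha = 0.19) {
    new("CrosstalkModel", alpha = alpha, beta = 1 - alpha)
}

#' One simulated molecular species in a burst scenario
#'
#' Describes a subpopulation of diffusing particles: its true
#' proximity-ratio center and between-particle spread, its mixing weight,
#' its mean brightness (total detected photons per burst) and mean burst
#' duration, and whether it is a slow/bright aggregate contaminant.
#'
#' @slot name character(1) label.
#' @slot eCenter numeric(1), true proximity-ratio center.
#' @slot eWidth numeric(1), between-particle SD of the true proximity ratio.
#' @slot fraction numeric(1), mixing weight in [0, 1].
#' @slot brightness numeric(1), mean total signal photons per burst.
#' @slot durationScale numeric(1), mean burst duration in ms.
#' @slot isAggregate logical(1), marks the aggregate contaminant species.
#'
#' @seealso [speciesSpec()], [scenarioConfig()]
#' @export
setClass("SpeciesSpec",
    representation(name = "character", eCenter = "numeric",
        eWidth = "numeric", fraction = "numeric", brightness = "numeric",
        durationScale = "numeric", isAggregate = "logical"))

setValidity("SpeciesSpec", function(object) {
    msg <- character()
    if (object@eWidth < 0) msg <- c(msg, "'eWidth' must be >= 0")
    if (object@fraction < 0 || object@fraction > 1)
        msg <- c(msg, "'fraction' must lie in [0, 1]")
    if (object@brightness <= 0) msg <- c(msg, "'brightness' must be > 0")
    if (object@durationScale <= 0)
        msg <- c(msg, "'durationScale' must be > 0")
    if (length(msg)) msg else TRUE
})

#' Constructor for a SpeciesSpec
#'
#' @param name species label, recorded per burst for ground-truth checks.
#' @param eCenter true proximity-ratio center of the species.
#' @param eWidth between-particle spread (SD) of the true proximity ratio.
#' @param fraction mixing weight; fractions in a scenario must sum to 1.
#' @param brightness mean total signal photons per burst.
#' @param durationScale mean burst duration (ms).
#' @param isAggregate if \code{TRUE} the scenario's aggregate brightness and
#'   duration multipliers are applied to this species at simulation time.
#' @return A [SpeciesSpec-class] object.
#' @export
speciesSpec <- function(name, eCenter, eWidth, fraction,
                        brightness = 100, durationScale = 1,
                        isAggregate = FALSE) {
    new("SpeciesSpec", name = name, eCenter = eCenter, eWidth = eWidth,
        fraction = fraction, brightness = brightness,
        durationScale = durationScale, isAggregate = isAggregate)
}

#' Full configuration of a simulated burst experiment
#'
#' Bundles the species list, the number of bursts, per-channel mean
#' background counts, the crosstalk model, the photon-noise switch, the
#' aggregate brightness/duration multipliers, and the seed. Identical
#' configurations (including seed) reproduce identical burst tables.
#'
#' @slot species list of [SpeciesSpec-class]; fractions must sum to 1.
#' @slot nBursts integer(1), number of bursts to generate.
#' @slot background3,background5 numeric(1), mean background counts per
#'   burst in the donor (I3) and acceptor (I5) channels.
#' @slot crosstalk a [CrosstalkModel-class].
#' @slot noise logical(1); if \code{TRUE} channel counts are Poisson draws
#'   around their expectations, otherwise expectations are returned exactly.
#' @slot aggBrightnessMult,aggDurationMult numeric(1), multipliers applied
#'   to brightness and duration of species flagged \code{isAggregate}.
#' @slot seed integer(1) RNG seed.
#'
#' @seealso [scenarioConfig()], [simulateBursts()]
#' @export
setClass("ScenarioConfig",
    representation(species = "list", nBursts = "integer",
        background3 = "numeric", background5 = "numeric",
        crosstalk = "CrosstalkModel", noise = "logical",
        aggBrightnessMult = "numeric", aggDurationMult = "numeric",
        seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    if (object@nBursts < 1L) msg <- c(msg, "'nBursts' must be >= 1")
    if (!length(object@species) ||
        !all(vapply(object@species, is, logical(1), "SpeciesSpec")))
        msg <- c(msg, "'species' must be a non-empty list of SpeciesSpec")
    else {
        fr <- vapply(object@species, slot, numeric(1), "fraction")
        if (abs(sum(fr) - 1) > 1e-9)
            msg <- c(msg, sprintf(
                "'species' fractions must sum to 1 (got %.12g)", sum(fr)))
        lo <- -object@crosstalk@alpha / object@crosstalk@beta
        for (sp in object@species) {
            if (!sp@isAggregate && (sp@eCenter < lo || sp@eCenter > 1))
                msg <- c(msg, sprintf(
                    "'eCenter' of species '%s' (%.4g) outside attainable proximity-ratio range [%.4g, 1]",
                    sp@name, sp@eCenter, lo))
        }
    }
    if (object@background3 < 0 || object@background5 < 0)
        msg <- c(msg, "'background3'/'background5' must be >= 0")
    if (object@aggBrightnessMult <= 0 || object@aggDurationMult <= 0)
        msg <- c(msg, "aggregate multipliers must be > 0")
    if (length(msg)) msg else TRUE
})

#' Constructor for a ScenarioConfig
#'
#' @param species list of [SpeciesSpec-class] objects.
#' @param nBursts number of bursts to simulate.
#' @param background3,background5 mean background counts per burst per
#'   channel.
#' @param crosstalk a [CrosstalkModel-class]; default \code{crosstalkModel()}.
#' @param noise logical, Poisson photon noise on/off.
#' @param aggBrightnessMult,aggDurationMult multipliers applied to species
#'   flagged as aggregates (default 10x brighter, 10x slower).
#' @param seed integer RNG seed.
#' @return A [ScenarioConfig-class] object.
#' @export
scenarioConfig <- function(species, nBursts, background3 = 0,
                           background5 = 0, crosstalk = crosstalkModel(),
                           noise = TRUE, aggBrightnessMult = 10,
                           aggDurationMult = 10, seed = 1L) {
    new("ScenarioConfig", species = species, nBursts = as.integer(nBursts),
        background3 = background3, background5 = background5,
        crosstalk = crosstalk, noise = noise,
        aggBrightnessMult = aggBrightnessMult,
        aggDurationMult = aggDurationMult, seed = as.integer(seed))
}

#' Aggregate-rejection filter configuration
#'
#' Two independent upper cuts (total intensity, burst duration) remove the
#' slow/bright aggregate signature, and a lower total-intensity floor
#' removes bursts too dim for a meaningful proximity ratio. Upper cuts may
#' be given as percentiles of the observed distribution (adapting to
#' brightness units) or as absolute values; absolute cuts make the filter
#' idempotent.
#'
#' @slot intensityPercentile,durationPercentile numeric(1) in (50, 100), or
#'   \code{NA} when an absolute cut is used.
#' @slot intensityAbs,durationAbs numeric(1) absolute cuts (counts, ms), or
#'   \code{NA} when a percentile cut is used.
#' @slot minTotal numeric(1), minimum I3 + I5 to retain a burst.
#'
#' @seealso [filterConfig()], [rejectAggregates()]
#' @export
setClass("FilterConfig",
    representation(intensityPercentile = "numeric", intensityAbs = "numeric",
        durationPercentile = "numeric", durationAbs = "numeric",
        minTotal = "numeric"))

setValidity("FilterConfig", function(object) {
    msg <- character()
    chkP <- function(p, nm) {
        if (!is.na(p) && (p <= 50 || p >= 100))
            sprintf("'%s' must lie in (50, 100)", nm) else character()
    }
    msg <- c(msg, chkP(object@intensityPercentile, "intensityPercentile"),
             chkP(object@durationPercentile, "durationPercentile"))
    if (!is.na(object@intensityAbs) && object@intensityAbs <= 0)
        msg <- c(msg, "'intensityAbs' must be > 0")
    if (!is.na(object@durationAbs) && object@durationAbs <= 0)
        msg <- c(msg, "'durationAbs' must be > 0")
    if (is.na(object@intensityAbs) == is.na(object@intensityPercentile))
        msg <- c(msg, "exactly one of 'intensityPercentile'/'intensityAbs' must be set")
    if (is.na(object@durationAbs) == is.na(object@durationPercentile))
        msg <- c(msg, "exactly one of 'durationPercentile'/'durationAbs' must be set")
    if (object@minTotal < 0) msg <- c(msg, "'minTotal' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Constructor for a FilterConfig
#'
#' @param intensityPercentile,durationPercentile upper percentile cuts
#'   (default 95th, sized so that a contaminant population of a few
#'   percent falls above the cut); set to \code{NA} to use absolute cuts
#'   instead.
#' @param intensityAbs,durationAbs absolute upper cuts in counts / ms.
#' @param minTotal minimum I3 + I5 (counts) to retain a burst; default 20.
#' @return A [FilterConfig-class] object.
#' @export
filterConfig <- function(intensityPercentile = 95, durationPercentile = 95,
                         intensityAbs = NA_real_, durationAbs = NA_real_,
                         minTotal = 20) {
    if (!is.na(intensityAbs)) intensityPercentile <- NA_real_
    if (!is.na(durationAbs)) durationPercentile <- NA_real_
    new("FilterConfig", intensityPercentile = intensityPercentile,
        intensityAbs = intensityAbs,
        durationPercentile = durationPercentile, durationAbs = durationAbs,
        minTotal = minTotal)
}

#' Binned relative-frequency profile of proximity ratios
#'
#' A histogram of per-particle proximity ratios on a fixed uniform grid,
#' normalised to sum 1, optionally carrying per-bin standard errors over
#' independent replicate experiments.
#'
#' @slot binCenters numeric, uniform bin-center grid.
#' @slot frequencies numeric, relative frequency per bin (sums to 1).
#' @slot sem numeric, per-bin SEM across replicates (zeros for a single
#'   replicate).
#' @slot nParticles integer(1), number of particles contributing.
#' @slot clipped integer(2), counts of values clipped into the lowest and
#'   highest bin.
#'
#' @seealso [buildProfile()], [aggregateReplicates()]
#' @export
setClass("EprProfile",
    representation(binCenters = "numeric", frequencies = "numeric",
        sem = "numeric", nParticles = "integer", clipped = "integer"))

setValidity("EprProfile", function(object) {
    msg <- character()
    nb <- length(object@binCenters)
    if (length(object@frequencies) != nb || length(object@sem) != nb)
        msg <- c(msg, "'frequencies' and 'sem' must match 'binCenters' length")
    if (nb >= 2) {
        d <- diff(object@binCenters)
        if (max(abs(d - d[1])) > 1e-9)
            msg <- c(msg, "bin grid must be uniform")
    }
    if (abs(sum(object@frequencies) - 1) > 1e-9)
        msg <- c(msg, "'frequencies' must sum to 1 (within 1e-9)")
    if (any(object@sem < 0)) msg <- c(msg, "'sem' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Gaussian mixture decomposition of a proximity-ratio distribution
#'
#' Result of maximum-likelihood mixture fitting: one row per Gaussian
#' component (weight, center, width), sorted by center, together with the
#' model-selection table across candidate component counts.
#'
#' @slot components data.frame with columns \code{weight}, \code{center},
#'   \code{width}, rows sorted ascending by center.
#' @slot nPoints integer(1), number of proximity ratios fitted.
#' @slot logLik numeric(1), maximised log-likelihood of the selected model.
#' @slot bic numeric(1), BIC of the selected model.
#' @slot bicTable data.frame with columns \code{k}, \code{logLik},
#'   \code{bic}, \code{icl} for every candidate component count.
#' @slot converged logical(1).
#' @slot seed integer(1), seed used for restarts.
#' @slot restarts data.frame of per-restart diagnostics (\code{k},
#'   \code{restart}, \code{logLik0}, \code{logLik}).
#'
#' @seealso [fitMixture()], [subpopulationFractions()], [compareConditions()]
#' @export
setClass("MixtureFit",
    representation(components = "data.frame", nPoints = "integer",
        logLik = "numeric", bic = "numeric", bicTable = "data.frame",
        converged = "logical", seed = "integer", restarts = "data.frame"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    cmp <- object@components
    need <- c("weight", "center", "width")
    if (!all(need %in% names(cmp)))
        msg <- c(msg, "components must have columns weight/center/width")
    else {
        if (abs(sum(cmp$weight) - 1) > 1e-9)
            msg <- c(msg, "component weights must sum to 1 (within 1e-9)")
        if (is.unsorted(cmp$center, strictly = FALSE))
            msg <- c(msg, "components must be sorted ascending by center")
        if (any(cmp$width <= 0)) msg <- c(msg, "widths must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' One-site binding fit of a fluorescence titration
#'
#' Parameters of the saturation isotherm
#' \eqn{I_{fl}(C) = I_m C / (K_d + C) + I_{fl0}} fitted by nonlinear least
#' squares: the dissociation constant \code{kd}, the amplitude \code{im},
#' the ligand-free intensity \code{ifl0}, and the standard error of
#' \code{kd} from the fit covariance.
#'
#' @slot kd numeric(1), dissociation constant (concentration units of the
#'   input table, conventionally uM).
#' @slot im numeric(1), maximal intensity increase (a.u.).
#' @slot ifl0 numeric(1), intensity at zero ligand (a.u.).
#' @slot seKd numeric(1), standard error of \code{kd}.
#' @slot residualNorm numeric(1), root sum of squared residuals.
#' @slot converged logical(1).
#'
#' @seealso [fitOneSite()]
#' @export
setClass("OneSiteFit",
    representation(kd = "numeric", im = "numeric", ifl0 = "numeric",
        seKd = "numeric", residualNorm = "numeric", converged = "logical"))

setValidity("OneSiteFit", function(object) {
    msg <- character()
    if (object@converged && (!is.finite(object@kd) || object@kd <= 0))
        msg <- c(msg, "'kd' must be strictly positive in a converged fit")
    if (object@converged && !is.finite(object@seKd))
        msg <- c(msg, "'seKd' must be finite in a converged fit")
    if (length(msg)) msg else TRUE
})

#' Half-saturation estimate from a binding series
#'
#' Hill-form interpolation \eqn{f(C) = 1/(1 + (C/c_{50})^h)} of the
#' fraction of free nucleosomes versus titrant concentration, with a
#' bootstrap confidence interval on the half-saturation point.
#'
#' @slot c50 numeric(1), concentration at which half the nucleosomes remain
#'   free (units of the input table, conventionally nM).
#' @slot hill numeric(1), fitted steepness.
#' @slot ci numeric(2), bootstrap percentile confidence interval for c50.
#' @slot nBoot integer(1), bootstrap draws used.
#' @slot extrapolated logical(1), \code{TRUE} when the data never cross
#'   fraction 0.5 and the estimate is an extrapolation.
#' @slot converged logical(1).
#'
#' @seealso [estimateHalfSaturation()]
#' @export
setClass("HalfSaturationFit",
    representation(c50 = "numeric", hill = "numeric", ci = "numeric",
        nBoot = "integer", extrapolated = "logical", converged = "logical"))

#' Single-complex acceptor-intensity profile of one gel band
#'
#' The raw per-particle Cy5 intensities measured within one band of a
#' native gel, plus their relative-frequency histogram on a grid shared
#' across the bands being compared.
#'
#' @slot samples numeric, per-particle acceptor intensities (all > 0).
#' @slot bandLabel character(1).
#' @slot breaks numeric, shared histogram break points.
#' @slot frequencies numeric, relative frequency per bin (sums to 1).
#'
#' @seealso [buildIntensityProfile()], [compareBands()]
#' @export
setClass("IntensityProfile",
    representation(samples = "numeric", bandLabel = "character",
        breaks = "numeric", frequencies = "numeric"))

setValidity("IntensityProfile", function(object) {
    msg <- character()
    if (any(object@samples <= 0))
        msg <- c(msg, "all intensity samples must be > 0")
    if (length(object@frequencies) &&
        abs(sum(object@frequencies) - 1) > 1e-9)
        msg <- c(msg, "'frequencies' must sum to 1 (within 1e-9)")
    if (length(object@breaks) &&
        length(object@frequencies) != length(object@breaks) - 1L)
        msg <- c(msg, "'frequencies' must have length(breaks) - 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CrosstalkModel", function(object) {
    cat(sprintf("CrosstalkModel: alpha = %.4g, beta = %.4g\n",
        object@alpha, object@beta))
})

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf("ScenarioConfig: %d bursts, %d species, noise %s, seed %d\n",
        object@nBursts, length(object@species),
        if (object@noise) "on" else "off", object@seed))
    for (sp in object@species)
        cat(sprintf("  %-14s eCenter %6.3f  width %5.3f  fraction %5.3f%s\n",
            sp@name, sp@eCenter, sp@eWidth, sp@fraction,
            if (sp@isAggregate) "  [aggregate]" else ""))
})

setMethod("show", "EprProfile", function(object) {
    cat(sprintf(
        "EprProfile: %d bins on [%.3g, %.3g], %d particles, %d clipped\n",
        length(object@binCenters), min(object@binCenters),
        max(object@binCenters), object@nParticles, sum(object@clipped)))
})

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf("MixtureFit: %d component(s), n = %d, logLik = %.2f, BIC = %.2f%s\n",
        nrow(object@components), object@nPoints, object@logLik, object@bic,
        if (object@converged) "" else "  [NOT CONVERGED]"))
    print(format(object@components, digits = 4), row.names = FALSE)
})

setMethod("show", "OneSiteFit", function(object) {
    cat(sprintf(
        "OneSiteFit: Kd = %.4g +/- %.2g, Im = %.4g, Ifl0 = %.4g%s\n",
        object@kd, object@seKd, object@im, object@ifl0,
        if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "HalfSaturationFit", function(object) {
    cat(sprintf(
        "HalfSaturationFit: c50 = %.4g [%.4g, %.4g], hill = %.3g%s%s\n",
        object@c50, object@ci[1], object@ci[2], object@hill,
        if (object@extrapolated) "  [extrapolated]" else "",
        if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "IntensityProfile", function(object) {
    cat(sprintf("IntensityProfile '%s': %d particles, median I = %.4g\n",
        object@bandLabel, length(object@samples),
        stats::median(object@samples)))
})
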