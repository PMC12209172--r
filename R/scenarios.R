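# Canonical study conditions: the nucleosome scenarios and ion
# concentration ladders used throughout the examples, tests and the
# reproduction script. Peak centers anchor to the measured subpopulation
# maxima (intact 0.8, open/histone-free 0.03, Zn-reorganized 0.4); the
# major/minor weights, widths, brightness and the 5% aggregate
# contamination are the generator's standing defaults.

#' Canonical nucleosome burst scenarios
#'
#' \code{npScenario} builds the boundary-labelled (N_P) nucleosome
#' scenario: a major intact subpopulation centered at proximity ratio 0.8
#' and a minor open/histone-free subpopulation at 0.03 (weights 0.7/0.3),
#' plus an optional bright/slow aggregate contaminant.
#' \code{znScenario} adds the Zn-dependent reorganized state at 0.4, the
#' signature of PARP2 + Zn-induced opening of the DNA gyres, with state
#' weights open/reorganized/intact = 0.25/0.45/0.30.
#'
#' @param nBursts bursts per experiment (default 3000, the scale of one
#'   measurement).
#' @param seed integer RNG seed.
#' @param aggregateFraction fraction of aggregate contaminant bursts
#'   (default 0.05); the named species' weights are scaled down to keep
#'   the total at 1.
#' @param noise Poisson photon noise on/off.
#' @param brightness mean signal photons per burst for regular species.
#' @return A [ScenarioConfig-class].
#' @examples
#' simulateBursts(npScenario(nBursts = 500, seed = 1))
#' @export
npScenario <- function(nBursts = 3000, seed = 1L, aggregateFraction = 0.05,
                       noise = TRUE, brightness = 100) {
    s <- 1 - aggregateFraction
    species <- list(
        speciesSpec("intact", 0.80, 0.07, 0.7 * s, brightness = brightness),
        speciesSpec("open", 0.03, 0.05, 0.3 * s, brightness = brightness))
    if (aggregateFraction > 0)
        species <- c(species, list(
            speciesSpec("aggregate", 0.80, 0.07, aggregateFraction,
                        brightness = brightness, isAggregate = TRUE)))
    scenarioConfig(species, nBursts = nBursts, noise = noise, seed = seed)
}

#' @rdname npScenario
#' @param reorganizedCenter center of the reorganized-state peak; 0.4 for
#'   boundary-region (N_P, N_m) labels, 0.5 for the distal (N_d) pair.
#' @export
znScenario <- function(nBursts = 3000, seed = 1L, aggregateFraction = 0.05,
                       noise = TRUE, brightness = 100,
                       reorganizedCenter = 0.4) {
    s <- 1 - aggregateFraction
    species <- list(
        speciesSpec("open", 0.03, 0.05, 0.25 * s, brightness = brightness),
        speciesSpec("reorganized", reorganizedCenter, 0.07, 0.45 * s,
                    brightness = brightness),
        speciesSpec("intact", 0.80, 0.07, 0.30 * s,
                    brightness = brightness))
    if (aggregateFraction > 0)
        species <- c(species, list(
            speciesSpec("aggregate", 0.80, 0.07, aggregateFraction,
                        brightness = brightness, isAggregate = TRUE)))
    scenarioConfig(species, nBursts = nBursts, noise = noise, seed = seed)
}

#' Ion titration concentration ladders
#'
#' Ten-point geometric ladders spanning the ranges used for the
#' tryptophan-fluorescence titrations of the WGR domain: Zn 0.2-308 uM,
#' Ca 8-5000 uM, Mg 15-5000 uM, each preceded by the zero-ligand point.
#'
#' @return Numeric vector of concentrations in uM (first element 0).
#' @examples
#' zincLadder()
#' @export
zincLadder <- function() {
    c(0, signif(exp(seq(log(0.2), log(308), length.out = 10)), 3))
}

#' @rdname zincLadder
#' @export
calciumLadder <- function() {
    c(0, signif(exp(seq(log(8), log(5000), length.out = 10)), 3))
}

#' @rdname zincLadder
#' @export
magnesiumLadder <- function() {
    c(0, signif(exp(seq(log(15), log(5000), length.out = 10)), 3))
}

#' Run the burst-processing pipeline on a burst table
#'
#' Convenience wrapper chaining aggregate rejection, crosstalk-corrected
#' proximity-ratio computation and mixture decomposition — the standard
#' route from a raw burst table to subpopulation parameters.
#'
#' @param bursts burst table.
#' @param filter a [FilterConfig-class].
#' @param crosstalk a [CrosstalkModel-class].
#' @param kCandidates,seed passed to [fitMixture()].
#' @param ... further arguments to [fitMixture()].
#' @return A list: \code{bursts} (filtered table), \code{epr} (proximity
#'   ratios), \code{fit} ([MixtureFit-class]).
#' @examples
#' res <- processBursts(simulateBursts(npScenario(seed = 5)), seed = 5)
#' components(res$fit)
#' @export
processBursts <- function(bursts, filter = filterConfig(),
                          crosstalk = crosstalkModel(), kCandidates = 1:3,
                          seed = 1L, ...) {
    kept <- rejectAggregates(bursts, filter)
    epr <- computeEpr(kept$I3, kept$I5, crosstalk)
    fit <- fitMixture(epr, kCandidates = kCandidates, seed = seed, ...)
    list(bursts = kept, epr = epr, fit = fit)
}
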