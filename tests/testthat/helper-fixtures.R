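# Shared fixtures: small noise-free scenarios and a direct arithmetic
# oracle for the crosstalk-corrected proximity ratio, kept independent of
# computeEpr().

eprOracle <- function(i3, i5, alpha = 0.19) {
    (i5 - alpha * i3) / (i5 + (1 - alpha) * i3)
}

singleSpeciesConfig <- function(eCenter, eWidth = 0, n = 500, seed = 1L,
                                noise = FALSE, brightness = 100) {
    scenarioConfig(
        species = list(speciesSpec("s", eCenter, eWidth, 1,
                                   brightness = brightness)),
        nBursts = n, noise = noise, seed = seed)
}

twoSpeciesConfig <- function(n = 5000, seed = 1L, noise = FALSE) {
    scenarioConfig(
        species = list(
            speciesSpec("intact", 0.8, 0.07, 0.7),
            speciesSpec("open", 0.03, 0.05, 0.3)),
        nBursts = n, noise = noise, seed = seed)
}

eprFromScenario <- function(config) {
    b <- rejectAggregates(simulateBursts(config))
    computeEpr(b$I3, b$I5, config@crosstalk)
}
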