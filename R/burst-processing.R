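# Burst-table processing: aggregate rejection, proximity-ratio profiles,
# replicate averaging.

checkBurstTable <- function(bursts) {
    need <- c("I3", "I5", "duration_ms")
    if (!is.data.frame(bursts) || !all(need %in% names(bursts)))
        stop("burst table must be a data.frame with columns I3, I5, duration_ms")
    invisible(bursts)
}

#' Reject aggregate and sub-threshold bursts
#'
#' Applies the mandatory aggregate-rejection rule: bursts whose total
#' intensity (I3 + I5) or duration is abnormally high — the signature of
#' slowly diffusing, very bright aggregates — are removed by two
#' independent upper cuts, and bursts below a minimum total intensity are
#' dropped as too dim to yield a meaningful proximity ratio. Upper cuts
#' are percentile-based by default (adapting to brightness units) or
#' absolute; with absolute cuts the filter is idempotent. A rejection
#' report (counts per criterion and the thresholds actually applied) is
#' attached as attribute \code{"rejection"}.
#'
#' @param bursts burst table (\code{data.frame} with \code{I3}, \code{I5},
#'   \code{duration_ms}).
#' @param cfg a [FilterConfig-class]; default \code{filterConfig()}.
#' @return The filtered burst table, with attribute \code{"rejection"}.
#' @examples
#' sc <- npScenario(nBursts = 2000, seed = 3)
#' kept <- rejectAggregates(simulateBursts(sc))
#' attr(kept, "rejection")
#' @export
rejectAggregates <- function(bursts, cfg = filterConfig()) {
    checkBurstTable(bursts)
    stopifnot(is(cfg, "FilterConfig"))
    validObject(cfg)
    total <- bursts$I3 + bursts$I5
    usesPercentile <- is.na(cfg@intensityAbs) || is.na(cfg@durationAbs)
    if (nrow(bursts) == 0L) {
        if (usesPercentile)
            stop("empty burst table: percentile limits are undefined; ",
                 "use absolute limits (intensityAbs/durationAbs)")
        out <- bursts
        attr(out, "rejection") <- list(
            nInput = 0L, nIntensity = 0L, nDuration = 0L, nDim = 0L,
            nKept = 0L, intensityCut = cfg@intensityAbs,
            durationCut = cfg@durationAbs)
        return(out)
    }
    intensityCut <- if (is.na(cfg@intensityAbs))
        stats::quantile(total, cfg@intensityPercentile / 100, names = FALSE)
    else cfg@intensityAbs
    durationCut <- if (is.na(cfg@durationAbs))
        stats::quantile(bursts$duration_ms, cfg@durationPercentile / 100,
                        names = FALSE)
    else cfg@durationAbs
    tooBright <- total > intensityCut
    tooSlow <- bursts$duration_ms > durationCut
    tooDim <- total < cfg@minTotal
    keep <- !(tooBright | tooSlow | tooDim)
    out <- bursts[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejection") <- list(
        nInput = nrow(bursts),
        nIntensity = sum(tooBright),
        nDuration = sum(tooSlow),
        nDim = sum(tooDim),
        nKept = sum(keep),
        intensityCut = intensityCut,
        durationCut = durationCut)
    out
}

#' Build a relative-frequency proximity-ratio profile
#'
#' Bins per-particle proximity ratios on a fixed uniform grid and
#' normalises to relative frequencies summing to 1. Values outside the
#' grid are clipped into the terminal bins (keeping normalisation honest)
#' and counted in the profile's \code{clipped} slot. Typical experiments
#' contribute 2000-5000 particles; a warning is issued below 2000 and
#' fewer than 100 values is an error.
#'
#' @param eprValues numeric vector of proximity ratios.
#' @param binWidth bin width on the proximity-ratio axis (default 0.05).
#' @param gridRange numeric(2), grid limits; the default
#'   \code{c(-0.25, 1.05)} covers the attainable range with margin.
#' @return An [EprProfile-class].
#' @examples
#' p <- buildProfile(rep(0.8, 3000))
#' binFrequencies(p)[which.max(binFrequencies(p))]   # single bin at 1
#' @export
buildProfile <- function(eprValues, binWidth = 0.05,
                         gridRange = c(-0.25, 1.05)) {
    if (binWidth <= 0) stop("'binWidth' must be > 0")
    if (length(eprValues) < 100)
        stop("at least 100 proximity-ratio values are required")
    if (length(eprValues) < 2000)
        warning("fewer than 2000 particles; profiles are typically built ",
                "from 2000-5000 particles per experiment")
    nb <- ceiling((gridRange[2] - gridRange[1]) / binWidth - 1e-9)
    breaks <- gridRange[1] + binWidth * (0:nb)
    clippedLow <- sum(eprValues < breaks[1])
    clippedHigh <- sum(eprValues > breaks[nb + 1])
    x <- pmin(pmax(eprValues, breaks[1]), breaks[nb + 1])
    counts <- tabulate(
        pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nb),
        nbins = nb)
    new("EprProfile",
        binCenters = breaks[-(nb + 1)] + binWidth / 2,
        frequencies = counts / sum(counts),
        sem = rep(0, nb),
        nParticles = length(eprValues),
        clipped = c(low = clippedLow, high = clippedHigh))
}

#' Average proximity-ratio profiles over replicate experiments
#'
#' Computes the per-bin mean relative frequency and its standard error
#' (SD over replicates divided by the square root of the replicate count)
#' across independent experiments measured on identical bin grids; the
#' mean profile is re-normalised to sum 1.
#'
#' @param profiles list of at least two [EprProfile-class] objects on
#'   identical grids.
#' @return An [EprProfile-class] whose \code{sem} slot holds the per-bin
#'   replicate SEM.
#' @export
aggregateReplicates <- function(profiles) {
    if (length(profiles) < 2)
        stop("at least 2 replicate profiles are required")
    if (!all(vapply(profiles, is, logical(1), "EprProfile")))
        stop("'profiles' must be a list of EprProfile objects")
    grid <- profiles[[1]]@binCenters
    for (p in profiles[-1])
        if (length(p@binCenters) != length(grid) ||
            max(abs(p@binCenters - grid)) > 1e-9)
            stop("replicate profiles are on different bin grids")
    freq <- do.call(rbind, lapply(profiles, slot, "frequencies"))
    k <- nrow(freq)
    m <- colMeans(freq)
    sem <- apply(freq, 2, stats::sd) / sqrt(k)
    new("EprProfile",
        binCenters = grid,
        frequencies = m / sum(m),
        sem = sem,
        nParticles = sum(vapply(profiles, slot, integer(1), "nParticles")),
        clipped = c(low = sum(vapply(profiles,
                        function(p) p@clipped[["low"]], integer(1))),
                    high = sum(vapply(profiles,
                        function(p) p@clipped[["high"]], integer(1)))))
}

#' Read or write burst tables and profiles as CSV
#'
#' Plain-text I/O helpers matching the column contracts used throughout
#' the package (\code{burst_id, I3, I5, duration_ms[, true_species,
#' true_e]} for burst tables; \code{bin_center, frequency, sem} for
#' profiles).
#'
#' @param path CSV file path.
#' @param bursts a burst table \code{data.frame}.
#' @param profile an [EprProfile-class].
#' @return Readers return the object; writers return \code{path}
#'   invisibly.
#' @export
readBurstTable <- function(path) {
    checkBurstTable(utils::read.csv(path))
}

#' @rdname readBurstTable
#' @export
writeBurstTable <- function(bursts, path) {
    utils::write.csv(checkBurstTable(bursts), path, row.names = FALSE)
    invisible(path)
}

#' @rdname readBurstTable
#' @export
writeProfile <- function(profile, path) {
    stopifnot(is(profile, "EprProfile"))
    utils::write.csv(
        data.frame(bin_center = profile@binCenters,
                   frequency = profile@frequencies,
                   sem = profile@sem),
        path, row.names = FALSE)
    invisible(path)
}
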