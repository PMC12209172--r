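# Gaussian mixture decomposition of proximity-ratio distributions.
# Maximum-likelihood EM with multiple random restarts per candidate
# component count, BIC model selection, a width floor against spike
# components, a weight floor with refitting, and an identifiability gap
# that prevents two components from collapsing onto the same center.

mixLogLik <- function(x, w, mu, sigma) {
    dens <- vapply(seq_along(w),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    dens <- if (is.matrix(dens)) rowSums(dens) else sum(dens)
    sum(log(pmax(dens, .Machine$double.xmin)))
}

# One EM run from a given initialisation. Returns parameters plus the
# initial and final log-likelihood (EM guarantees monotone improvement).
emRun <- function(x, w, mu, sigma, widthFloor, maxIter = 500, tol = 1e-8) {
    n <- length(x)
    k <- length(w)
    ll0 <- mixLogLik(x, w, mu, sigma)
    ll <- ll0
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        # E-step: responsibilities
        d <- vapply(seq_len(k),
                    function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                    numeric(n))
        if (!is.matrix(d)) d <- matrix(d, nrow = n)
        tot <- pmax(rowSums(d), .Machine$double.xmin)
        r <- d / tot
        # M-step
        nk <- colSums(r)
        nk <- pmax(nk, 1e-12)
        w <- nk / n
        mu <- colSums(r * x) / nk
        sigma <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
        sigma <- pmax(sigma, widthFloor)
        llNew <- mixLogLik(x, w, mu, sigma)
        if (is.finite(llNew) && llNew - ll < tol * (abs(ll) + 1)) {
            ll <- max(llNew, ll)
            converged <- TRUE
            break
        }
        ll <- llNew
    }
    list(w = w, mu = mu, sigma = sigma, logLik = ll, logLik0 = ll0,
         converged = converged)
}

fitOneK <- function(x, k, nRestarts, widthFloor, maxIter, tol) {
    n <- length(x)
    sdx <- stats::sd(x)
    best <- NULL
    diag <- vector("list", nRestarts)
    for (r in seq_len(nRestarts)) {
        mu0 <- if (r == 1L)
            stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
        else sample(x, k)
        sigma0 <- rep(max(sdx / k, widthFloor), k)
        w0 <- rep(1 / k, k)
        fit <- emRun(x, w0, mu0, sigma0, widthFloor, maxIter, tol)
        diag[[r]] <- data.frame(k = k, restart = r,
                                logLik0 = fit$logLik0, logLik = fit$logLik)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    best$restarts <- do.call(rbind, diag)
    best
}

# Mean classification entropy of the fitted responsibilities; the ICL
# criterion penalises solutions whose components overlap so much that
# particles cannot be assigned to one of them.
classEntropy <- function(x, w, mu, sigma) {
    k <- length(w)
    if (k == 1L) return(0)
    d <- vapply(seq_len(k),
                function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                numeric(length(x)))
    tot <- pmax(rowSums(d), .Machine$double.xmin)
    r <- d / tot
    -sum(r * log(pmax(r, .Machine$double.xmin)))
}

#' Fit a Gaussian mixture to per-particle proximity ratios
#'
#' Decomposes a proximity-ratio distribution into normal subpopulations —
#' the intact, reorganized and open nucleosome states appear as distinct
#' components. For each candidate component count an EM fit with multiple
#' random restarts is run; the component count is selected by ICL
#' (BIC plus twice the classification entropy), which asks components to
#' be separated subpopulations rather than mere density-shape terms. That
#' matters here because per-burst shot noise scales with photon count, so
#' each physical state is a variance mixture with heavier-than-Gaussian
#' tails that plain BIC tends to split into two overlapping Gaussians;
#' ICL keeps one component per resolvable state (plain BIC selection is
#' available via \code{criterion = "bic"}). Components falling below the
#' weight floor are pruned and the model refit with fewer components, and
#' a model whose centers sit closer than the identifiability gap is
#' replaced by the next smaller one. Fitting operates on the raw
#' per-particle values (not the binned profile), which carry more
#' information than the histogram.
#'
#' @param eprValues numeric vector of proximity ratios (>= 200 values).
#' @param kCandidates candidate component counts, subset of 1..4
#'   (default \code{1:3}).
#' @param seed integer seed for the random restarts.
#' @param nRestarts EM restarts per candidate count (default 10).
#' @param widthFloor minimum component SD (default 0.01).
#' @param weightFloor minimum component weight; lighter components are
#'   pruned and the model refit (default 0.02).
#' @param minSeparation identifiability gap: minimum distance between
#'   component centers in the selected model (default 0.05).
#' @param criterion model-selection criterion, \code{"icl"} (default) or
#'   \code{"bic"}.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A [MixtureFit-class]; components sorted ascending by center.
#' @examples
#' sc <- npScenario(nBursts = 3000, seed = 11)
#' b <- rejectAggregates(simulateBursts(sc))
#' fit <- fitMixture(computeEpr(b$I3, b$I5), seed = 11)
#' components(fit)
#' @export
fitMixture <- function(eprValues, kCandidates = 1:3, seed = 1L,
                       nRestarts = 10, widthFloor = 0.01,
                       weightFloor = 0.02, minSeparation = 0.05,
                       criterion = c("icl", "bic"),
                       maxIter = 1000, tol = 1e-8) {
    criterion <- match.arg(criterion)
    x <- as.numeric(eprValues)
    if (length(x) < 200)
        stop("at least 200 proximity-ratio values are required")
    if (!all(kCandidates %in% 1:4))
        stop("'kCandidates' must be a subset of 1..4")
    kCandidates <- sort(unique(as.integer(kCandidates)))
    n <- length(x)

    # Degenerate input: all values identical
    if (stats::sd(x) == 0) {
        cmp <- data.frame(weight = 1, center = x[1], width = widthFloor)
        ll <- mixLogLik(x, 1, x[1], widthFloor)
        return(new("MixtureFit", components = cmp, nPoints = n,
                   logLik = ll, bic = -2 * ll + 2 * log(n),
                   bicTable = data.frame(k = 1L, logLik = ll,
                                         bic = -2 * ll + 2 * log(n),
                                         icl = -2 * ll + 2 * log(n)),
                   converged = TRUE, seed = as.integer(seed),
                   restarts = data.frame(k = integer(), restart = integer(),
                                         logLik0 = numeric(),
                                         logLik = numeric())))
    }

    withSeed(seed, {
        fits <- lapply(kCandidates, function(k)
            fitOneK(x, k, nRestarts, widthFloor, maxIter, tol))
        bicOf <- function(f) {
            p <- 3 * length(f$w) - 1
            -2 * f$logLik + p * log(n)
        }
        bicTab <- data.frame(
            k = kCandidates,
            logLik = vapply(fits, `[[`, numeric(1), "logLik"),
            bic = vapply(fits, bicOf, numeric(1)))
        bicTab$icl <- bicTab$bic + 2 * vapply(fits, function(f)
            classEntropy(x, f$w, f$mu, f$sigma), numeric(1))
        allRestarts <- do.call(rbind, lapply(fits, `[[`, "restarts"))

        refitReduced <- function(fit, drop) {
            keep <- setdiff(seq_along(fit$w), drop)
            if (!length(keep)) keep <- which.max(fit$w)
            emRun(x, fit$w[keep] / sum(fit$w[keep]), fit$mu[keep],
                  fit$sigma[keep], widthFloor, maxIter, tol)
        }
        finalize <- function(fit) {
            # prune under-weight components, then enforce the center gap
            repeat {
                light <- which(fit$w < weightFloor)
                if (!length(light) || length(fit$w) == 1L) break
                fit <- refitReduced(fit, which.min(fit$w))
            }
            repeat {
                if (length(fit$w) == 1L) break
                o <- order(fit$mu)
                gaps <- diff(fit$mu[o])
                if (all(gaps >= minSeparation)) break
                j <- o[which.min(gaps) + 1L]  # drop the lighter of the pair
                pair <- o[which.min(gaps) + c(0L, 1L)]
                fit <- refitReduced(fit, pair[which.min(fit$w[pair])])
            }
            fit
        }

        ord <- order(if (criterion == "icl") bicTab$icl else bicTab$bic)
        chosen <- NULL
        for (i in ord) {
            cand <- finalize(fits[[i]])
            if (!is.null(cand)) { chosen <- cand; break }
        }
        if (is.null(chosen) || !is.finite(chosen$logLik))
            stop("mixture fit failed to converge across all restarts; ",
                 "BIC table: ",
                 paste(sprintf("k=%d bic=%.1f", bicTab$k, bicTab$bic),
                       collapse = ", "))
        o <- order(chosen$mu)
        cmp <- data.frame(weight = chosen$w[o] / sum(chosen$w),
                          center = chosen$mu[o], width = chosen$sigma[o])
        rownames(cmp) <- NULL
        p <- 3 * nrow(cmp) - 1
        new("MixtureFit", components = cmp, nPoints = n,
            logLik = chosen$logLik,
            bic = -2 * chosen$logLik + p * log(n),
            bicTable = bicTab, converged = isTRUE(chosen$converged),
            seed = as.integer(seed), restarts = allRestarts)
    })
}

#' Default proximity-ratio windows for nucleosome structural states
#'
#' Windows bracketing the reported subpopulation centers: the open /
#' histone-free state near 0.03, the reorganized state near 0.4-0.5, and
#' the intact state near 0.8. Windows are half-open \code{[lo, hi)}.
#'
#' @return Named list of numeric(2) intervals.
#' @export
defaultStateWindows <- function() {
    list(open = c(-0.25, 0.2),
         reorganized = c(0.2, 0.6),
         intact = c(0.6, 1.06))
}

#' Map mixture components to structural-state fractions
#'
#' Assigns each Gaussian component to the structural state whose
#' proximity-ratio window contains its center (components outside every
#' window go to \code{"other"}) and sums the component weights per state.
#'
#' @param fit a [MixtureFit-class].
#' @param stateWindows named list of half-open \code{[lo, hi)} intervals;
#'   must be pairwise disjoint. Default [defaultStateWindows()].
#' @return Named numeric vector of state fractions (including
#'   \code{"other"}), summing to 1.
#' @export
subpopulationFractions <- function(fit, stateWindows = defaultStateWindows()) {
    stopifnot(is(fit, "MixtureFit"))
    wn <- names(stateWindows)
    if (is.null(wn) || any(wn == ""))
        stop("'stateWindows' must be a named list")
    iv <- do.call(rbind, stateWindows)
    if (any(iv[, 2] <= iv[, 1]))
        stop("each state window must have lo < hi")
    o <- order(iv[, 1])
    if (any(iv[o, 2][-length(o)] > iv[o, 1][-1] + 1e-12))
        stop("state windows must be disjoint")
    cmp <- fit@components
    out <- stats::setNames(numeric(length(wn) + 1), c(wn, "other"))
    for (i in seq_len(nrow(cmp))) {
        hit <- which(cmp$center[i] >= iv[, 1] & cmp$center[i] < iv[, 2])
        state <- if (length(hit)) wn[hit[1]] else "other"
        out[state] <- out[state] + cmp$weight[i]
    }
    out / sum(out)
}

#' Compare mixture fits between two conditions
#'
#' Matches components of two fits by nearest centers (within
#' \code{matchTol}) and reports per-pair center shifts and weight
#' changes; components of the second fit with no partner are reported as
#' appeared peaks (e.g. the reorganized state emerging under Zn), and
#' unmatched components of the first fit as disappeared.
#'
#' @param fitA,fitB converged [MixtureFit-class] objects (reference and
#'   comparison condition).
#' @param matchTol maximum center distance for matching (default 0.1).
#' @return A list with data.frames \code{matched} (centerA, centerB,
#'   shift, weightA, weightB, weightChange), \code{appeared} and
#'   \code{disappeared} (weight, center, width).
#' @export
compareConditions <- function(fitA, fitB, matchTol = 0.1) {
    stopifnot(is(fitA, "MixtureFit"), is(fitB, "MixtureFit"))
    if (!fitA@converged || !fitB@converged)
        stop("both fits must have converged")
    ca <- fitA@components
    cb <- fitB@components
    usedA <- logical(nrow(ca))
    matched <- list()
    appearedIdx <- integer()
    for (i in seq_len(nrow(cb))) {
        d <- abs(ca$center - cb$center[i])
        d[usedA] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= matchTol) {
            usedA[j] <- TRUE
            matched[[length(matched) + 1L]] <- data.frame(
                centerA = ca$center[j], centerB = cb$center[i],
                shift = cb$center[i] - ca$center[j],
                weightA = ca$weight[j], weightB = cb$weight[i],
                weightChange = cb$weight[i] - ca$weight[j])
        } else {
            appearedIdx <- c(appearedIdx, i)
        }
    }
    emptyCmp <- data.frame(weight = numeric(), center = numeric(),
                           width = numeric())
    list(
        matched = if (length(matched)) do.call(rbind, matched) else
            data.frame(centerA = numeric(), centerB = numeric(),
                       shift = numeric(), weightA = numeric(),
                       weightB = numeric(), weightChange = numeric()),
        appeared = if (length(appearedIdx))
            cb[appearedIdx, , drop = FALSE] else emptyCmp,
        disappeared = if (any(!usedA))
            ca[!usedA, , drop = FALSE] else emptyCmp)
}

#' Serialize a mixture fit to JSON
#'
#' @param fit a [MixtureFit-class].
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeMixtureFit <- function(fit, path) {
    stopifnot(is(fit, "MixtureFit"))
    jsonlite::write_json(
        list(components = fit@components, n_points = fit@nPoints,
             log_lik = fit@logLik, bic = fit@bic,
             bic_table = fit@bicTable, converged = fit@converged,
             seed = fit@seed),
        path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    invisible(path)
}
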