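#' Binomial log-likelihood of a pair's rejection count
#'
#' Log of the binomial probability of `delta` rejecting SNPs out of `n`
#' compared SNPs at rate `tau`.  Stable at array scale (n in the hundreds of
#' thousands) and at the boundary `tau = 0`, where the log-likelihood is 0
#' for `delta = 0` and `-Inf` otherwise.
#'
#' @param delta,n rejection count and number of compared SNPs (vectorized).
#' @param tau binomial rate.
#' @return log-likelihood(s).
#' @export
pairLogLikelihood <- function(delta, n, tau) {
    stats::dbinom(delta, size = n, prob = tau, log = TRUE)
}

.asPairTable <- function(pairs) {
    if (is(pairs, "DataFrame") || is.data.frame(pairs)) {
        stopifnot(all(c("delta", "n_eff") %in% colnames(pairs)))
        return(DataFrame(pairs))
    }
    stop("pairs must be a RejectionSet, DataFrame or data.frame with ",
         "columns delta and n_eff")
}

#' E-step: posterior membership in the error component
#'
#' Responsibilities are computed from the log-likelihood difference,
#' `1 / (1 + exp(lnL(tauR) - lnL(tauG)))`, never by exponentiating raw
#' likelihoods (which underflow at array scale).  The binomial coefficient
#' cancels in the ratio.
#'
#' As printed, the posterior ratio does not weight by the mixing proportion;
#' `gamma` may optionally be supplied to use the prior-weighted variant
#' `gamma*L_g / (gamma*L_g + (1-gamma)*L_r)`.  At the component separations
#' this method targets the two give identical assignments.
#'
#' @param pairs pair table with columns `delta` and `n_eff`.
#' @param tauG,tauR the two component rates, `tauG != tauR`.
#' @param gamma optional mixing proportion for the prior-weighted variant.
#' @return numeric vector of responsibilities in `[0, 1]`.
#' @export
eStep <- function(pairs, tauG, tauR, gamma = NULL) {
    pairs <- .asPairTable(pairs)
    diff <- pairLogLikelihood(pairs$delta, pairs$n_eff, tauR) -
        pairLogLikelihood(pairs$delta, pairs$n_eff, tauG)
    if (!is.null(gamma))
        diff <- diff + log(1 - gamma) - log(gamma)
    diff[is.nan(diff)] <- 0   # both components impossible: split evenly
    stats::plogis(-diff)
}

#' M-step: update component rates and mixing proportion
#'
#' Implements the estimator in which each pair's expectation is its
#' responsibility scaled by its rejection count `delta`, so the rate updates
#' are `tau' = sum(w * delta/n_eff) / sum(w)` with `w = resp * delta` for
#' the error component and `w = (1 - resp) * delta` for the rejection
#' component.  Pairs with `delta = 0` therefore carry no weight in the rate
#' updates; the error-component rate is driven by pairs with at least one
#' rejection.  The mixing proportion is the normalized responsibility sum,
#' `gamma' = mean(resp)`.
#'
#' @param pairs pair table with columns `delta` and `n_eff`.
#' @param resp responsibilities from [eStep()].
#' @return list with `tauG`, `tauR`, `gamma` and logical `collapsed`
#'   (a component received zero total weight; its rate is returned as `NA`).
#' @export
mStep <- function(pairs, resp) {
    pairs <- .asPairTable(pairs)
    rate <- pairs$delta / pairs$n_eff
    wG <- resp * pairs$delta
    wR <- (1 - resp) * pairs$delta
    sG <- sum(wG); sR <- sum(wR)
    list(tauG = if (sG > 0) sum(wG * rate) / sG else NA_real_,
         tauR = if (sR > 0) sum(wR * rate) / sR else NA_real_,
         gamma = mean(resp),
         collapsed = (sG == 0 || sR == 0))
}

## observed-data log-likelihood, Eq.-(3)-style product over pairs in log form
.obsLogLik <- function(pairs, tauG, tauR, gamma) {
    a <- log(gamma) + pairLogLikelihood(pairs$delta, pairs$n_eff, tauG)
    b <- log(1 - gamma) + pairLogLikelihood(pairs$delta, pairs$n_eff, tauR)
    m <- pmax(a, b)
    ll <- m + log1p(exp(pmin(a, b) - m))
    ll[is.infinite(m) & m < 0] <- -Inf
    sum(ll)
}

#' Data-driven initial values for the mixture rates
#'
#' Returns starting rates near the two modes of the observed `tau`
#' distribution: the 5th and 60th percentiles, falling back to the means of
#' a largest-gap two-cluster split when the percentiles coincide.  EM on
#' this mixture converges only from initial values near the peaks, so
#' automatic near-mode initialization replaces the manual histogram
#' inspection the procedure otherwise requires.
#'
#' @param pairs pair table with columns `delta` and `n_eff`.
#' @return numeric of length 2: ordered, distinct initial rates.
#' @export
defaultInit <- function(pairs) {
    pairs <- .asPairTable(pairs)
    tau <- pairs$delta / pairs$n_eff
    tau <- tau[!is.na(tau)]
    if (length(tau) < 2 || diff(range(tau)) < .Machine$double.eps)
        stop("rejection rates show a single mode; cannot initialize ",
             "a two-component fit")
    q <- unname(stats::quantile(tau, c(0.05, 0.60)))
    if (q[2] - q[1] < 1e-12)
        q <- .gapInit(tau)
    sort(q)
}

## means of the two sides of the largest gap in sorted tau
.gapInit <- function(tau) {
    s <- sort(tau)
    gap <- which.max(diff(s))
    c(mean(s[seq_len(gap)]), mean(s[(gap + 1L):length(s)]))
}

#' Fit the two-component binomial mixture by EM
#'
#' Alternates [eStep()] and [mStep()] until the maximum relative change in
#' `(tauG, tauR, gamma)` falls below `tol`.  Component order `tauG <= tauR`
#' is enforced after every M-step to prevent label switching, so
#' initializing with swapped rates yields the same ordered fit.  By default
#' three starting points are tried (the percentile initializer, a
#' largest-gap split, and an interquartile pair) and the fit with the
#' highest observed-data log-likelihood is returned, guarding against the
#' non-convergence seen from initial values far from the modes.
#'
#' Pairs are assigned to the error component (a true first-degree
#' relationship) when their responsibility exceeds `threshold`; a tie at
#' exactly the threshold is conservatively not assigned.
#'
#' @param pairs a [RejectionSet-class] (typically filtered to one
#'   relationship group) or any table with columns `delta` and `n_eff`.
#' @param init optional length-2 numeric of initial rates; overrides the
#'   multi-start search.
#' @param maxIter,tol iteration cap and relative-change tolerance.
#' @param threshold assignment threshold on the responsibility.
#' @param gammaWeighted use the prior-weighted E-step variant (see
#'   [eStep()]).
#' @return a [MixtureFit-class].
#' @examples
#' set.seed(1)
#' pairs <- data.frame(delta = c(rbinom(60, 5e4, 7e-4),
#'                               rbinom(140, 5e4, 1e-2)),
#'                     n_eff = 5e4)
#' fit <- fitMixture(pairs)
#' c(tauG(fit), tauR(fit), mixingProportion(fit))
#' @export
fitMixture <- function(pairs, init = NULL, maxIter = 1000, tol = 1e-8,
                       threshold = 0.5, gammaWeighted = FALSE) {
    pairs <- .asPairTable(pairs)
    if (nrow(pairs) < 2)
        stop("need at least two pairs")
    if (all(pairs$delta == 0)) {
        warning("all pairs have zero rejections: degenerate ",
                "single-component fit")
        n <- nrow(pairs)
        return(new("MixtureFit", tauG = 0, tauR = 0, gamma = 1,
                   responsibilities = rep(1, n), assignments = rep(TRUE, n),
                   threshold = threshold,
                   trace = matrix(numeric(0), ncol = 4,
                                  dimnames = list(NULL, c("tauG", "tauR",
                                                          "gamma", "logLik"))),
                   converged = TRUE, collapsed = TRUE, nIter = 0L,
                   logLik = 0, pairs = pairs))
    }
    if (is.null(init)) {
        tau <- pairs$delta / pairs$n_eff
        starts <- list(defaultInit(pairs), .gapInit(tau[!is.na(tau)]),
                       unname(stats::quantile(tau, c(0.25, 0.75),
                                              na.rm = TRUE)))
        starts <- Filter(function(s) diff(sort(s)) > 1e-12, starts)
        if (!length(starts))
            starts <- list(defaultInit(pairs))
    } else {
        stopifnot(length(init) == 2, init[1] != init[2])
        starts <- list(sort(init))
    }
    fits <- lapply(starts, .emRun, pairs = pairs, maxIter = maxIter,
                   tol = tol, gammaWeighted = gammaWeighted)
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logLik"))]]
    resp <- eStep(pairs, best$tauG, best$tauR,
                  gamma = if (gammaWeighted) best$gamma else NULL)
    new("MixtureFit", tauG = best$tauG, tauR = best$tauR, gamma = best$gamma,
        responsibilities = resp, assignments = resp > threshold,
        threshold = threshold, trace = best$trace, converged = best$converged,
        collapsed = best$collapsed, nIter = nrow(best$trace),
        logLik = best$logLik, pairs = pairs)
}

.emRun <- function(start, pairs, maxIter, tol, gammaWeighted) {
    tauG <- min(start); tauR <- max(start); gamma <- 0.5
    trace <- matrix(NA_real_, nrow = 0, ncol = 4,
                    dimnames = list(NULL, c("tauG", "tauR", "gamma",
                                            "logLik")))
    converged <- FALSE; collapsed <- FALSE
    for (it in seq_len(maxIter)) {
        resp <- eStep(pairs, tauG, tauR,
                      gamma = if (gammaWeighted) gamma else NULL)
        m <- mStep(pairs, resp)
        newG <- if (is.na(m$tauG)) tauG else m$tauG
        newR <- if (is.na(m$tauR)) tauR else m$tauR
        newGamma <- m$gamma
        if (newG > newR) {   # keep components ordered
            tmp <- newG; newG <- newR; newR <- tmp
            newGamma <- 1 - newGamma
        }
        ll <- .obsLogLik(pairs, newG, newR, newGamma)
        trace <- rbind(trace, c(newG, newR, newGamma, ll))
        delta <- max(abs(c(newG - tauG, newR - tauR, newGamma - gamma)) /
                     pmax(abs(c(tauG, tauR, gamma)), 1e-12))
        tauG <- newG; tauR <- newR; gamma <- newGamma
        if (m$collapsed) {
            collapsed <- TRUE
            converged <- TRUE
            break
        }
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("EM did not converge in ", maxIter, " iterations")
    list(tauG = tauG, tauR = tauR, gamma = gamma, trace = trace,
         converged = converged, collapsed = collapsed,
         logLik = trace[nrow(trace), "logLik"])
}

#' @rdname MixtureFit-class
#' @export
setMethod("tauG", "MixtureFit", function(object) object@tauG)

#' @rdname MixtureFit-class
#' @export
setMethod("tauR", "MixtureFit", function(object) object@tauR)

#' @rdname MixtureFit-class
#' @export
setMethod("mixingProportion", "MixtureFit", function(object) object@gamma)

#' @rdname MixtureFit-class
#' @export
setMethod("responsibilities", "MixtureFit",
          function(object) object@responsibilities)

#' @rdname MixtureFit-class
#' @export
setMethod("assignments", "MixtureFit", function(object) object@assignments)

setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit over", nrow(object@pairs), "pairs\n")
    cat(sprintf("  tauG = %.6g  tauR = %.6g  gamma = %.4f\n",
                object@tauG, object@tauR, object@gamma))
    cat(sprintf("  assigned true first-degree: %d / %d\n",
                sum(object@assignments), length(object@assignments)))
    cat(sprintf("  %s in %d iteration(s)%s; logLik = %.4f\n",
                if (object@converged) "converged" else "NOT converged",
                object@nIter,
                if (object@collapsed) " [collapsed]" else "",
                object@logLik))
    invisible(NULL)
})
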