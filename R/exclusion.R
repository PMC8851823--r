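## Indicator matrices shared by the pairwise statistics.  Missing calls are
## dropped per pair: they contribute to neither delta nor n_eff.
.indicators <- function(d) {
    out <- lapply(c(0L, 1L, 2L), function(v) {
        m <- d == v
        m[is.na(m)] <- FALSE
        storage.mode(m) <- "double"
        m
    })
    nm <- !is.na(d)
    storage.mode(nm) <- "double"
    names(out) <- c("hom0", "het", "hom2")
    out$nonmiss <- nm
    out
}

.pairGroup <- function(roleI, roleJ) {
    key <- paste(pmin(roleI, roleJ), pmax(roleI, roleJ))
    lut <- c("DAM OFFSPRING" = "DAM_OFF", "OFFSPRING SIRE" = "SIRE_OFF",
             "OFFSPRING OFFSPRING" = "OFF_OFF", "DAM DAM" = "DAM_DAM",
             "SIRE SIRE" = "SIRE_SIRE", "DAM SIRE" = "SIRE_DAM")
    unname(lut[key])
}

#' Opposing-homozygote counts and rejection rates for all sample pairs
#'
#' For every unordered pair of samples, counts the SNPs at which the two are
#' homozygous for alternative alleles (`delta`), the SNPs at which both
#' calls are non-missing (`n_eff`), and the rate of rejection of a
#' first-degree relationship `tau = delta / n_eff`.  Under strict Mendelian
#' inheritance a true parent-offspring pair cannot be homozygous for
#' alternative alleles, so for such pairs `tau` departs from zero only
#' through genotyping error.  Pairs are labelled by relationship group from
#' the sample roles (`DAM_OFF`, `SIRE_OFF`, `OFF_OFF`, `DAM_DAM`,
#' `SIRE_SIRE`, `SIRE_DAM`).
#'
#' The computation is matrix-formulated (three cross-products over 0/1
#' indicator matrices), not a per-pair loop, and scales to hundreds of
#' samples at array densities.
#'
#' @param g a [GenotypeMatrix-class] with at least two samples.
#' @return a [RejectionSet-class].
#' @export
pairwiseRejections <- function(g) {
    d <- dosages(g)
    if (ncol(d) < 2)
        stop("need at least two samples")
    ind <- .indicators(d)
    cross <- crossprod(ind$hom0, ind$hom2)
    delta <- cross + t(cross)
    neff <- crossprod(ind$nonmiss)
    ut <- which(upper.tri(delta), arr.ind = TRUE)
    ids <- colnames(d)
    roles <- sampleRoles(g)
    dd <- delta[ut]
    nn <- neff[ut]
    res <- DataFrame(sample_i = ids[ut[, 1L]], sample_j = ids[ut[, 2L]],
                     group = .pairGroup(roles[ut[, 1L]], roles[ut[, 2L]]),
                     delta = as.integer(dd), n_eff = as.integer(nn),
                     tau = ifelse(nn > 0, dd / nn, NA_real_))
    res <- new("RejectionSet", res)
    metadata(res)$n_samples <- ncol(d)
    res
}

#' Number of pairwise relationships among ni individuals
#'
#' @param ni number of individuals, at least 2.
#' @return `ni * (ni - 1) / 2`.
#' @examples
#' pairCount(300)  # 44850 pairwise tests among 300 individuals
#' @export
pairCount <- function(ni) {
    if (any(ni < 2))
        stop("ni must be at least 2")
    ni * (ni - 1) / 2
}

#' Binomial probability of an opposing-homozygote count
#'
#' Probability of observing `delta` rejecting SNPs out of `nSnp` when the
#' per-SNP rejection rate is `tau`; computed in log space and exponentiated
#' on demand.
#'
#' @param tau per-SNP rejection rate in `[0, 1]`.
#' @param nSnp number of SNPs compared.
#' @param delta opposing-homozygote count, `0 <= delta <= nSnp`.
#' @param log return the log probability.
#' @return the (log) binomial probability mass.
#' @export
binomialRejectionProb <- function(tau, nSnp, delta, log = FALSE) {
    stopifnot(all(tau >= 0 & tau <= 1), all(delta >= 0 & delta <= nSnp))
    stats::dbinom(delta, size = nSnp, prob = tau, log = log)
}

#' Detect duplicated samples by genotype concordance
#'
#' Two samples of the same individual agree at almost every SNP, differing
#' only through two independent error draws; their concordance sits far
#' above that of any pair of distinct individuals (a parent-offspring pair
#' shares at most ~90% of calls at array MAF spectra).  Pairs with
#' concordance over non-missing calls at or above the threshold are flagged
#' as the same individual.
#'
#' The default threshold 0.98 tolerates per-genotype error rates up to about
#' 1% on both copies (expected discordance ~ 2e) while keeping a wide margin
#' above non-duplicate pairs.
#'
#' @param g a [GenotypeMatrix-class].
#' @param threshold concordance threshold in `(0.9, 1]`.
#' @return `data.frame` with `sample_i`, `sample_j`, `n_eff`, `concordance`
#'   for flagged pairs (zero rows if none).
#' @export
detectDuplicates <- function(g, threshold = 0.98) {
    stopifnot(threshold > 0.9, threshold <= 1)
    d <- dosages(g)
    ind <- .indicators(d)
    agree <- crossprod(ind$hom0) + crossprod(ind$het) + crossprod(ind$hom2)
    neff <- crossprod(ind$nonmiss)
    conc <- ifelse(neff > 0, agree / neff, 0)
    ut <- which(upper.tri(conc) & conc >= threshold, arr.ind = TRUE)
    ids <- colnames(d)
    data.frame(sample_i = ids[ut[, 1L]], sample_j = ids[ut[, 2L]],
               n_eff = as.integer(neff[ut]), concordance = conc[ut],
               row.names = NULL)
}

#' Histogram of rejection rates per relationship group
#'
#' Tabulates the distribution of `tau` within each relationship group; the
#' multimodality of these histograms is what motivates the two-component
#' mixture fit.
#'
#' @param rejections a [RejectionSet-class] (or compatible data frame).
#' @param bins number of equal-width bins over `[0, max(tau)]`, or a numeric
#'   vector of breakpoints.
#' @return `data.frame` with `group`, `bin_low`, `bin_high`, `count`.
#' @export
tauHistogram <- function(rejections, bins = 50) {
    tau <- rejections$tau
    grp <- as.character(rejections$group)
    keep <- !is.na(tau)
    tau <- tau[keep]; grp <- grp[keep]
    if (length(bins) == 1L) {
        hi <- max(tau, 1e-12)
        breaks <- seq(0, hi, length.out = bins + 1L)
    } else breaks <- sort(bins)
    out <- lapply(split(tau, grp), function(x) {
        cut_idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE)
        tabulate(cut_idx, nbins = length(breaks) - 1L)
    })
    data.frame(group = rep(names(out), each = length(breaks) - 1L),
               bin_low = rep(utils::head(breaks, -1L), length(out)),
               bin_high = rep(breaks[-1L], length(out)),
               count = unlist(out, use.names = FALSE), row.names = NULL)
}
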