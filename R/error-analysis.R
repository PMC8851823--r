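#' Per-SNP counts of rejections among verified parent-offspring pairs
#'
#' Once true parent-offspring relationships are verified by the mixture fit,
#' every opposing-homozygote site in such a pair is a Mendelian
#' inconsistency, i.e. at least one genotyping error.  Counting, per SNP,
#' the number of verified pairs it rejects localizes recurrent errors: the
#' total over SNPs equals the total over pairs of their `delta` restricted
#' to verified pairs.
#'
#' @param g a [GenotypeMatrix-class].
#' @param verifiedPairs two-column `data.frame` (or matrix) of sample
#'   identifiers, one verified pair per row.
#' @param failingThreshold threshold forwarded to [flagFailingSnps()].
#' @return `data.frame` with `snp_id`, `chrom`, `pos`, `maf`,
#'   `n_rejections`, `failing`.
#' @export
snpRejectionCounts <- function(g, verifiedPairs, failingThreshold = 5) {
    d <- dosages(g)
    vp <- as.matrix(verifiedPairs)[, 1:2, drop = FALSE]
    i <- match(vp[, 1L], colnames(d))
    j <- match(vp[, 2L], colnames(d))
    if (anyNA(i) || anyNA(j))
        stop("verified pairs reference unknown samples")
    ind <- .indicators(d)
    counts <- if (length(i)) {
        rowSums(ind$hom0[, i, drop = FALSE] * ind$hom2[, j, drop = FALSE] +
                ind$hom2[, i, drop = FALSE] * ind$hom0[, j, drop = FALSE])
    } else rep(0, nrow(d))
    info <- snpInfo(g)
    prof <- data.frame(snp_id = info$snp_id, chrom = info$chrom,
                       pos = info$pos, maf = snpSummaries(g)$maf,
                       n_rejections = as.integer(counts),
                       failing = NA, row.names = NULL)
    flagFailingSnps(prof, threshold = failingThreshold)
}

#' Flag SNPs that reject many verified relationships
#'
#' A SNP rejecting `threshold` or more verified parent-offspring pairs is
#' considered failing: its calls are inconsistent with autosomal Mendelian
#' inheritance in multiple pairs, pointing at recurrent miscalling,
#' mismapping or structural variation rather than isolated errors.  Failing
#' SNPs are flagged, never auto-removed.
#'
#' @param profiles output of [snpRejectionCounts()].
#' @param threshold minimum rejection count, default 5.
#' @return `profiles` with the `failing` column set to
#'   `n_rejections >= threshold`.
#' @export
flagFailingSnps <- function(profiles, threshold = 5) {
    stopifnot(threshold >= 1)
    profiles$failing <- profiles$n_rejections >= threshold
    profiles
}

#' Probability that a single miscall creates opposing homozygotes
#'
#' For a true parent-offspring pair at a biallelic locus with allele
#' frequency `p` (parents in Hardy-Weinberg proportions, Mendelian
#' transmission), a genotyping error is only detectable through the
#' exclusion statistic when it turns the pair into opposing homozygotes.
#' This function returns the first-order detection factor `c(p)` such that
#' the per-SNP rejection rate in true pairs is `e * c(p)` for a small
#' per-genotype error rate `e`:
#'
#' * `"genotype_uniform"` (a miscalled genotype becomes one of the other two
#'   genotypes with equal probability): `c(p) = p^2 + (1-p)^2`, since a
#'   rejection needs the partner to be homozygous and the miscall to land on
#'   the opposite homozygote.
#' * `"allele_flip"` (each allele miscalled independently at rate `e/2`):
#'   `c(p) = p (1-p)`, since only heterozygote-to-homozygote single flips
#'   can create a rejection at first order.
#'
#' As `p` approaches 0 or 1 under the default model `c(p)` approaches 1:
#' at low MAF the rate of rejection approaches the genotyping error itself,
#' because true rejections essentially cannot occur when one homozygote
#' class is vanishingly rare.  Both forms are symmetric in `p` and `1-p`.
#'
#' @param p allele frequency, strictly between 0 and 1 (vectorized).
#' @param errorModel miscall model.
#' @return detection factor(s) in `(0, 1)`.
#' @export
rejectionDetectionProb <- function(p, errorModel = c("genotype_uniform",
                                                     "allele_flip")) {
    errorModel <- match.arg(errorModel)
    if (any(p <= 0 | p >= 1))
        stop("degenerate locus: allele frequency must be in (0, 1)")
    switch(errorModel,
           genotype_uniform = p^2 + (1 - p)^2,
           allele_flip = p * (1 - p))
}

#' Allele-frequency-adjusted genotyping-error rate
#'
#' The fitted error-component rate `tauG` is a lower bound on the
#' per-genotype error rate: miscalls are observed only when they create
#' opposing homozygotes.  Averaging the detection factor `c(p)` over the
#' SNP panel's allele-frequency spectrum and dividing recovers the
#' underlying rate, `e = tauG / mean(c(p))`.
#'
#' SNPs with undefined or zero MAF are excluded from the average (at a
#' monomorphic locus the detection factor is degenerate).
#'
#' @param tauG fitted error-component rate (see [fitMixture()]).
#' @param summaries per-SNP summaries from [snpSummaries()], or any table
#'   with a `maf` column.
#' @param errorModel miscall model, see [rejectionDetectionProb()].
#' @return an [ErrorEstimate-class].
#' @export
adjustedErrorRate <- function(tauG, summaries,
                              errorModel = c("genotype_uniform",
                                             "allele_flip")) {
    errorModel <- match.arg(errorModel)
    stopifnot(tauG >= 0)
    maf <- summaries$maf
    maf <- maf[!is.na(maf) & maf > 0 & maf < 1]
    if (!length(maf))
        stop("no SNPs with defined polymorphic MAF")
    cf <- mean(rejectionDetectionProb(maf, errorModel))
    if (cf <= 0)
        stop("mean detection factor is zero; adjustment undefined")
    new("ErrorEstimate", tauGLowerBound = tauG, detectionFactor = cf,
        adjustedError = tauG / cf, errorModel = errorModel)
}

setMethod("show", "ErrorEstimate", function(object) {
    cat("ErrorEstimate (", object@errorModel, ")\n", sep = "")
    cat(sprintf("  tauG lower bound : %.6g\n", object@tauGLowerBound))
    cat(sprintf("  detection factor : %.4f\n", object@detectionFactor))
    cat(sprintf("  adjusted error   : %.6g (%.3g%%)\n",
                object@adjustedError, 100 * object@adjustedError))
    invisible(NULL)
})

#' Low-MAF representation among rejecting SNPs
#'
#' Low-MAF markers rarely produce true rejections (one homozygote class is
#' nearly absent), so SNPs that reject verified relationships are depleted
#' of low-MAF markers relative to the panel.  This reports the proportion
#' of SNPs below the MAF cut overall and among rejecting SNPs.
#'
#' @param profiles output of [snpRejectionCounts()]; SNPs with
#'   `n_rejections >= 1` form the rejecting set.
#' @param summaries per-SNP summaries from [snpSummaries()].
#' @param mafCut MAF threshold, default 0.05.
#' @return `data.frame` with rows `all_snps` and `rejecting_snps` and
#'   columns `n_low_maf`, `n_total`, `proportion` (NA when the set is
#'   empty).
#' @export
mafStratifiedReport <- function(profiles, summaries, mafCut = 0.05) {
    lowAll <- sum(summaries$maf < mafCut, na.rm = TRUE)
    nAll <- sum(!is.na(summaries$maf))
    rej <- profiles[profiles$n_rejections >= 1, , drop = FALSE]
    lowRej <- sum(rej$maf < mafCut, na.rm = TRUE)
    nRej <- nrow(rej)
    data.frame(set = c("all_snps", "rejecting_snps"),
               n_low_maf = c(lowAll, lowRej),
               n_total = c(nAll, nRej),
               proportion = c(if (nAll) lowAll / nAll else NA_real_,
                              if (nRej) lowRej / nRej else NA_real_),
               row.names = NULL)
}

#' Opposing-homozygote probability between full sibs
#'
#' Full sibs can be homozygous for alternative alleles only at loci where
#' both parents are heterozygous; there, each offspring is independently
#' AA with probability 1/4 and aa with probability 1/4, so the pair is
#' opposing with probability `2 * 1/4 * 1/4 = 1/8`.  With `nSim = 0` the
#' value is computed by exhaustive enumeration of the 16 equally likely
#' gamete combinations; with `nSim > 0` it is a Monte-Carlo estimate over
#' that many simulated loci.
#'
#' @param nSim number of simulated loci (0 for exact enumeration).
#' @return the probability (exactly 0.125 for `nSim = 0`).
#' @export
fullSibOpposingProb <- function(nSim = 0) {
    if (nSim == 0) {
        gam <- expand.grid(a1 = 0:1, a2 = 0:1, b1 = 0:1, b2 = 0:1)
        g1 <- gam$a1 + gam$a2
        g2 <- gam$b1 + gam$b2
        return(mean((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)))
    }
    g1 <- stats::rbinom(nSim, 2, 0.5)
    g2 <- stats::rbinom(nSim, 2, 0.5)
    mean((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0))
}
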