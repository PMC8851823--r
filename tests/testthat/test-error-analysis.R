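test_that("per-SNP rejection counts match a brute-force recount", {
    sim <- simulateCross(simConfig(nSires = 3, nDams = 6, nOffspring = 15,
                                   nSnps = 1500, errorRate = 0.01,
                                   missingRate = 0.02, nDuplicateDams = 0,
                                   nFailingSnps = 0,
                                   unrelatedParentFraction = 0, seed = 40))
    g <- sim$genotypes
    ped <- sim$truth$pedigree
    verified <- rbind(data.frame(a = ped$sire, b = ped$offspring),
                      data.frame(a = ped$dam, b = ped$offspring))
    prof <- snpRejectionCounts(g, verified)
    d <- dosages(g)
    brute <- rep(0L, nrow(d))
    for (k in seq_len(nrow(verified))) {
        x <- d[, verified$a[k]]; y <- d[, verified$b[k]]
        opp <- (x == 0 & y == 2) | (x == 2 & y == 0)
        opp[is.na(opp)] <- FALSE
        brute <- brute + opp
    }
    expect_equal(prof$n_rejections, as.integer(brute))

    # conservation: per-SNP totals equal per-pair delta totals
    rej <- as.data.frame(pairwiseRejections(g))
    key <- paste(rej$sample_i, rej$sample_j)
    vKey1 <- paste(verified$a, verified$b)
    vKey2 <- paste(verified$b, verified$a)
    deltaSum <- sum(rej$delta[key %in% c(vKey1, vKey2)])
    expect_equal(sum(prof$n_rejections), deltaSum)
})

test_that("zero-error simulations produce zero rejection counts", {
    sim <- simulateCross(simConfig(nSires = 2, nDams = 4, nOffspring = 8,
                                   nSnps = 800, errorRate = 0,
                                   missingRate = 0, nDuplicateDams = 0,
                                   nFailingSnps = 0,
                                   unrelatedParentFraction = 0, seed = 41))
    ped <- sim$truth$pedigree
    verified <- rbind(data.frame(a = ped$sire, b = ped$offspring),
                      data.frame(a = ped$dam, b = ped$offspring))
    prof <- snpRejectionCounts(sim$genotypes, verified)
    expect_true(all(prof$n_rejections == 0L))
    expect_false(any(prof$failing))
})

test_that("a SNP miscalled across offspring accumulates rejections", {
    sim <- simulateCross(simConfig(nSires = 2, nDams = 4, nOffspring = 20,
                                   nSnps = 500, errorRate = 0,
                                   missingRate = 0, nDuplicateDams = 0,
                                   nFailingSnps = 0,
                                   unrelatedParentFraction = 0, seed = 42))
    d <- dosages(sim$genotypes)
    ped <- sim$truth$pedigree
    # force every offspring homozygous-reference at one SNP
    snp <- "snp00007"
    d[snp, ped$offspring] <- 2L
    g2 <- GenotypeMatrix(d, roles = sampleRoles(sim$genotypes))
    verified <- rbind(data.frame(a = ped$sire, b = ped$offspring),
                      data.frame(a = ped$dam, b = ped$offspring))
    prof <- snpRejectionCounts(g2, verified)
    expected <- sum(d[snp, verified$a] == 0)   # parents opposing-homozygous
    got <- prof$n_rejections[prof$snp_id == snp]
    expect_equal(got, expected)
    expect_true(expected > 0)
})

test_that("failing flag applies the at-least-threshold rule", {
    prof <- data.frame(snp_id = c("a", "b", "c"), maf = 0.2,
                       n_rejections = c(4L, 5L, 9L), failing = NA)
    out <- flagFailingSnps(prof, threshold = 5)
    expect_identical(out$failing, c(FALSE, TRUE, TRUE))
    expect_error(flagFailingSnps(prof, threshold = 0))
})

test_that("detection factor matches exhaustive enumeration of miscalls", {
    for (model in c("genotype_uniform", "allele_flip")) {
        for (p in c(0.1, 0.3, 0.5, 0.77)) {
            # enumeration at a tiny error rate isolates the first-order term
            e <- 1e-6
            cEnum <- enumOpposingProb(p, e, model) / e
            expect_equal(rejectionDetectionProb(p, model), cEnum,
                         tolerance = 1e-4)
            # allele-label symmetry
            expect_equal(rejectionDetectionProb(p, model),
                         rejectionDetectionProb(1 - p, model))
        }
    }
    expect_error(rejectionDetectionProb(0), "degenerate")
    expect_error(rejectionDetectionProb(1), "degenerate")
})

test_that("Monte-Carlo rejection rate matches e * c(p) at p = 0.5", {
    set.seed(44)
    n <- 2e5; p <- 0.5; e <- 0.01
    trio <- simTrioLocus(n, p)
    gp <- applyGenotypeUniformError(trio$parent, e)
    go <- applyGenotypeUniformError(trio$offspring, e)
    rate <- mean((gp == 0 & go == 2) | (gp == 2 & go == 0))
    # c(p) already sums the two single-miscall routes (parent or offspring)
    expected <- e * rejectionDetectionProb(p)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(rate - expected), 3 * se + 2 * e^2)
})

test_that("error adjustment divides by the mean detection factor", {
    s <- data.frame(maf = c(0.1, 0.3, NA, 0, 0.5))
    est <- adjustedErrorRate(2e-3, s)
    cf <- mean(rejectionDetectionProb(c(0.1, 0.3, 0.5)))
    expect_equal(est@detectionFactor, cf)
    expect_equal(est@adjustedError, 2e-3 / cf)
    expect_gte(est@adjustedError, est@tauGLowerBound)
    est0 <- adjustedErrorRate(0, s)
    expect_equal(est0@adjustedError, 0)
    expect_error(adjustedErrorRate(1e-3, data.frame(maf = NA_real_)),
                 "no SNPs")
})

test_that("MAF-spectrum shifts move the adjusted error as each model implies", {
    lowSpec <- data.frame(maf = rep(0.02, 100))
    midSpec <- data.frame(maf = rep(0.4, 100))
    # genotype-uniform: low MAF -> rejection rate approaches the error
    # itself, so the same tauG implies a SMALLER underlying error
    expect_lt(adjustedErrorRate(1e-3, lowSpec)@adjustedError,
              adjustedErrorRate(1e-3, midSpec)@adjustedError)
    # allele-flip: low MAF hides miscalls, so the implied error grows
    expect_gt(adjustedErrorRate(1e-3, lowSpec, "allele_flip")@adjustedError,
              adjustedErrorRate(1e-3, midSpec, "allele_flip")@adjustedError)
})

test_that("low-MAF SNPs are depleted among rejecting SNPs", {
    # under allele-flip miscalls a rejection needs a true heterozygote,
    # which is rare at low MAF -- the depletion the field observes
    sim <- simulateCross(simConfig(nSires = 6, nDams = 12, nOffspring = 60,
                                   nSnps = 6000,
                                   sireFreq = uniformFreqs(0.005, 0.95),
                                   damFreq = uniformFreqs(0.005, 0.95),
                                   errorRate = 0.02,
                                   errorModel = "allele_flip",
                                   missingRate = 0,
                                   nDuplicateDams = 0, nFailingSnps = 0,
                                   unrelatedParentFraction = 0, seed = 45))
    ped <- sim$truth$pedigree
    verified <- rbind(data.frame(a = ped$sire, b = ped$offspring),
                      data.frame(a = ped$dam, b = ped$offspring))
    prof <- snpRejectionCounts(sim$genotypes, verified)
    s <- snpSummaries(sim$genotypes)
    rep_ <- mafStratifiedReport(prof, s, mafCut = 0.05)
    expect_lt(rep_$proportion[rep_$set == "rejecting_snps"],
              rep_$proportion[rep_$set == "all_snps"])
})

test_that("stratified proportions reproduce worked examples", {
    summaries <- data.frame(maf = c(rep(0.01, 122615),
                                    rep(0.25, 546220 - 122615)))
    profiles <- data.frame(snp_id = seq_len(7744),
                           maf = c(rep(0.01, 165), rep(0.25, 7744 - 165)),
                           n_rejections = 1L, failing = FALSE)
    rep_ <- mafStratifiedReport(profiles, summaries)
    expect_equal(round(rep_$proportion[rep_$set == "all_snps"], 3), 0.224)
    expect_equal(round(rep_$proportion[rep_$set == "rejecting_snps"], 3),
                 0.021)
    empty <- mafStratifiedReport(
        data.frame(snp_id = "x", maf = 0.2, n_rejections = 0L,
                   failing = FALSE), summaries)
    expect_true(is.na(empty$proportion[empty$set == "rejecting_snps"]))
})

test_that("full-sib opposing probability is exactly one eighth", {
    expect_identical(fullSibOpposingProb(), 0.125)
    set.seed(46)
    mc <- fullSibOpposingProb(nSim = 2e5)
    expect_lt(abs(mc - 0.125), 3 * sqrt(0.125 * 0.875 / 2e5))
})
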