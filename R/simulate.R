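#' Allele-frequency specifications for the simulator
#'
#' `uniformFreqs()` draws per-SNP reference-allele frequencies uniformly on
#' an interval ("common pool" regime, for null testing and error-rate
#' round-trips).  `divergentFreqs()` draws Beta-distributed frequencies
#' skewed towards 1 (`side = "high"`) or 0 (`side = "low"`); giving the two
#' breeds opposite skews reproduces the large sire-dam rejection rates of a
#' crossbred design, where the parental breeds differ genetically.
#'
#' @param min,max interval for the uniform spec.
#' @param side which way the Beta skews.
#' @param shape1,shape2 Beta parameters of the skewed side.
#' @return a list understood by the `sireFreq`/`damFreq` slots of
#'   [SimConfig-class].
#' @export
uniformFreqs <- function(min = 0.05, max = 0.95)
    list(dist = "uniform", min = min, max = max)

#' @rdname uniformFreqs
#' @export
divergentFreqs <- function(side = c("high", "low"), shape1 = 3,
                           shape2 = 0.8) {
    side <- match.arg(side)
    if (side == "high") list(dist = "beta", shape1 = shape1, shape2 = shape2)
    else list(dist = "beta", shape1 = shape2, shape2 = shape1)
}

.drawFreqs <- function(spec, n) {
    f <- switch(spec$dist,
                uniform = stats::runif(n, spec$min, spec$max),
                beta = stats::rbeta(n, spec$shape1, spec$shape2),
                stop("unknown frequency spec: ", spec$dist))
    # keep loci polymorphic so every SNP is informative in expectation
    pmin(pmax(f, 0.001), 0.999)
}

#' Build a simulator configuration
#'
#' Defaults emulate a two-breed terminal cross genotyped on a dense array
#' (9 candidate sires, 55 dams, 214 crossbred offspring, 50,000 SNPs,
#' divergent breed frequencies, per-genotype miscall rate 0.00588, 1%
#' missingness, 2 duplicated dam samples, 20 failing SNPs, and 60% of true
#' parents not among the genotyped candidates).  See [SimConfig-class] for
#' slot semantics.
#'
#' @param nSires,nDams,nOffspring,nSnps design dimensions.
#' @param sireFreq,damFreq frequency specs (see [uniformFreqs()]).
#' @param errorRate,errorModel per-genotype miscall rate and model.
#' @param missingRate per-call missingness.
#' @param nDuplicateDams duplicated dam samples.
#' @param nFailingSnps,failureMode systematically failing SNPs.
#' @param unrelatedParentFraction probability a true parent is ungenotyped.
#' @param seed integer seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nSires = 9, nDams = 55, nOffspring = 214,
                      nSnps = 50000,
                      sireFreq = divergentFreqs("high"),
                      damFreq = divergentFreqs("low"),
                      errorRate = 0.00588,
                      errorModel = c("genotype_uniform", "allele_flip"),
                      missingRate = 0.01, nDuplicateDams = 2,
                      nFailingSnps = 20,
                      failureMode = c("force_homozygote", "random_call",
                                      "swap_local"),
                      unrelatedParentFraction = 0.6, seed = 1) {
    new("SimConfig", nSires = as.integer(nSires), nDams = as.integer(nDams),
        nOffspring = as.integer(nOffspring), nSnps = as.integer(nSnps),
        sireFreq = sireFreq, damFreq = damFreq, errorRate = errorRate,
        errorModel = match.arg(errorModel), missingRate = missingRate,
        nDuplicateDams = as.integer(nDuplicateDams),
        nFailingSnps = as.integer(nFailingSnps),
        failureMode = match.arg(failureMode),
        unrelatedParentFraction = unrelatedParentFraction,
        seed = as.integer(seed))
}

## per-genotype miscalls; returns list(calls, errIdx) with errIdx the
## linear indices whose call was changed
.injectErrors <- function(calls, e, model) {
    if (e == 0)
        return(list(calls = calls, errIdx = integer(0)))
    n <- length(calls)
    if (model == "genotype_uniform") {
        hit <- which(stats::runif(n) < e)
        shift <- sample(1:2, length(hit), replace = TRUE)
        calls[hit] <- (calls[hit] + shift) %% 3L
        errIdx <- hit
    } else {    # allele_flip: each allele flips independently at e/2
        refToAlt <- stats::rbinom(n, calls, e / 2)
        altToRef <- stats::rbinom(n, 2L - calls, e / 2)
        newCalls <- calls - refToAlt + altToRef
        errIdx <- which(newCalls != calls)
        calls <- as.integer(newCalls)
    }
    list(calls = calls, errIdx = errIdx)
}

.mendelianChild <- function(sireG, damG, nSnps) {
    fromSire <- as.integer(stats::runif(nSnps) < sireG / 2)
    fromDam <- as.integer(stats::runif(nSnps) < damG / 2)
    fromSire + fromDam
}

#' Simulate a crossbred pedigree with known truth
#'
#' Generates genotyped candidate sires and dams from Hardy-Weinberg
#' proportions at breed-specific allele frequencies, mates them (or
#' ungenotyped animals from the same breed pools) under strict Mendelian
#' transmission to produce crossbred offspring, then layers on per-genotype
#' miscalls, missing calls, duplicated samples (re-corruptions of the
#' pre-error genotype with fresh error draws) and systematically failing
#' SNPs.  With the same seed the output is identical across runs.
#'
#' @param config a [SimConfig-class], e.g. from [simConfig()].
#' @return list with elements
#'   \describe{
#'     \item{genotypes}{a [GenotypeMatrix-class] with roles set;}
#'     \item{truth}{a list with `pedigree` (per offspring: true sire/dam id
#'       and whether each is genotyped), `duplicates` (`sample`,
#'       `duplicate_of`), `errorMask` (SNP/sample indices of injected
#'       miscalls), `failingSnps` (ids), `fullSibs` and `halfSibs` (pair
#'       tables among offspring), and the drawn `sireFreqs`/`damFreqs`.}
#'   }
#' @examples
#' sim <- simulateCross(simConfig(nSires = 3, nDams = 6, nOffspring = 10,
#'                                nSnps = 200, errorRate = 0, seed = 42))
#' sim$genotypes
#' @export
simulateCross <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    ns <- config@nSnps
    pS <- .drawFreqs(config@sireFreq, ns)
    pD <- .drawFreqs(config@damFreq, ns)

    # genotyped candidates plus same-size pools of ungenotyped animals
    mkIds <- function(prefix, n)
        if (n > 0) paste0(prefix, seq_len(n)) else character(0)
    sireIds <- mkIds("S", config@nSires)
    damIds <- mkIds("D", config@nDams)
    offIds <- mkIds("O", config@nOffspring)
    extraSires <- paste0("US", seq_len(max(config@nSires, 1L)))
    extraDams <- paste0("UD", seq_len(max(config@nDams, 1L)))

    drawHWE <- function(p, ids) {
        m <- matrix(stats::rbinom(ns * length(ids), 2L, p), nrow = ns,
                    dimnames = list(NULL, ids))
        storage.mode(m) <- "integer"
        m
    }
    sireG <- drawHWE(pS, c(sireIds, extraSires))
    damG <- drawHWE(pD, c(damIds, extraDams))

    f <- config@unrelatedParentFraction
    sireGenotyped <- stats::runif(config@nOffspring) >= f
    damGenotyped <- stats::runif(config@nOffspring) >= f
    trueSire <- ifelse(sireGenotyped,
                       sample(sireIds, config@nOffspring, replace = TRUE),
                       sample(extraSires, config@nOffspring, replace = TRUE))
    trueDam <- ifelse(damGenotyped,
                      sample(damIds, config@nOffspring, replace = TRUE),
                      sample(extraDams, config@nOffspring, replace = TRUE))

    offG <- matrix(0L, nrow = ns, ncol = config@nOffspring,
                   dimnames = list(NULL, offIds))
    for (k in seq_len(config@nOffspring))
        offG[, k] <- .mendelianChild(sireG[, trueSire[k]],
                                     damG[, trueDam[k]], ns)

    clean <- cbind(sireG[, sireIds, drop = FALSE],
                   damG[, damIds, drop = FALSE], offG)
    inj <- .injectErrors(as.integer(clean), config@errorRate,
                         config@errorModel)
    calls <- matrix(inj$calls, nrow = ns, dimnames = dimnames(clean))
    errIdx <- inj$errIdx

    # duplicates: fresh corruption of the pre-error dam genotypes
    dupTable <- data.frame(sample = character(0), duplicate_of = character(0))
    if (config@nDuplicateDams > 0) {
        dupOf <- sample(damIds, config@nDuplicateDams)
        dupIds <- paste0(dupOf, "rep")
        dupClean <- clean[, dupOf, drop = FALSE]
        dupInj <- .injectErrors(as.integer(dupClean), config@errorRate,
                                config@errorModel)
        dupCalls <- matrix(dupInj$calls, nrow = ns,
                           dimnames = list(NULL, dupIds))
        calls <- cbind(calls, dupCalls)
        errIdx <- c(errIdx, dupInj$errIdx + length(clean))
        dupTable <- data.frame(sample = dupIds, duplicate_of = dupOf)
    }

    # systematically failing SNPs (assay-level corruption, all samples)
    failing <- sort(sample.int(ns, config@nFailingSnps))
    for (s in failing) {
        row <- calls[s, ]
        if (config@failureMode == "force_homozygote") {
            het <- which(row == 1L)
            row[het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
        } else if (config@failureMode == "random_call") {
            row <- sample(0:2, length(row), replace = TRUE)
        } else {    # swap_local: sample labels scrambled at this SNP
            row <- row[sample.int(length(row))]
        }
        calls[s, ] <- as.integer(row)
    }

    if (config@missingRate > 0)
        calls[stats::runif(length(calls)) < config@missingRate] <- NA_integer_

    snpIds <- sprintf("snp%05d", seq_len(ns))
    rownames(calls) <- snpIds
    chrom <- as.character(1L + (seq_len(ns) - 1L) %% 18L)  # autosomes
    roles <- c(rep("SIRE", config@nSires), rep("DAM", config@nDams),
               rep("OFFSPRING", config@nOffspring),
               rep("DAM", nrow(dupTable)))
    g <- GenotypeMatrix(calls,
                        snpMap = data.frame(snp_id = snpIds, chrom = chrom,
                                            pos = seq_len(ns)),
                        roles = stats::setNames(roles, colnames(calls)))

    ped <- data.frame(offspring = offIds, sire = trueSire, dam = trueDam,
                      sire_genotyped = sireGenotyped,
                      dam_genotyped = damGenotyped, row.names = NULL)
    sibPairs <- function(sameSire, sameDam) {
        hit <- which(upper.tri(sameSire) & sameSire & sameDam, arr.ind = TRUE)
        data.frame(sample_i = offIds[hit[, 1L]], sample_j = offIds[hit[, 2L]],
                   row.names = NULL)
    }
    sameS <- outer(trueSire, trueSire, "==")
    sameD <- outer(trueDam, trueDam, "==")
    fullSibs <- sibPairs(sameS, sameD)
    halfSibs <- sibPairs(sameS | sameD, !(sameS & sameD))

    err <- data.frame(snp = ((errIdx - 1L) %% ns) + 1L,
                      sample = ((errIdx - 1L) %/% ns) + 1L)
    list(genotypes = g,
         truth = list(pedigree = ped, duplicates = dupTable,
                      errorMask = err, failingSnps = snpIds[failing],
                      fullSibs = fullSibs, halfSibs = halfSibs,
                      sireFreqs = pS, damFreqs = pD))
}
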