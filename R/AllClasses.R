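#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.ROLES <- c("SIRE", "DAM", "OFFSPRING")

.GROUPS <- c("DAM_OFF", "SIRE_OFF", "OFF_OFF", "DAM_DAM", "SIRE_SIRE",
             "SIRE_DAM")

#' GenotypeMatrix: diploid dosage genotypes with a SNP map and sample roles
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"dosage"` assay: a SNPs x samples integer matrix counting copies of
#' the reference allele (0, 1, 2, or `NA` for a missing call).  Row metadata
#' carries the SNP map (`chrom`, `pos`, 1-based); column metadata carries the
#' sample `role`, one of `"SIRE"`, `"DAM"`, `"OFFSPRING"`.
#'
#' The opposing-homozygote statistic is symmetric under allele relabelling,
#' so the choice of counting reference (rather than alternative) alleles is
#' inert downstream; it is fixed here so that all readers and writers agree.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [GenotypeMatrix()] for the constructor, [readVcfGenotypes()],
#'   [readDosageTable()].
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !(d %in% c(0L, 1L, 2L)) & !is.na(d)
        if (any(bad))
            msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "SNP identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (!all(c("chrom", "pos") %in%
             colnames(SummarizedExperiment::rowData(object))))
        msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
    if (!("role" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain 'role'")
    else {
        r <- SummarizedExperiment::colData(object)$role
        if (!all(r %in% .ROLES | is.na(r)))
            msg <- c(msg, paste0("roles must be one of ",
                                 paste(.ROLES, collapse = "/"), " or NA"))
    }
    if (length(msg)) msg else TRUE
})

#' RejectionSet: opposing-homozygote counts for all sample pairs
#'
#' A [S4Vectors::DataFrame] subclass with one row per unordered sample pair
#' (`sample_i` before `sample_j` in sample order) and columns
#' `sample_i`, `sample_j`, `group`, `delta` (number of SNPs at which the two
#' samples are homozygous for alternative alleles), `n_eff` (SNPs with both
#' calls non-missing) and `tau = delta / n_eff`, the rate of rejection of a
#' first-degree relationship.  `metadata()$n_samples` records the number of
#' samples, so `nrow == n_samples * (n_samples - 1) / 2`.
#'
#' @seealso [pairwiseRejections()]
#' @export
setClass("RejectionSet", contains = "DFrame")

setValidity("RejectionSet", function(object) {
    need <- c("sample_i", "sample_j", "group", "delta", "n_eff", "tau")
    msg <- character()
    if (!all(need %in% colnames(object)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (any(object$delta > object$n_eff, na.rm = TRUE))
        msg <- c(msg, "delta must not exceed n_eff")
    ns <- metadata(object)$n_samples
    if (!is.null(ns) && nrow(object) != ns * (ns - 1) / 2)
        msg <- c(msg, "number of pairs must equal n_samples*(n_samples-1)/2")
    if (length(msg)) msg else TRUE
})

#' MixtureFit: EM fit of the two-component binomial mixture
#'
#' Result of [fitMixture()].  The error component (rate `tauG`) models true
#' first-degree pairs whose rejections arise only from genotyping error; the
#' rejection component (rate `tauR`) models everything else.  Components are
#' kept ordered, `tauG <= tauR`.
#'
#' @slot tauG,tauR numeric(1), binomial rates of the two components.
#' @slot gamma numeric(1), mixing proportion of the error component.
#' @slot responsibilities per-pair posterior probability of membership in the
#'   error component.
#' @slot assignments logical, `responsibilities > threshold` (ties are not
#'   assigned).
#' @slot threshold assignment threshold used (default 0.5).
#' @slot trace matrix with one row per iteration and columns
#'   `tauG`, `tauR`, `gamma`, `logLik`.
#' @slot converged,collapsed logical flags; `collapsed` marks degenerate fits
#'   where one component received no weight.
#' @slot nIter number of EM iterations performed.
#' @slot logLik observed-data log-likelihood at the final parameters.
#' @slot pairs the pair table that was fitted (DataFrame with at least
#'   `delta` and `n_eff`).
#' @export
setClass("MixtureFit",
    representation(tauG = "numeric", tauR = "numeric", gamma = "numeric",
                   responsibilities = "numeric", assignments = "logical",
                   threshold = "numeric", trace = "matrix",
                   converged = "logical", collapsed = "logical",
                   nIter = "integer", logLik = "numeric", pairs = "DFrame"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (length(object@tauG) == 1 && length(object@tauR) == 1 &&
        (object@tauG > object@tauR))
        msg <- c(msg, "components must be ordered: tauG <= tauR")
    if (length(object@gamma) == 1 &&
        (object@gamma < 0 || object@gamma > 1))
        msg <- c(msg, "gamma must lie in [0, 1]")
    if (any(object@responsibilities < 0 | object@responsibilities > 1,
            na.rm = TRUE))
        msg <- c(msg, "responsibilities must lie in [0, 1]")
    if (nrow(object@trace) != object@nIter)
        msg <- c(msg, "trace must have one row per iteration")
    if (length(msg)) msg else TRUE
})

#' ErrorEstimate: genotyping-error rate derived from verified pairs
#'
#' @slot tauGLowerBound the fitted error-component rate; a lower bound on the
#'   per-genotype error because only miscalls that create opposing
#'   homozygotes are observable.
#' @slot detectionFactor mean over SNPs of c(p), the probability that a
#'   single miscall in a true parent-offspring pair produces opposing
#'   homozygotes at a locus with allele frequency p.
#' @slot adjustedError `tauGLowerBound / detectionFactor`.
#' @slot errorModel the miscall model under which c(p) was derived.
#' @seealso [adjustedErrorRate()], [rejectionDetectionProb()]
#' @export
setClass("ErrorEstimate",
    representation(tauGLowerBound = "numeric", detectionFactor = "numeric",
                   adjustedError = "numeric", errorModel = "character"))

setValidity("ErrorEstimate", function(object) {
    msg <- character()
    if (object@detectionFactor <= 0 || object@detectionFactor >= 1)
        msg <- c(msg, "detectionFactor must lie in (0, 1)")
    if (object@adjustedError < object@tauGLowerBound - 1e-12)
        msg <- c(msg, "adjustedError must be >= tauGLowerBound")
    if (length(msg)) msg else TRUE
})

#' PowerDesign: SNPs required to separate the two rejection rates
#'
#' Sample-size design for testing a pair's rejection rate `p0` (error
#' component) against `p1` (rejection component) with a Bonferroni-adjusted
#' significance level over all pairwise tests among `nIndividuals`.
#'
#' @slot p0,p1 null and alternative rejection rates, `0 < p0 < p1 < 1`.
#' @slot alphaGlobal global significance level.
#' @slot power target power.
#' @slot nIndividuals number of individuals screened.
#' @slot nTests number of pairwise tests, `nIndividuals*(nIndividuals-1)/2`.
#' @slot alphaAdjusted `alphaGlobal / nTests` (Bonferroni).
#' @slot sided `"two"` (default) or `"one"`.
#' @slot requiredSnps the resulting SNP count (ceiling of the normal
#'   approximation).
#' @seealso [requiredSnps()], [achievedPower()]
#' @export
setClass("PowerDesign",
    representation(p0 = "numeric", p1 = "numeric", alphaGlobal = "numeric",
                   power = "numeric", nIndividuals = "numeric",
                   nTests = "numeric", alphaAdjusted = "numeric",
                   sided = "character", requiredSnps = "numeric"))

setValidity("PowerDesign", function(object) {
    msg <- character()
    if (!(object@p0 > 0 && object@p0 < object@p1 && object@p1 < 1))
        msg <- c(msg, "need 0 < p0 < p1 < 1")
    if (!(object@alphaGlobal > 0 && object@alphaGlobal < 1))
        msg <- c(msg, "alphaGlobal must lie in (0, 1)")
    if (!(object@power > 0.5 && object@power < 1))
        msg <- c(msg, "power must lie in (0.5, 1)")
    if (abs(object@alphaAdjusted - object@alphaGlobal / object@nTests) > 1e-15)
        msg <- c(msg, "alphaAdjusted must equal alphaGlobal / nTests")
    if (length(msg)) msg else TRUE
})

#' SimConfig: configuration for the crossbred-pedigree simulator
#'
#' Defaults describe a two-breed terminal cross genotyped on a dense array:
#' 9 candidate sires of one breed, 55 dams of another, 214 crossbred
#' offspring, divergent breed allele frequencies, a per-genotype miscall rate
#' of 0.00588, two duplicated dam samples and 20 systematically failing SNPs,
#' with 60% of true parents not among the genotyped candidates.
#'
#' @slot nSires,nDams,nOffspring,nSnps design dimensions.
#' @slot sireFreq,damFreq per-SNP allele-frequency specs, a list with
#'   element `dist` (`"uniform"` or `"beta"`) plus its parameters; see
#'   [divergentFreqs()] and [uniformFreqs()].
#' @slot errorRate per-genotype miscall probability.
#' @slot errorModel `"genotype_uniform"` (a miscalled genotype is replaced by
#'   one of the other two with equal probability) or `"allele_flip"` (each
#'   allele miscalled independently at `errorRate / 2`).
#' @slot missingRate per-call missingness probability.
#' @slot nDuplicateDams number of dam samples duplicated under a fresh
#'   identifier, re-corrupted from the pre-error genotype with fresh error
#'   draws.
#' @slot nFailingSnps,failureMode number of corrupted SNPs and the failure
#'   mechanism: `"force_homozygote"` (heterozygous calls miscalled to a
#'   random homozygote), `"random_call"` or `"swap_local"`.
#' @slot unrelatedParentFraction probability, per offspring and per parent
#'   slot, that the true parent is an ungenotyped animal from the same breed
#'   pool.
#' @slot seed integer seed; a fixed seed gives identical output.
#' @export
setClass("SimConfig",
    representation(nSires = "integer", nDams = "integer",
                   nOffspring = "integer", nSnps = "integer",
                   sireFreq = "list", damFreq = "list",
                   errorRate = "numeric", errorModel = "character",
                   missingRate = "numeric", nDuplicateDams = "integer",
                   nFailingSnps = "integer", failureMode = "character",
                   unrelatedParentFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    rates <- c(error = object@errorRate, missing = object@missingRate,
               unrelated = object@unrelatedParentFraction)
    if (any(rates < 0 | rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    counts <- c(object@nSires, object@nDams, object@nOffspring, object@nSnps,
                object@nDuplicateDams, object@nFailingSnps)
    if (any(counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (!object@errorModel %in% c("genotype_uniform", "allele_flip"))
        msg <- c(msg, "unknown errorModel")
    if (!object@failureMode %in%
        c("force_homozygote", "random_call", "swap_local"))
        msg <- c(msg, "unknown failureMode")
    if (object@nDuplicateDams > object@nDams)
        msg <- c(msg, "cannot duplicate more dams than exist")
    if (object@nFailingSnps > object@nSnps)
        msg <- c(msg, "cannot fail more SNPs than exist")
    if (length(msg)) msg else TRUE
})
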