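.writeTsv <- function(x, path)
    data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA",
                       quote = FALSE)

#' Read a pairs table written by the pipeline
#'
#' @param path a `pairs.tsv` produced by [runPipeline()] (or any TSV with
#'   the [RejectionSet-class] columns).
#' @return a [RejectionSet-class]; `metadata()$n_samples` is reconstructed
#'   from the identifiers.
#' @export
readPairsTable <- function(path) {
    df <- data.table::fread(path, sep = "\t", data.table = FALSE)
    res <- new("RejectionSet", DataFrame(df))
    metadata(res)$n_samples <- length(unique(c(df$sample_i, df$sample_j)))
    res
}

## collapse duplicate sample ids onto a canonical representative
.canonicalId <- function(ids, duplicates) {
    if (!nrow(duplicates))
        return(ids)
    # sample_i precedes sample_j in sample order; keep the first-seen id
    m <- match(ids, duplicates$sample_j)
    out <- ids
    out[!is.na(m)] <- duplicates$sample_i[m[!is.na(m)]]
    out
}

#' Run the full verification workflow
#'
#' Filters SNPs, computes all pairwise rejection rates, screens for
#' duplicated samples, fits the binomial mixture within the dam-offspring
#' and sire-offspring groups (and optionally offspring-offspring, labelled
#' full-sib *candidates* since half-sibs contaminate that component),
#' derives the parentage table, estimates the genotyping error from the
#' verified pairs, and profiles per-SNP rejections.  An offspring assigned
#' more than one dam (or sire) triggers the duplicate check first: if the
#' two parents are concordance-duplicates they are collapsed onto one
#' individual, otherwise both are reported as a conflict.
#'
#' When `outDir` is given, writes `pairs.tsv`, `duplicates.tsv`, per-group
#' `<group>_assignments.tsv` and `<group>_fit.json`, `parentage.tsv`,
#' `conflicts.tsv`, `snp_rejections.tsv`, `error_estimate.json` and
#' `summary.json`.
#'
#' @param g a [GenotypeMatrix-class] with roles set.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param minCallRate,chromosomes SNP filters, see [filterSnps()].
#' @param groups relationship groups to fit.
#' @param duplicateThreshold concordance threshold for
#'   [detectDuplicates()].
#' @param emThreshold assignment threshold for [fitMixture()].
#' @param failingThreshold rejection-count threshold for
#'   [flagFailingSnps()].
#' @param errorModel miscall model for the error adjustment.
#' @return (invisibly) a list with `pairs`, `duplicates`, `fits`,
#'   `parentage`, `conflicts`, `snpProfiles`, `errorEstimate`, `summary`.
#' @export
runPipeline <- function(g, outDir = NULL, minCallRate = 0.97,
                        chromosomes = NULL,
                        groups = c("DAM_OFF", "SIRE_OFF"),
                        duplicateThreshold = 0.98, emThreshold = 0.5,
                        failingThreshold = 5,
                        errorModel = c("genotype_uniform", "allele_flip")) {
    errorModel <- match.arg(errorModel)
    stopifnot(all(groups %in% .GROUPS))
    g <- filterSnps(g, minCallRate = minCallRate, chromosomes = chromosomes)
    pairs <- pairwiseRejections(g)
    dups <- detectDuplicates(g, threshold = duplicateThreshold)

    fits <- list()
    for (grp in groups) {
        sub <- pairs[!is.na(pairs$group) & pairs$group == grp, , drop = FALSE]
        if (nrow(sub) < 2) {
            warning("group ", grp, " has fewer than two pairs; skipped")
            next
        }
        fits[[grp]] <- fitMixture(sub, threshold = emThreshold)
    }

    parentage <- conflicts <- data.frame(
        offspring = character(0), parent = character(0),
        parent_as_sampled = character(0), role = character(0),
        tau = numeric(0), responsibility = numeric(0))
    for (grp in intersect(c("DAM_OFF", "SIRE_OFF"), names(fits))) {
        fit <- fits[[grp]]
        sub <- fit@pairs[assignments(fit), , drop = FALSE]
        if (!nrow(sub))
            next
        roles <- sampleRoles(g)
        off <- ifelse(roles[sub$sample_i] == "OFFSPRING", sub$sample_i,
                      sub$sample_j)
        par <- ifelse(roles[sub$sample_i] == "OFFSPRING", sub$sample_j,
                      sub$sample_i)
        parCanon <- .canonicalId(par, dups)
        tab <- data.frame(offspring = off, parent = parCanon,
                          parent_as_sampled = par,
                          role = if (grp == "DAM_OFF") "DAM" else "SIRE",
                          tau = sub$tau,
                          responsibility =
                              responsibilities(fit)[assignments(fit)],
                          row.names = NULL)
        tab <- tab[!duplicated(tab[, c("offspring", "parent")]), ]
        multi <- names(which(table(tab$offspring) > 1))
        if (length(multi)) {
            conflicts <- rbind(conflicts,
                               tab[tab$offspring %in% multi, , drop = FALSE])
            tab <- tab[!tab$offspring %in% multi, , drop = FALSE]
        }
        parentage <- rbind(parentage, tab)
    }

    verified <- unique(do.call(rbind, lapply(
        intersect(c("DAM_OFF", "SIRE_OFF"), names(fits)),
        function(grp) {
            fit <- fits[[grp]]
            as.data.frame(fit@pairs[assignments(fit),
                                    c("sample_i", "sample_j"), drop = FALSE])
        })))

    snpProfiles <- NULL
    errEst <- NULL
    if (!is.null(verified) && nrow(verified)) {
        snpProfiles <- snpRejectionCounts(g, verified,
                                          failingThreshold = failingThreshold)
        poPairs <- do.call(rbind, lapply(
            intersect(c("DAM_OFF", "SIRE_OFF"), names(fits)),
            function(grp) as.data.frame(
                fits[[grp]]@pairs[, c("delta", "n_eff")])))
        # joint tauG across both parent-offspring groups, one combined fit
        jointFit <- tryCatch(fitMixture(poPairs, threshold = emThreshold),
                             error = function(e) NULL)
        tg <- if (!is.null(jointFit)) tauG(jointFit)
              else mean(unlist(lapply(fits, tauG)))
        errEst <- adjustedErrorRate(tg, snpSummaries(g),
                                    errorModel = errorModel)
    }

    nOff <- sum(sampleRoles(g) == "OFFSPRING", na.rm = TRUE)
    pat <- parentage[parentage$role == "SIRE", , drop = FALSE]
    mat <- parentage[parentage$role == "DAM", , drop = FALSE]
    summary <- list(
        n_samples = ncol(g), n_snps = nrow(g), n_offspring = nOff,
        n_pairs = nrow(pairs), n_duplicates = nrow(dups),
        resolved_paternities = length(unique(pat$offspring)),
        resolved_maternities = length(unique(mat$offspring)),
        both_parents_resolved = length(intersect(pat$offspring,
                                                 mat$offspring)),
        n_conflicts = length(unique(conflicts$offspring)),
        tau_g = if (!is.null(errEst)) errEst@tauGLowerBound else NA,
        adjusted_error = if (!is.null(errEst)) errEst@adjustedError else NA,
        n_failing_snps = if (!is.null(snpProfiles))
            sum(snpProfiles$failing) else NA)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        .writeTsv(pairs, file.path(outDir, "pairs.tsv"))
        .writeTsv(dups, file.path(outDir, "duplicates.tsv"))
        for (grp in names(fits)) {
            fit <- fits[[grp]]
            out <- as.data.frame(fit@pairs)
            out$responsibility <- responsibilities(fit)
            out$assigned <- assignments(fit)
            .writeTsv(out, file.path(outDir,
                                     paste0(grp, "_assignments.tsv")))
            jsonlite::write_json(
                list(tau_g = tauG(fit), tau_r = tauR(fit),
                     gamma = mixingProportion(fit), n_iter = fit@nIter,
                     converged = fit@converged,
                     trace = as.data.frame(fit@trace)),
                file.path(outDir, paste0(grp, "_fit.json")),
                auto_unbox = TRUE, digits = NA)
        }
        .writeTsv(parentage, file.path(outDir, "parentage.tsv"))
        .writeTsv(conflicts, file.path(outDir, "conflicts.tsv"))
        if (!is.null(snpProfiles))
            .writeTsv(snpProfiles, file.path(outDir, "snp_rejections.tsv"))
        if (!is.null(errEst))
            jsonlite::write_json(
                list(tau_g = errEst@tauGLowerBound,
                     detection_factor = errEst@detectionFactor,
                     adjusted_error = errEst@adjustedError,
                     error_model = errEst@errorModel),
                file.path(outDir, "error_estimate.json"),
                auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(pairs = pairs, duplicates = dups, fits = fits,
                   parentage = parentage, conflicts = conflicts,
                   snpProfiles = snpProfiles, errorEstimate = errEst,
                   summary = summary))
}
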