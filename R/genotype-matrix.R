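#' Construct a GenotypeMatrix
#'
#' @param dosage SNPs x samples matrix of reference-allele counts (0, 1, 2,
#'   `NA`); `rownames` are SNP identifiers, `colnames` sample identifiers.
#' @param snpMap `data.frame` with columns `snp_id`, `chrom`, `pos`
#'   (1-based).  If `NULL`, chromosome and position are set to `NA`.
#' @param roles sample roles: a character vector named by sample id (or
#'   unnamed, in column order) with values `"SIRE"`, `"DAM"`,
#'   `"OFFSPRING"`, or a `data.frame` with columns `sample_id` and `role`.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' d <- matrix(c(2L, 1L, 0L, NA, 1L, 1L), nrow = 3,
#'             dimnames = list(paste0("snp", 1:3), c("a", "b")))
#' g <- GenotypeMatrix(d, roles = c(a = "DAM", b = "OFFSPRING"))
#' dosages(g)
#' @export
GenotypeMatrix <- function(dosage, snpMap = NULL, roles = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
    if (is.null(snpMap)) {
        rd <- DataFrame(chrom = rep(NA_character_, nrow(dosage)),
                        pos = rep(NA_integer_, nrow(dosage)))
    } else {
        snpMap <- as.data.frame(snpMap)
        if (!all(c("snp_id", "chrom", "pos") %in% colnames(snpMap)))
            stop("snpMap needs columns snp_id, chrom, pos")
        idx <- match(rownames(dosage), snpMap$snp_id)
        if (anyNA(idx))
            stop("snpMap does not cover all SNPs in the dosage matrix")
        rd <- DataFrame(chrom = as.character(snpMap$chrom[idx]),
                        pos = as.integer(snpMap$pos[idx]))
    }
    role <- rep(NA_character_, ncol(dosage))
    if (!is.null(roles)) {
        if (is.data.frame(roles)) {
            idx <- match(colnames(dosage), roles$sample_id)
            role <- as.character(roles$role[idx])
        } else if (!is.null(names(roles))) {
            role <- as.character(roles[colnames(dosage)])
        } else {
            if (length(roles) != ncol(dosage))
                stop("unnamed roles must match the number of samples")
            role <- as.character(roles)
        }
    }
    se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd,
                               colData = DataFrame(role = role,
                                                   row.names = colnames(dosage)))
    new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix",
          function(x) SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    data.frame(snp_id = rownames(x), chrom = rd$chrom, pos = rd$pos,
               row.names = NULL)
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleRoles", "GenotypeMatrix", function(x) {
    r <- SummarizedExperiment::colData(x)$role
    names(r) <- colnames(x)
    r
})

#' @rdname GenotypeMatrix-class
#' @export
setReplaceMethod("sampleRoles", "GenotypeMatrix", function(x, value) {
    if (!is.null(names(value)))
        value <- value[colnames(x)]
    SummarizedExperiment::colData(x)$role <- as.character(value)
    validObject(x)
    x
})

setMethod("show", "GenotypeMatrix", function(object) {
    roles <- sampleRoles(object)
    cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object), "samples\n")
    tab <- table(factor(roles, levels = .ROLES), useNA = "ifany")
    cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    d <- dosages(object)
    cat(sprintf("  missing calls: %.3f%%\n", 100 * mean(is.na(d))))
    invisible(NULL)
})
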