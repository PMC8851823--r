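#' Read diploid genotypes from a VCF file
#'
#' Biallelic records are converted to reference-allele dosages (`0/0` -> 2,
#' `0/1` -> 1, `1/1` -> 0, `./.` -> `NA`; phased separators are accepted).
#' Multiallelic records are skipped, not split, with a message reporting the
#' count: the exclusion statistic is defined for biallelic SNPs.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param roles optional sample roles passed on to [GenotypeMatrix()].
#' @return a [GenotypeMatrix-class].
#' @seealso [writeVcfGenotypes()] for the inverse operation.
#' @export
readVcfGenotypes <- function(path, roles = NULL) {
    if (!file.exists(path))
        stop("cannot read VCF: ", path)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(vcf)
    nskip <- sum(!bi)
    if (nskip > 0)
        message("skipped ", nskip, " multiallelic record(s)")
    if (!any(bi))
        stop("no biallelic SNPs in ", path)
    vcf <- vcf[bi, ]
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt[] <- gsub("|", "/", gt, fixed = TRUE)
    lut <- c("0/0" = 2L, "0/1" = 1L, "1/0" = 1L, "1/1" = 0L)
    dosage <- matrix(lut[gt], nrow = nrow(gt), dimnames = dimnames(gt))
    fix <- vcfR::getFIX(vcf)
    ids <- fix[, "ID"]
    auto <- is.na(ids) | ids == "."
    ids[auto] <- paste0(fix[auto, "CHROM"], "_", fix[auto, "POS"])
    rownames(dosage) <- ids
    GenotypeMatrix(dosage,
                   snpMap = data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                                       pos = as.integer(fix[, "POS"])),
                   roles = roles)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Serializes dosages back to diploid genotypes (2 -> `0/0`, 1 -> `0/1`,
#' 0 -> `1/1`, `NA` -> `./.`).  The container stores dosages only, so REF and
#' ALT are written as placeholder alleles `A`/`B`; round-tripping through
#' [readVcfGenotypes()] reproduces the calls exactly.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(g, path) {
    d <- dosages(g)
    info <- snpInfo(g)
    gtlut <- c("1/1", "0/1", "0/0")
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtlut[d[ok] + 1L]
    chrom <- ifelse(is.na(info$chrom), ".", info$chrom)
    pos <- ifelse(is.na(info$pos), 0L, info$pos)
    body <- cbind(chrom, pos, info$snp_id, "A", "B", ".", ".", ".", "GT", gt)
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read genotypes from a PLINK-style dosage table
#'
#' The table is whitespace- or tab-delimited with a header row of
#' identifiers and a first column of identifiers; entries are 0/1/2
#' reference-allele counts or a missing token.  `orientation` says whether
#' rows are SNPs (transposed-PED style) or samples.
#'
#' @param path path to the dosage table.
#' @param mapPath path to a 3-column SNP map (`snp_id`, `chrom`, `pos`),
#'   with header.
#' @param orientation `"snps_in_rows"` (default) or `"samples_in_rows"`.
#' @param missingTokens strings read as missing calls.
#' @param roles optional sample roles passed on to [GenotypeMatrix()].
#' @return a [GenotypeMatrix-class].
#' @export
readDosageTable <- function(path, mapPath,
                            orientation = c("snps_in_rows",
                                            "samples_in_rows"),
                            missingTokens = c("NA", "-9"), roles = NULL) {
    orientation <- match.arg(orientation)
    tab <- data.table::fread(path, header = TRUE, na.strings = missingTokens,
                             data.table = FALSE)
    rn <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- rn
    if (orientation == "samples_in_rows")
        m <- t(m)
    map <- data.table::fread(mapPath, header = TRUE, data.table = FALSE)
    if (ncol(map) < 3L)
        stop("SNP map must have 3 columns: snp_id, chrom, pos")
    colnames(map)[1:3] <- c("snp_id", "chrom", "pos")
    if (nrow(map) != nrow(m))
        stop("dosage table has ", nrow(m), " SNPs but map has ", nrow(map))
    if (!setequal(rownames(m), map$snp_id))
        stop("SNP identifiers in table and map disagree")
    GenotypeMatrix(m, snpMap = map, roles = roles)
}

#' Per-SNP call rate and minor-allele frequency
#'
#' @param g a [GenotypeMatrix-class].
#' @return `data.frame` with `snp_id`, `call_rate` (fraction of non-missing
#'   calls) and `maf` in `[0, 0.5]` computed over non-missing calls;
#'   `maf` is `NA` for SNPs with no calls.
#' @export
snpSummaries <- function(g) {
    d <- dosages(g)
    nnm <- rowSums(!is.na(d))
    freq <- rowSums(d, na.rm = TRUE) / (2 * nnm)
    maf <- pmin(freq, 1 - freq)
    maf[nnm == 0] <- NA_real_
    data.frame(snp_id = rownames(d), call_rate = nnm / ncol(d), maf = maf,
               row.names = NULL)
}

#' Filter SNPs by call rate and chromosome
#'
#' @param g a [GenotypeMatrix-class].
#' @param minCallRate minimum fraction of non-missing calls, in `[0, 1]`.
#' @param chromosomes chromosomes to retain (character), or `NULL` for all.
#'   For a pig autosome set use `as.character(1:18)`.
#' @return the filtered [GenotypeMatrix-class]; SNP order is preserved.
#' @export
filterSnps <- function(g, minCallRate = 0, chromosomes = NULL) {
    stopifnot(minCallRate >= 0, minCallRate <= 1)
    s <- snpSummaries(g)
    keep <- s$call_rate >= minCallRate
    if (!is.null(chromosomes))
        keep <- keep & snpInfo(g)$chrom %in% as.character(chromosomes)
    if (!any(keep))
        warning("no SNPs pass the filter")
    g[keep, ]
}
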