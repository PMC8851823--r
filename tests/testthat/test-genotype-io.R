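test_that("VCF genotypes decode to reference-allele dosages", {
    vcf <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpig1",
             "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0",
             "1\t200\trs2\tA\tG\t.\t.\t.\tGT\t0/1",
             "2\t300\trs3\tC\tT\t.\t.\t.\tGT\t1/1",
             "2\t400\trs4\tC\tT\t.\t.\t.\tGT\t./.")
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, path)
    g <- readVcfGenotypes(path)
    expect_identical(unname(dosages(g)[, "pig1"]), c(2L, 1L, 0L, NA))
    expect_identical(snpInfo(g)$chrom, c("1", "1", "2", "2"))
    expect_identical(snpInfo(g)$pos, c(100L, 200L, 300L, 400L))
})

test_that("multiallelic records are skipped with a reported count", {
    vcf <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
             "1\t1\ts1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
             "1\t2\ts2\tA\tG,T\t.\t.\t.\tGT\t0/2\t1/2",
             "1\t3\ts3\tA\tG\t.\t.\t.\tGT\t1|1\t0|0",
             "1\t4\ts4\tA\tC\t.\t.\t.\tGT\t0/1\t1/1")
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, path)
    expect_message(g <- readVcfGenotypes(path), "1 multiallelic")
    expect_equal(nrow(g), 3L)
    expect_false("s2" %in% snpInfo(g)$snp_id)
    # phased separators decode like unphased ones
    expect_identical(unname(dosages(g)["s3", ]), c(0L, 2L))
})

test_that("write/read round trip reproduces calls exactly", {
    set.seed(42)
    d <- randomDosage(60, 5, missingRate = 0.1)
    g <- GenotypeMatrix(d, snpMap = data.frame(snp_id = rownames(d),
                                               chrom = "3",
                                               pos = seq_len(nrow(d))))
    path <- withr::local_tempfile(fileext = ".vcf")
    writeVcfGenotypes(g, path)
    g2 <- readVcfGenotypes(path)
    expect_identical(dosages(g2), dosages(g))
    expect_identical(snpInfo(g2), snpInfo(g))
})

test_that("dosage table and VCF routes give identical matrices", {
    set.seed(7)
    d <- randomDosage(40, 6, missingRate = 0.05)
    vcfPath <- withr::local_tempfile(fileext = ".vcf")
    writeVcfGenotypes(GenotypeMatrix(d), vcfPath)
    fromVcf <- readVcfGenotypes(vcfPath)

    tabPath <- withr::local_tempfile(fileext = ".tsv")
    mapPath <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(snp_id = rownames(d), d, check.names = FALSE),
                tabPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(snp_id = rownames(d), chrom = ".", pos = 0L),
                mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
    fromTab <- readDosageTable(tabPath, mapPath)
    expect_identical(dosages(fromTab), dosages(fromVcf))

    # orientation flag transposes to the same matrix
    tPath <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(sample_id = colnames(d), t(d),
                           check.names = FALSE),
                tPath, sep = "\t", quote = FALSE, row.names = FALSE)
    fromT <- readDosageTable(tPath, mapPath, orientation = "samples_in_rows")
    expect_identical(dosages(fromT), dosages(fromVcf))
})

test_that("dosage-table missing tokens and dimension checks work", {
    tabPath <- withr::local_tempfile(fileext = ".tsv")
    mapPath <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("snp_id\ta\tb", "s1\t1\t1", "s2\tNA\t-9", "s3\t1\t1"),
               tabPath)
    writeLines(c("snp_id\tchrom\tpos", "s1\t1\t1", "s2\t1\t2", "s3\t1\t3"),
               mapPath)
    g <- readDosageTable(tabPath, mapPath)
    expect_identical(unname(dosages(g)["s1", ]), c(1L, 1L))
    expect_identical(unname(dosages(g)["s2", ]), c(NA_integer_, NA_integer_))
    short <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("snp_id\tchrom\tpos", "s1\t1\t1"), short)
    expect_error(readDosageTable(tabPath, short), "map")
})

test_that("dosage values outside 0/1/2/NA are rejected", {
    d <- matrix(c(0L, 3L), nrow = 2)
    expect_error(GenotypeMatrix(d), "0, 1, 2 or NA")
})

test_that("snpSummaries counts alleles over non-missing calls", {
    d <- rbind(s1 = c(0L, 0L, 1L),      # REF freq 1/6 -> maf 1/6
               s2 = c(1L, 1L, 1L),      # all het -> maf 0.5
               s3 = c(2L, NA, NA),      # one call, monomorphic
               s4 = c(NA, NA, NA))      # no calls
    colnames(d) <- c("a", "b", "c")
    s <- snpSummaries(GenotypeMatrix(d))
    expect_equal(s$maf, c(1 / 6, 0.5, 0, NA))
    expect_equal(s$call_rate, c(1, 1, 1 / 3, 0))
})

test_that("maf matches brute-force allele counting and is label-symmetric", {
    set.seed(1)
    d <- randomDosage(100, 50, missingRate = 0.05)
    s <- snpSummaries(GenotypeMatrix(d))
    brute <- apply(d, 1, function(x) {
        x <- x[!is.na(x)]
        f <- sum(x) / (2 * length(x))
        min(f, 1 - f)
    })
    expect_equal(s$maf, unname(brute))
    # swapping allele labels (dosage -> 2 - dosage) leaves MAF unchanged
    sSwap <- snpSummaries(GenotypeMatrix(2L - d))
    expect_equal(sSwap$maf, s$maf)
})

test_that("filterSnps applies call-rate and chromosome rules, idempotently", {
    set.seed(2)
    d <- randomDosage(200, 20, missingRate = 0)
    miss <- runif(200, 0, 0.15)
    for (i in seq_len(200))
        d[i, runif(20) < miss[i]] <- NA_integer_
    d[7, ] <- NA_integer_
    g <- GenotypeMatrix(d, snpMap = data.frame(
        snp_id = rownames(d), chrom = rep(c("1", "2", "X", "5"), 50),
        pos = seq_len(200)))

    expect_identical(dosages(filterSnps(g, 0)), dosages(g))
    expect_false("s0007" %in% rownames(filterSnps(g, 0.97)))

    keepOracle <- rowMeans(!is.na(d)) >= 0.9 &
        rep(c("1", "2", "X", "5"), 50) %in% c("1", "2", "5")
    f <- filterSnps(g, 0.9, chromosomes = c("1", "2", "5"))
    expect_identical(rownames(f), rownames(d)[keepOracle])
    expect_identical(dosages(filterSnps(f, 0.9, c("1", "2", "5"))),
                     dosages(f))  # idempotent
    expect_warning(filterSnps(g, 1, chromosomes = "99"), "no SNPs")
})
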