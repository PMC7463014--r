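writeFixtureTables <- function(dir, geno_lines, pheno_lines) {
    gpath <- file.path(dir, "g.tsv"); ppath <- file.path(dir, "p.tsv")
    writeLines(geno_lines, gpath); writeLines(pheno_lines, ppath)
    c(gpath, ppath)
}

test_that("genotype/phenotype tables are read with missing-code handling", {
    panel <- tinyPanel()
    dir <- withr::local_tempdir()
    paths <- writeFixtureTables(
        dir,
        c("subject_id\trs1\trs2",
          "A\t0\t2", "B\tNA\t1", "C\t.\t"),
        c("subject_id\tstatus\tage\tsex\tcountry\tsubtype\tjak2",
          "A\tcase\t60\tmale\tItaly\tPV\tpositive",
          "B\tcontrol\t50\tfemale\tSpain\tnone\tunknown",
          "C\tcontrol\t55\tmale\tSpain\tnone\tunknown"))
    cohort <- readCohort(paths[1], paths[2], panel)
    expect_equal(ncol(cohort), 3L)
    g <- genotypes(cohort)
    expect_identical(g["rs1", "A"], 0L)
    expect_true(is.na(g["rs1", "B"]))     # "NA"
    expect_true(is.na(g["rs1", "C"]))     # "."
    expect_true(is.na(g["rs2", "C"]))     # empty field
    expect_equal(nCases(cohort), 1L)

    # unknown genotype codes become missing with a warning
    paths2 <- writeFixtureTables(
        dir,
        c("subject_id\trs1\trs2", "A\tXX\t1", "B\t1\t1", "C\t2\t0"),
        readLines(paths[2]))
    expect_warning(cohort2 <- readCohort(paths2[1], paths2[2], panel),
                   "unrecognized")
    expect_true(is.na(genotypes(cohort2)["rs1", "A"]))
})

test_that("malformed tables are rejected", {
    panel <- tinyPanel()
    dir <- withr::local_tempdir()
    pheno_ok <- c("subject_id\tstatus\tage\tsex\tcountry\tsubtype\tjak2",
                  "A\tcase\t60\tmale\tItaly\tPV\tpositive",
                  "B\tcontrol\t50\tfemale\tSpain\tnone\tunknown")
    # duplicated subject id
    paths <- writeFixtureTables(
        dir, c("subject_id\trs1\trs2", "A\t0\t1", "A\t1\t1"), pheno_ok)
    expect_error(readCohort(paths[1], paths[2], panel), "duplicated")
    # missing phenotype column
    paths <- writeFixtureTables(
        dir, c("subject_id\trs1\trs2", "A\t0\t1", "B\t1\t1"),
        c("subject_id\tstatus\tage\tsex\tcountry\tsubtype",
          "A\tcase\t60\tmale\tItaly\tPV",
          "B\tcontrol\t50\tfemale\tSpain\tnone"))
    expect_error(readCohort(paths[1], paths[2], panel), "jak2")
    # controls must have subtype none
    paths <- writeFixtureTables(
        dir, c("subject_id\trs1\trs2", "A\t0\t1", "B\t1\t1"),
        c("subject_id\tstatus\tage\tsex\tcountry\tsubtype\tjak2",
          "A\tcase\t60\tmale\tItaly\tPV\tpositive",
          "B\tcontrol\t50\tfemale\tSpain\tET\tunknown"))
    expect_error(readCohort(paths[1], paths[2], panel), "subtype")
})

test_that("VCF genotypes convert to effect-allele counts with orientation flips", {
    panel <- tinyPanel(betas = c(0.10, 0.05, 0.08), eafs = c(0.3, 0.6, 0.2))
    # rs1: ALT is the effect allele (A); rs2: REF is the effect allele (C,
    # flipped); rs3 has a mismatching allele pair and must be skipped.
    df <- panelTable(panel)
    vcf <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
             sprintf("1\t%d\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1|1\t./.",
                     df$position[1]),
             sprintf("2\t%d\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1",
                     df$position[2]),
             sprintf("3\t%d\trs3\tG\tC\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
                     df$position[3]))
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, path)
    expect_warning(m <- readVcfGenotypes(path, panel), "inconsistent")
    expect_identical(m["rs1", ], c(S1 = 1L, S2 = 2L, S3 = NA_integer_))
    # flipped orientation: 2 - ALT count
    expect_identical(m["rs2", ], c(S1 = 0L, S2 = 2L, S3 = 1L))
    expect_true(all(is.na(m["rs3", ])))
})

test_that("VCF-derived genotypes round-trip through the TSV dialect", {
    panel <- tinyPanel(betas = c(0.10, 0.05), eafs = c(0.3, 0.6))
    df <- panelTable(panel)
    vcf <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
             sprintf("1\t%d\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
                     df$position[1]),
             sprintf("2\t%d\trs2\tT\tC\t.\tPASS\t.\tGT\t0/0\t./.",
                     df$position[2]))
    vpath <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, vpath)
    m <- readVcfGenotypes(vpath, panel)
    cohort <- makeCohort(m, status = c("case", "control"), panel = panel)
    dir <- withr::local_tempdir()
    writeCohort(cohort, file.path(dir, "g.tsv"), file.path(dir, "p.tsv"))
    back <- readCohort(file.path(dir, "g.tsv"), file.path(dir, "p.tsv"), panel)
    expect_identical(genotypes(back), genotypes(cohort))
})

test_that("call-rate computation and filtering match the 8-of-11 rule", {
    panel <- builtinPanel()
    g <- matrix(1L, nrow = 11, ncol = 3)
    g[1:3, 2] <- NA_integer_   # 8 of 11 called
    g[, 3] <- NA_integer_      # 0 called
    cohort <- makeCohort(g, status = c("case", "control", "control"))
    cr <- callRate(cohort)
    expect_equal(cr$n_called, c(11L, 8L, 0L))
    expect_equal(round(cr$call_rate, 3), c(1.000, 0.727, 0.000))

    res <- filterByCallRate(cohort, min_called = 8L)
    expect_equal(ncol(res$cohort), 2L)
    expect_equal(res$excluded$n_called, 0L)
    expect_equal(nrow(res$excluded) + ncol(res$cohort), ncol(cohort))
    # idempotent
    res2 <- filterByCallRate(res$cohort, min_called = 8L)
    expect_equal(ncol(res2$cohort), 2L)
    expect_equal(nrow(res2$excluded), 0L)
    # min_called = 0 keeps everyone
    expect_equal(ncol(filterByCallRate(cohort, 0L)$cohort), 3L)
})

test_that("minor allele frequency follows the control-tie rule", {
    panel <- tinyPanel()
    # rs1: 9 hom-EA, 42 het, 49 hom-OA over 100 subjects -> EA freq 0.30
    g1 <- c(rep(2L, 9), rep(1L, 42), rep(0L, 49))
    g <- rbind(rs1 = g1, rs2 = rep(1L, 100))
    cohort <- makeCohort(g, status = rep(c("case", "control"), 50),
                         panel = panel)
    maf <- minorAlleleFrequency(cohort, "rs1")
    expect_equal(as.numeric(maf), 0.30)
    expect_true(attr(maf, "minor_is_effect"))

    # all heterozygous: tie at 0.5 resolves to the panel other allele
    maf2 <- minorAlleleFrequency(cohort, "rs2")
    expect_equal(as.numeric(maf2), 0.5)
    expect_false(attr(maf2, "minor_is_effect"))
    expect_equal(attr(maf2, "minor_allele"),
                 panelTable(panel)$other_allele[2])

    g[] <- NA_integer_
    empty <- makeCohort(g, status = rep(c("case", "control"), 50),
                        panel = panel)
    expect_error(minorAlleleFrequency(empty, "rs1"), "no called")
})

test_that("duplicate concordance pools both-called comparisons", {
    panel <- tinyPanel(betas = rep(0.1, 11), eafs = rep(0.3, 11))
    a <- rep(1L, 11)
    g <- cbind(A = a, A2 = a, B = a, B2 = c(0L, NA_integer_, a[-(1:2)]),
               C = rep(NA_integer_, 11))
    rownames(g) <- panelRsids(panel)
    cohort <- makeCohort(g, status = rep("control", 5), panel = panel)
    expect_equal(as.numeric(duplicateConcordance(cohort, cbind("A", "A2"))), 1.0)
    # 10 comparable calls, 1 discordant
    expect_equal(as.numeric(duplicateConcordance(cohort, cbind("B", "B2"))), 0.9)
    expect_equal(attr(duplicateConcordance(cohort, cbind("B", "B2")),
                      "n_comparable"), 10L)
    expect_error(duplicateConcordance(cohort, cbind("C", "C")), "comparable")
    expect_error(duplicateConcordance(cohort, cbind("A", "ZZ")), "not in cohort")
})
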