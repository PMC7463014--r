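# Readers/writers for the cohort TSV dialect and panel-restricted VCFs, plus
# the genotyping QC steps applied before any association analysis.

.MISSING_CODES <- c("NA", ".", "")

#' Read a cohort from genotype and phenotype tables
#'
#' The genotype table is TSV with a \code{subject_id} column followed by one
#' column per panel rsid holding effect-allele counts 0/1/2; missing calls
#' are \code{NA}, \code{.} or an empty field. Any other code is converted to
#' missing with a warning. The phenotype table is TSV with columns
#' \code{subject_id}, \code{status} (case/control), \code{age}, \code{sex},
#' \code{country}, \code{subtype}, \code{jak2}.
#'
#' @param genotype_path path to the genotype TSV
#' @param phenotype_path path to the phenotype TSV
#' @param panel the \linkS4class{TeloPanel} the genotype columns refer to
#'   (default the built-in 11-SNP panel)
#' @return a \linkS4class{TeloCohort}
#' @export
readCohort <- function(genotype_path, phenotype_path, panel = builtinPanel()) {
    for (p in c(genotype_path, phenotype_path))
        if (!file.exists(p)) stop("file not found: ", p)
    geno <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                              colClasses = "character", check.names = FALSE)
    if (!"subject_id" %in% colnames(geno))
        stop("genotype table lacks a 'subject_id' column")
    if (anyDuplicated(geno$subject_id))
        stop("duplicated subject_id in genotype table")
    rsids <- panelRsids(panel)
    missing_snps <- setdiff(rsids, colnames(geno))
    if (length(missing_snps) > 0L)
        stop("genotype table lacks panel columns: ",
             paste(missing_snps, collapse = ", "))
    m <- as.matrix(geno[, rsids, drop = FALSE])
    m[m %in% .MISSING_CODES] <- NA_character_
    unknown <- !is.na(m) & !(m %in% c("0", "1", "2"))
    if (any(unknown)) {
        warning(sum(unknown), " genotype value(s) with unrecognized codes (",
                paste(unique(m[unknown]), collapse = ", "),
                ") treated as missing")
        m[unknown] <- NA_character_
    }
    counts <- matrix(as.integer(m), nrow = nrow(m),
                     dimnames = list(geno$subject_id, rsids))

    pheno <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
    need <- c("subject_id", .PHENO_COLUMNS)
    missing_cols <- setdiff(need, colnames(pheno))
    if (length(missing_cols) > 0L)
        stop("phenotype table lacks columns: ",
             paste(missing_cols, collapse = ", "))
    if (anyDuplicated(pheno$subject_id))
        stop("duplicated subject_id in phenotype table")
    TeloCohort(t(counts), pheno, panel)
}

#' Write a cohort back to the TSV dialect
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param genotype_path,phenotype_path output paths
#' @return invisibly, the two paths
#' @export
writeCohort <- function(cohort, genotype_path, phenotype_path) {
    g <- t(genotypes(cohort))
    out <- data.frame(subject_id = rownames(g), g, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, genotype_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(phenotypes(cohort), phenotype_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    invisible(c(genotype_path, phenotype_path))
}

#' Extract panel effect-allele counts from a VCF
#'
#' Panel sites are matched by chromosome + position; the VCF REF/ALT pair
#' must equal the panel's effect/other allele pair (in either orientation).
#' Diploid GT fields are converted to effect-allele counts; where the panel
#' effect allele is the VCF REF the ALT count is flipped (\code{2 - count}).
#' Sites whose allele pair does not match the panel are skipped with a
#' warning (never silently strand-complemented); panel sites absent from the
#' VCF are missing for all subjects.
#'
#' @param vcf_path path to a VCF 4.x file with diploid GT fields
#' @param panel a \linkS4class{TeloPanel}
#' @return integer matrix of effect-allele counts, SNPs x subjects, with one
#'   row per panel SNP (all-NA for sites absent from the VCF)
#' @export
readVcfGenotypes <- function(vcf_path, panel = builtinPanel()) {
    if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
    vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    df <- panelTable(panel)
    subjects <- colnames(gt)
    out <- matrix(NA_integer_, nrow = nrow(df), ncol = length(subjects),
                  dimnames = list(df$rsid, subjects))
    key_vcf <- paste(fix$CHROM, fix$POS)
    for (i in seq_len(nrow(df))) {
        j <- which(key_vcf == paste(df$chromosome[i], df$position[i]))
        if (length(j) == 0L) next
        if (length(j) > 1L) {
            warning("multiple VCF records at panel site ", df$rsid[i],
                    "; site skipped")
            next
        }
        ref <- fix$REF[j]; alt <- fix$ALT[j]
        ea <- df$effect_allele[i]; oa <- df$other_allele[i]
        if (ref == oa && alt == ea) flip <- FALSE
        else if (ref == ea && alt == oa) flip <- TRUE
        else {
            warning("allele pair ", ref, "/", alt, " at ", df$rsid[i],
                    " inconsistent with panel ", ea, "/", oa,
                    "; site skipped")
            next
        }
        alt_count <- .parseDiploidGT(gt[j, ])
        out[i, ] <- if (flip) 2L - alt_count else alt_count
    }
    out
}

# "0/1", "1|1", "./." etc. -> ALT allele count (NA when any allele missing)
.parseDiploidGT <- function(gt) {
    gt[is.na(gt)] <- "./."
    parts <- strsplit(gt, "[/|]")
    vapply(parts, function(a) {
        if (length(a) != 2L || any(a == ".")) return(NA_integer_)
        sum(as.integer(a))
    }, integer(1))
}

#' Per-subject genotyping call rate
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @return data.frame with \code{subject_id}, \code{n_called} (non-missing
#'   panel genotypes) and \code{call_rate} (= n_called / panel size)
#' @examples
#' # 8 of 11 called corresponds to the 72.7% threshold
#' round(8 / 11, 3)
#' @export
callRate <- function(cohort) {
    g <- genotypes(cohort)
    n_called <- colSums(!is.na(g))
    data.frame(subject_id = colnames(g),
               n_called = as.integer(n_called),
               call_rate = n_called / nrow(g),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter subjects by genotyping call rate
#'
#' Retains subjects with at least \code{min_called} non-missing panel
#' genotypes (default 8 of the 11-SNP panel, i.e. a 72.7% call rate).
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param min_called minimum number of called SNPs, in 0..panel size
#' @return list with \code{cohort} (retained subjects) and \code{excluded}
#'   (data.frame of excluded subject_id, status, n_called, call_rate)
#' @export
filterByCallRate <- function(cohort, min_called = 8L) {
    stopifnot(min_called >= 0L, min_called <= nrow(cohort))
    cr <- callRate(cohort)
    keep <- cr$n_called >= min_called
    excluded <- cbind(cr[!keep, , drop = FALSE],
                      status = phenotypes(cohort)$status[!keep])
    rownames(excluded) <- NULL
    out <- if (all(keep)) cohort else
        subsetCohort(cohort, subjects = cr$subject_id[keep])
    list(cohort = out, excluded = excluded)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact test: conditional on the observed allele counts, the
#' probability of each possible heterozygote count is computed, and the
#' two-sided p-value is the total probability of configurations no more
#' likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total >= 1)
#' @return exact two-sided p-value
#' @examples
#' hweExactTest(25, 50, 25)  # modal heterozygote count -> p = 1
#' hweExactTest(1, 0, 1)     # 1/3
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
    stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
    n <- n_hom_ref + n_het + n_hom_alt
    if (n < 1) stop("no genotypes: total count is zero")
    n_a <- 2 * n_hom_alt + n_het          # alt allele count
    n_minor <- min(n_a, 2 * n - n_a)
    hets <- seq.int(n_minor %% 2, n_minor, by = 2)
    # log P(het = h | allele counts), Levene-Haldane
    logp <- h_logprob(hets, n, n_minor)
    p_obs <- logp[match(n_het, hets)]
    if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
    sum(exp(logp[logp <= p_obs + 1e-10]))
}

h_logprob <- function(h, n, n_minor) {
    n_major <- 2 * n - n_minor
    a <- (n_minor - h) / 2       # minor homozygotes
    b <- (n_major - h) / 2       # major homozygotes
    h * log(2) + lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) -
        lgamma(b + 1) + lgamma(n_minor + 1) + lgamma(n_major + 1) -
        lgamma(2 * n + 1)
}

#' Chi-square Hardy-Weinberg test (optional alternative)
#'
#' One-degree-of-freedom goodness-of-fit test against HWE expected genotype
#' counts, without continuity correction.
#'
#' @inheritParams hweExactTest
#' @return p-value
#' @export
hweChisqTest <- function(n_hom_ref, n_het, n_hom_alt) {
    n <- n_hom_ref + n_het + n_hom_alt
    if (n < 1) stop("no genotypes: total count is zero")
    p <- (2 * n_hom_alt + n_het) / (2 * n)
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (any(expected == 0)) return(1)
    x2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expected)^2 / expected)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg QC across the panel in controls
#'
#' Applies [hweExactTest()] (or the chi-square variant) per SNP, by default
#' to control subjects only, the standard genotyping QC.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param stratum subjects to test: controls (default), cases, or all
#' @param method exact (default) or chisq
#' @param alpha flagging threshold (default 0.05)
#' @return data.frame with per-SNP genotype counts, p-value and an
#'   \code{in_hwe} flag
#' @export
hweControls <- function(cohort, stratum = c("controls", "cases", "all"),
                        method = c("exact", "chisq"), alpha = 0.05) {
    stratum <- match.arg(stratum)
    method <- match.arg(method)
    g <- genotypes(cohort)
    st <- phenotypes(cohort)$status
    g <- switch(stratum,
                controls = g[, st == "control", drop = FALSE],
                cases = g[, st == "case", drop = FALSE],
                all = g)
    test <- if (method == "exact") hweExactTest else hweChisqTest
    res <- lapply(rownames(g), function(rs) {
        x <- g[rs, ]
        counts <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                    sum(x == 2, na.rm = TRUE))
        p <- if (sum(counts) == 0) NA_real_ else
            test(counts[1], counts[2], counts[3])
        data.frame(rsid = rs, n_hom_other = counts[1], n_het = counts[2],
                   n_hom_effect = counts[3], p_hwe = p,
                   in_hwe = !is.na(p) && p >= alpha,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Minor allele frequency of a panel SNP
#'
#' Frequency of the less-frequent allele among called genotypes in the
#' requested stratum. When both alleles sit exactly at 0.5 the panel's
#' \emph{other} allele is taken as the minor allele.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param rsid panel SNP id
#' @param stratum all (default), cases, or controls
#' @return MAF, with attributes \code{minor_allele} and
#'   \code{minor_is_effect} (is the minor allele the panel effect allele?)
#' @export
minorAlleleFrequency <- function(cohort, rsid,
                                 stratum = c("all", "cases", "controls")) {
    stratum <- match.arg(stratum)
    g <- genotypes(cohort)
    if (!rsid %in% rownames(g)) stop("not a panel SNP: ", rsid)
    st <- phenotypes(cohort)$status
    x <- switch(stratum,
                all = g[rsid, ],
                cases = g[rsid, st == "case"],
                controls = g[rsid, st == "control"])
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("no called genotypes for ", rsid, " in ", stratum)
    f_ea <- sum(x) / (2 * length(x))
    df <- panelTable(cohortPanel(cohort))
    row <- df[df$rsid == rsid, ]
    minor_is_effect <- f_ea < 0.5      # tie -> other allele is "minor"
    maf <- min(f_ea, 1 - f_ea)
    structure(maf,
              minor_allele = if (minor_is_effect) row$effect_allele else row$other_allele,
              minor_is_effect = minor_is_effect)
}

#' Genotype concordance between duplicated samples
#'
#' Pools genotype comparisons over pairs of duplicated subjects and returns
#' the fraction of comparisons, among those where both calls are non-missing,
#' that agree.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param pairs two-column matrix or data.frame of subject ids
#' @return concordance rate in [0, 1], with attribute \code{n_comparable}
#' @export
duplicateConcordance <- function(cohort, pairs) {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    g <- genotypes(cohort)
    unknown <- setdiff(as.vector(pairs), colnames(g))
    if (length(unknown) > 0L)
        stop("subject ids not in cohort: ", paste(unknown, collapse = ", "))
    a <- g[, pairs[, 1], drop = FALSE]
    b <- g[, pairs[, 2], drop = FALSE]
    comparable <- !is.na(a) & !is.na(b)
    if (!any(comparable)) stop("no comparable (both-called) genotype pairs")
    structure(sum(a[comparable] == b[comparable]) / sum(comparable),
              n_comparable = sum(comparable))
}
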