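#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' TeloPanel: a weighted SNP panel for genetically determined telomere length
#'
#' A \code{TeloPanel} holds one row per SNP: identifiers, alleles, the effect
#' allele (EA, the allele associated with longer telomeres), its frequency
#' (EAF), the per-allele effect on leukocyte telomere length in SD units
#' (\code{beta}, with standard error) and in base pairs (\code{bp_per_allele}),
#' plus discovery provenance. Weights are oriented to the long-telomere
#' allele, so \code{beta >= 0} for every entry and
#' \code{bp_per_allele == beta * 1200} at one-decimal precision.
#'
#' @slot snps data.frame with columns \code{rsid}, \code{gene},
#'   \code{chromosome}, \code{position}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{beta_se},
#'   \code{bp_per_allele}, \code{discovery_pvalue}, \code{discovery_study}.
#'
#' @seealso [builtinPanel()], [validatePanel()], [readPanel()]
#' @export
setClass("TeloPanel", representation(snps = "data.frame"))

.PANEL_COLUMNS <- c("rsid", "gene", "chromosome", "position", "effect_allele",
                    "other_allele", "eaf", "beta", "beta_se", "bp_per_allele",
                    "discovery_pvalue", "discovery_study")

setValidity("TeloPanel", function(object) {
    issues <- validatePanel(object, builtin = FALSE)
    if (length(issues) == 0L) TRUE else issues
})

#' Construct a TeloPanel from a SNP table
#'
#' @param snps data.frame with the columns documented in
#'   \linkS4class{TeloPanel}.
#' @return a \code{TeloPanel}
#' @export
TeloPanel <- function(snps) {
    snps <- as.data.frame(snps, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.PANEL_COLUMNS, colnames(snps))
    if (length(missing_cols) > 0L)
        stop("panel table lacks columns: ", paste(missing_cols, collapse = ", "))
    snps <- snps[, .PANEL_COLUMNS]
    rownames(snps) <- snps$rsid
    new("TeloPanel", snps = snps)
}

#' @describeIn TeloPanel number of SNPs in the panel
#' @param x a \code{TeloPanel}
#' @export
setMethod("length", "TeloPanel", function(x) nrow(x@snps))

#' @export
setMethod("show", "TeloPanel", function(object) {
    cat("TeloPanel with", length(object), "SNPs\n")
    df <- object@snps
    cat(sprintf("  total per-allele weight: %.1f bp (beta x 1200)\n",
                sum(df$bp_per_allele)))
    print(df[, c("rsid", "gene", "effect_allele", "other_allele",
                 "eaf", "beta", "bp_per_allele")], row.names = FALSE)
})

#' Panel accessors
#'
#' \code{panelTable} returns the underlying SNP data.frame; \code{panelRsids}
#' the rsid vector; \code{panelWeights} the named per-allele bp weights.
#'
#' @param panel a \code{TeloPanel}
#' @return data.frame, character vector, or named numeric vector respectively
#' @export
panelTable <- function(panel) {
    stopifnot(is(panel, "TeloPanel"))
    panel@snps
}

#' @rdname panelTable
#' @export
panelRsids <- function(panel) panelTable(panel)$rsid

#' @rdname panelTable
#' @export
panelWeights <- function(panel) {
    df <- panelTable(panel)
    stats::setNames(df$bp_per_allele, df$rsid)
}

#' Subset a panel by rsid
#'
#' @param panel a \code{TeloPanel}
#' @param rsids rsids to keep (order preserved from the panel)
#' @param exclude rsids to drop instead; mutually exclusive with \code{rsids}
#' @return a smaller \code{TeloPanel}
#' @export
subsetPanel <- function(panel, rsids = NULL, exclude = NULL) {
    df <- panelTable(panel)
    if (!is.null(rsids) && !is.null(exclude))
        stop("give either 'rsids' or 'exclude', not both")
    if (!is.null(exclude)) {
        unknown <- setdiff(exclude, df$rsid)
        if (length(unknown) > 0L)
            stop("not in panel: ", paste(unknown, collapse = ", "))
        rsids <- setdiff(df$rsid, exclude)
    }
    if (is.null(rsids)) return(panel)
    unknown <- setdiff(rsids, df$rsid)
    if (length(unknown) > 0L)
        stop("not in panel: ", paste(unknown, collapse = ", "))
    if (length(rsids) == 0L)
        stop("subsetting would leave an empty panel")
    TeloPanel(df[df$rsid %in% rsids, , drop = FALSE])
}

#' TeloCohort: genotypes plus phenotypes for a case-control study
#'
#' A \code{TeloCohort} extends \code{SummarizedExperiment}: the
#' \code{"genotypes"} assay is an integer matrix of effect-allele counts
#' (0/1/2, \code{NA} = missing call) with one row per panel SNP and one
#' column per subject; \code{colData} carries the phenotypes
#' (\code{status} case/control, \code{age}, \code{sex}, \code{country},
#' \code{subtype}, \code{jak2}); \code{rowData} carries the panel table.
#'
#' Invariants: subject ids (column names) unique; genotypes in \{0, 1, 2,
#' NA\}; controls have subtype \code{"none"} and cases do not.
#'
#' @seealso [TeloCohort()], [readCohort()], [simulateCaseControl()]
#' @export
setClass("TeloCohort", contains = "SummarizedExperiment")

.PHENO_COLUMNS <- c("status", "age", "sex", "country", "subtype", "jak2")

setValidity("TeloCohort", function(object) {
    msg <- character()
    g <- SummarizedExperiment::assay(object, "genotypes")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated subject ids")
    bad <- !(g %in% c(0L, 1L, 2L, NA))
    if (any(bad)) msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(.PHENO_COLUMNS, colnames(cd))
    if (length(missing_cols) > 0L)
        msg <- c(msg, paste("phenotype columns missing:",
                            paste(missing_cols, collapse = ", ")))
    else {
        if (!all(cd$status %in% c("case", "control")))
            msg <- c(msg, "status must be 'case' or 'control'")
        ctrl <- cd$status == "control"
        if (any(ctrl & !is.na(cd$subtype) & cd$subtype != "none"))
            msg <- c(msg, "controls must have subtype 'none'")
        if (any(!ctrl & !is.na(cd$subtype) & cd$subtype == "none"))
            msg <- c(msg, "cases must not have subtype 'none'")
    }
    if (length(msg) == 0L) TRUE else msg
})

#' Construct a TeloCohort
#'
#' @param genotypes matrix of effect-allele counts, SNPs x subjects (row
#'   names = panel rsids, column names = subject ids) \emph{or} subjects x
#'   SNPs (auto-transposed when the column names match the panel).
#' @param phenotypes data.frame with one row per subject and columns
#'   \code{subject_id}, \code{status}, \code{age}, \code{sex},
#'   \code{country}, \code{subtype}, \code{jak2}.
#' @param panel the \code{TeloPanel} the genotype rows refer to.
#' @return a \code{TeloCohort}
#' @export
TeloCohort <- function(genotypes, phenotypes, panel) {
    stopifnot(is(panel, "TeloPanel"))
    genotypes <- as.matrix(genotypes)
    rsids <- panelRsids(panel)
    if (!setequal(rownames(genotypes), rsids) &&
        setequal(colnames(genotypes), rsids))
        genotypes <- t(genotypes)
    if (!setequal(rownames(genotypes), rsids))
        stop("genotype row names do not match the panel rsids")
    genotypes <- genotypes[rsids, , drop = FALSE]
    storage.mode(genotypes) <- "integer"

    phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
    if (!"subject_id" %in% colnames(phenotypes))
        stop("phenotype table lacks a 'subject_id' column")
    missing_cols <- setdiff(.PHENO_COLUMNS, colnames(phenotypes))
    if (length(missing_cols) > 0L)
        stop("phenotype table lacks columns: ",
             paste(missing_cols, collapse = ", "))
    if (anyDuplicated(phenotypes$subject_id))
        stop("duplicated subject_id in phenotype table")
    if (is.null(colnames(genotypes)))
        stop("genotype matrix lacks subject ids")
    if (!setequal(colnames(genotypes), phenotypes$subject_id))
        stop("genotype and phenotype subject ids do not match")
    rownames(phenotypes) <- phenotypes$subject_id
    phenotypes <- phenotypes[colnames(genotypes), .PHENO_COLUMNS]

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(genotypes = genotypes),
        rowData = S4Vectors::DataFrame(panelTable(panel)),
        colData = S4Vectors::DataFrame(phenotypes))
    new("TeloCohort", se)
}

#' @export
setMethod("show", "TeloCohort", function(object) {
    st <- phenotypes(object)$status
    cat(sprintf("TeloCohort: %d subjects (%d cases / %d controls), %d panel SNPs\n",
                ncol(object), sum(st == "case"), sum(st == "control"),
                nrow(object)))
    g <- genotypes(object)
    cat(sprintf("  overall genotype call rate: %.1f%%\n",
                100 * mean(!is.na(g))))
})

#' Cohort accessors
#'
#' \code{genotypes} returns the SNPs x subjects effect-allele-count matrix,
#' \code{phenotypes} the per-subject phenotype data.frame (with a
#' \code{subject_id} column), \code{cohortPanel} the \code{TeloPanel},
#' \code{nCases}/\code{nControls} the group sizes.
#'
#' @param cohort a \code{TeloCohort}
#' @return matrix, data.frame, TeloPanel, or integer respectively
#' @export
genotypes <- function(cohort) {
    stopifnot(is(cohort, "TeloCohort"))
    SummarizedExperiment::assay(cohort, "genotypes")
}

#' @rdname genotypes
#' @export
phenotypes <- function(cohort) {
    stopifnot(is(cohort, "TeloCohort"))
    df <- as.data.frame(SummarizedExperiment::colData(cohort))
    data.frame(subject_id = colnames(cohort), df,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname genotypes
#' @export
cohortPanel <- function(cohort) {
    stopifnot(is(cohort, "TeloCohort"))
    TeloPanel(as.data.frame(SummarizedExperiment::rowData(cohort)))
}

#' @rdname genotypes
#' @export
nCases <- function(cohort) sum(phenotypes(cohort)$status == "case")

#' @rdname genotypes
#' @export
nControls <- function(cohort) sum(phenotypes(cohort)$status == "control")

#' Restrict a cohort to a subset of subjects or panel SNPs
#'
#' @param cohort a \code{TeloCohort}
#' @param subjects subject ids to keep (default all)
#' @param rsids panel rsids to keep (default all)
#' @return a \code{TeloCohort}
#' @export
subsetCohort <- function(cohort, subjects = NULL, rsids = NULL) {
    stopifnot(is(cohort, "TeloCohort"))
    if (is.null(subjects)) subjects <- colnames(cohort)
    if (is.null(rsids)) rsids <- rownames(cohort)
    unknown <- setdiff(subjects, colnames(cohort))
    if (length(unknown) > 0L)
        stop("unknown subject ids: ", paste(utils::head(unknown, 5), collapse = ", "))
    TeloCohort(genotypes(cohort)[rsids, subjects, drop = FALSE],
               phenotypes(cohort)[match(subjects, colnames(cohort)), ],
               subsetPanel(cohortPanel(cohort), rsids = rsids))
}
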