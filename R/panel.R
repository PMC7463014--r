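# The 11-SNP leukocyte-telomere-length panel. Each row stores the GWAS
# discovery estimate of the per-effect-allele LTL change in SD units and the
# equivalent in base pairs (uniformly beta x 1200 bp/SD across the panel),
# with the effect allele oriented to longer telomeres. Coordinates are
# 1-based GRCh37.
.BUILTIN_PANEL <- data.frame(
    rsid = c("rs412658", "rs8105767", "rs3027234", "rs9420907", "rs755017",
             "rs6028466", "rs7675998", "rs10936599", "rs11125529",
             "rs6772228", "rs2736100"),
    gene = c("ZNF676", "ZNF208", "CTC1", "OBFC1", "ZBTB46", "DHX35", "NAF1",
             "TERC", "ACYP2", "PXK", "TERT"),
    chromosome = c("19", "19", "17", "10", "20", "20", "4", "3", "2", "3", "5"),
    position = c(22359440L, 22032639L, 8232774L, 103916707L, 62421622L,
                 39500359L, 163086668L, 169774313L, 54248729L, 58390292L,
                 1286401L),
    effect_allele = c("T", "G", "C", "C", "G", "A", "G", "C", "A", "T", "C"),
    other_allele  = c("C", "A", "T", "A", "A", "G", "A", "T", "C", "A", "A"),
    eaf  = c(0.35, 0.28, 0.78, 0.13, 0.12, 0.07, 0.76, 0.76, 0.11, 0.96, 0.50),
    beta = c(0.086, 0.064, 0.103, 0.142, 0.019, 0.058, 0.048, 0.100, 0.065,
             0.041, 0.085),
    beta_se = c(0.010, 0.011, 0.012, 0.014, 0.013, 0.013, 0.012, 0.011,
                0.012, 0.014, 0.013),
    bp_per_allele = c(103.2, 76.8, 123.6, 170.4, 22.8, 69.6, 57.6, 120.0,
                      78.0, 49.2, 102.0),
    discovery_pvalue = c(1.00e-8, 1.11e-9, 2.00e-8, 7.00e-11, 6.71e-9,
                         2.57e-8, 4.35e-16, 3.00e-31, 8.00e-10, 3.91e-10,
                         4.38e-19),
    discovery_study = c("Mangino", "Codd", "Mangino", "Levy", "Codd",
                        "Haycock", "Codd", "Codd", "Codd", "Haycock", "Codd"),
    stringsAsFactors = FALSE)

# bp-per-SD conversion implied by every panel row
.BP_PER_SD <- 1200

#' The built-in 11-SNP telomere-length panel
#'
#' Returns the fixed panel of 11 GWAS-discovered SNPs associated with
#' leukocyte telomere length, with effect alleles oriented to longer
#' telomeres, effect-allele frequencies, SD-scale effect sizes and the
#' per-allele weights in base pairs used by [teloscores()].
#'
#' @return a \linkS4class{TeloPanel} of 11 SNPs
#' @examples
#' panel <- builtinPanel()
#' sum(panelWeights(panel))   # 973.2 bp summed over the panel
#' @export
builtinPanel <- function() TeloPanel(.BUILTIN_PANEL)

#' Convert an SD-scale telomere-length effect to base pairs
#'
#' The panel's base-pair weights are the SD-scale effect sizes multiplied by
#' a uniform 1200 bp per SD, the conversion implied by every built-in panel
#' row at printed precision.
#'
#' @param beta per-allele effect in SD units (finite numeric)
#' @return per-allele effect in base pairs (\code{beta * 1200})
#' @examples
#' bpFromBeta(0.142)  # 170.4, the OBFC1 rs9420907 weight
#' @export
bpFromBeta <- function(beta) {
    stopifnot(is.numeric(beta), all(is.finite(beta)))
    beta * .BP_PER_SD
}

#' Validate a SNP panel
#'
#' Checks every panel invariant and returns a character vector of issues
#' (empty when the panel is valid): allele frequencies strictly inside (0,1),
#' distinct effect/other alleles, non-negative long-telomere-oriented betas,
#' unique rsids, and base-pair weights consistent with \code{beta * 1200}
#' within 0.05 bp.
#'
#' @param panel a \linkS4class{TeloPanel}, or a data.frame with panel columns
#' @param builtin when TRUE also require exactly 11 entries
#' @return character vector of human-readable issues; \code{character(0)} if
#'   the panel is valid
#' @export
validatePanel <- function(panel, builtin = FALSE) {
    df <- if (is(panel, "TeloPanel")) panel@snps else as.data.frame(panel)
    issues <- character()
    if (anyDuplicated(df$rsid))
        issues <- c(issues, "duplicated rsids")
    if (builtin && nrow(df) != 11L)
        issues <- c(issues, sprintf("builtin panel must have 11 entries, found %d",
                                    nrow(df)))
    if (nrow(df) == 0L)
        issues <- c(issues, "empty panel")
    bad_eaf <- !is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1
    if (any(bad_eaf))
        issues <- c(issues, paste0("eaf out of range for ",
                                   paste(df$rsid[bad_eaf], collapse = ", ")))
    same <- df$effect_allele == df$other_allele
    if (any(same))
        issues <- c(issues, paste0("effect and other allele identical for ",
                                   paste(df$rsid[same], collapse = ", ")))
    neg <- is.finite(df$beta) & df$beta < 0
    if (any(neg))
        issues <- c(issues, paste0("beta negative (weights must be oriented to the long-telomere allele) for ",
                                   paste(df$rsid[neg], collapse = ", ")))
    incons <- abs(df$bp_per_allele - bpFromBeta(df$beta)) > 0.05
    if (any(incons))
        issues <- c(issues, paste0("weight inconsistent (bp_per_allele != beta x 1200) for ",
                                   paste(df$rsid[incons], collapse = ", ")))
    issues
}

#' Read / write a panel as a tab-separated file
#'
#' The on-disk format has one header row with the panel column names
#' (\code{rsid}, \code{gene}, \code{chromosome}, \code{position},
#' \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#' \code{beta_se}, \code{bp_per_allele}, \code{discovery_pvalue},
#' \code{discovery_study}) and one row per SNP.
#'
#' @param path file path
#' @return \code{readPanel} returns a \linkS4class{TeloPanel};
#'   \code{writePanel} returns \code{path} invisibly.
#' @export
readPanel <- function(path) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(chromosome = "character"))
    TeloPanel(df)
}

#' @rdname readPanel
#' @param panel a \linkS4class{TeloPanel} to write
#' @export
writePanel <- function(panel, path) {
    utils::write.table(panelTable(panel), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
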