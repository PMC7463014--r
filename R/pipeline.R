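# End-to-end analysis pipeline and the command entry points behind the
# inst/scripts/teloscore-cli.R wrapper. QC ordering follows the study design:
# call-rate exclusions happen before HWE reporting and score computation.

#' Run the full teloscore case-control analysis
#'
#' Stages, in order: call-rate filter (default: keep subjects with >= 8 of
#' 11 SNPs called) -> Hardy-Weinberg report in retained controls -> raw and
#' scaled teloscores -> control quintile cutpoints -> quintile association
#' (categorical + per-quintile trend) -> per-SNP association (allelic +
#' codominant by default) with the Bonferroni threshold over SNPs x models
#' -> optional JAK2/subtype strata and leave-one-out score analyses.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param min_called call-rate filter threshold (called SNPs)
#' @param score_variant headline score: \code{"scaled"} (all subjects,
#'   default) or \code{"raw"} (100\% call-rate subjects)
#' @param models genetic models for the per-SNP analysis
#' @param covariates adjustment covariates
#' @param stratify optional stratification variables (subset of
#'   \code{c("jak2", "subtype")})
#' @param exclude_snps rsids excluded from the score (a leave-one-out
#'   quintile analysis is added for each)
#' @param cutpoints \code{"per-stratum"} or \code{"overall"} quintile
#'   cutpoints for stratified runs
#' @param min_subjects abort when QC retains fewer subjects than this
#' @return object of class \code{teloAnalysis}: a list with the QC log, HWE
#'   table, per-subject scores + quintiles, cutpoints, association tables,
#'   Bonferroni threshold, any strata / leave-one-out tables, and a
#'   \code{flagged_fits} indicator
#' @export
analyzeCohort <- function(cohort, min_called = 8L,
                          score_variant = c("scaled", "raw"),
                          models = c("allelic", "codominant"),
                          covariates = c("age", "sex", "country"),
                          stratify = character(),
                          exclude_snps = character(),
                          cutpoints = c("per-stratum", "overall"),
                          min_subjects = 50L) {
    score_variant <- match.arg(score_variant)
    cutpoints <- match.arg(cutpoints)
    n_in <- ncol(cohort)
    message("QC: ", n_in, " subjects in (",
            nCases(cohort), " cases / ", nControls(cohort), " controls)")

    qc <- filterByCallRate(cohort, min_called = min_called)
    kept <- qc$cohort
    message("QC: excluded ", sum(qc$excluded$status == "case"), " cases and ",
            sum(qc$excluded$status == "control"),
            " controls with fewer than ", min_called, " called SNPs; ",
            nCases(kept), " cases / ", nControls(kept), " controls retained")
    if (ncol(kept) < min_subjects)
        stop("QC abort: only ", ncol(kept), " subjects retained (< ",
             min_subjects, ")")

    hwe <- hweControls(kept)
    message("QC: ", sum(hwe$in_hwe, na.rm = TRUE), " of ", nrow(hwe),
            " SNPs in HWE in controls (exact test, alpha 0.05)")

    scores <- teloscores(kept, exclude = exclude_snps)
    n_scored <- length(setdiff(rownames(kept), exclude_snps))
    mean_cr <- mean(scores$n_called) / n_scored
    message(sprintf("Scores: mean genotyping call rate %.1f%%; %d subjects fully called",
                    100 * mean_cr, sum(scores$n_called == n_scored)))

    quintiles <- quintileAssociation(kept, score_variant = score_variant,
                                     covariates = covariates,
                                     exclude = exclude_snps)
    cuts <- attr(quintiles, "cutpoints")
    scores$quintile <- assignQuintile(
        if (score_variant == "scaled") scores$scaled_score else scores$raw_score,
        cuts)

    snps <- allSnpAssociations(kept, models = models, covariates = covariates)
    thr <- attr(snps, "bonferroni_threshold")
    message("Association: Bonferroni threshold ",
            signif(thr, 2), " over ", nrow(kept), " x ", length(models),
            " tests")

    strata <- list()
    for (v in stratify)
        strata[[v]] <- list(
            quintile = stratifiedAssociation(kept, v, "quintile",
                                             cutpoints = cutpoints,
                                             score_variant = score_variant,
                                             covariates = covariates),
            snp = stratifiedAssociation(kept, v, "snp",
                                        models = models,
                                        covariates = covariates))

    flagged <- any(quintiles$flagged & is.na(quintiles$note), na.rm = TRUE) ||
        any(snps$flagged & is.na(snps$note), na.rm = TRUE)

    structure(list(n_input = n_in,
                   qc_excluded = qc$excluded,
                   min_called = min_called,
                   mean_call_rate = mean_cr,
                   hwe = hwe,
                   scores = scores,
                   cutpoints = cuts,
                   score_variant = score_variant,
                   quintile_association = quintiles,
                   snp_association = snps,
                   bonferroni_threshold = thr,
                   strata = strata,
                   excluded_snps = exclude_snps,
                   n_cases = nCases(kept), n_controls = nControls(kept),
                   flagged_fits = flagged),
              class = "teloAnalysis")
}

#' @export
print.teloAnalysis <- function(x, ...) {
    cat(renderReport(x), sep = "\n")
    invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Writes full-precision TSVs (qc_exclusions, hwe_controls, scores,
#' quintile_association, snp_association, one table per stratified analysis)
#' plus a plain-text quintile/per-SNP report.
#'
#' @param analysis a \code{teloAnalysis}
#' @param dir output directory
#' @return invisibly, the directory
#' @export
writeAnalysis <- function(analysis, dir) {
    stopifnot(is(analysis, "teloAnalysis"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name)
        utils::write.table(df, file.path(dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "")
    w(analysis$qc_excluded, "qc_exclusions.tsv")
    w(analysis$hwe, "hwe_controls.tsv")
    w(analysis$scores, "scores.tsv")
    w(analysis$quintile_association, "quintile_association.tsv")
    w(analysis$snp_association, "snp_association.tsv")
    for (v in names(analysis$strata)) {
        w(analysis$strata[[v]]$quintile,
          paste0("quintile_association_by_", v, ".tsv"))
        w(analysis$strata[[v]]$snp, paste0("snp_association_by_", v, ".tsv"))
    }
    writeLines(renderReport(analysis), file.path(dir, "report.txt"))
    invisible(dir)
}

.fmtOR <- function(or, lo, hi) {
    ifelse(is.na(or), "-",
           ifelse(or == 1 & is.na(lo), "1 - Ref.",
                  sprintf("%.2f (%.2f-%.2f)", or, lo, hi)))
}
.fmtP <- function(p) ifelse(is.na(p), "-", sprintf("%.2e", p))

#' Render a human-readable analysis report
#'
#' QC narrative plus rounded association tables (ORs to 2 decimal places,
#' p-values in scientific notation), with the reference quintile shown as
#' "1 - Ref." in the quintile section.
#'
#' @param analysis a \code{teloAnalysis}
#' @return character vector of report lines
#' @export
renderReport <- function(analysis) {
    stopifnot(is(analysis, "teloAnalysis"))
    out <- c("Teloscore case-control analysis",
             "===============================",
             sprintf("Subjects in: %d; excluded at call-rate filter (<%d of %d SNPs): %d cases, %d controls",
                     analysis$n_input, analysis$min_called,
                     nrow(analysis$hwe),
                     sum(analysis$qc_excluded$status == "case"),
                     sum(analysis$qc_excluded$status == "control")),
             sprintf("Retained: %d cases / %d controls; mean call rate %.1f%%",
                     analysis$n_cases, analysis$n_controls,
                     100 * analysis$mean_call_rate),
             sprintf("HWE (exact, controls): %d of %d SNPs with p >= 0.05; min p = %.3g",
                     sum(analysis$hwe$in_hwe, na.rm = TRUE),
                     nrow(analysis$hwe), min(analysis$hwe$p_hwe, na.rm = TRUE)),
             "")
    if (length(analysis$excluded_snps) > 0L)
        out <- c(out, paste("Score computed without:",
                            paste(analysis$excluded_snps, collapse = ", ")), "")
    q <- analysis$quintile_association
    out <- c(out,
             sprintf("Quintile association (%s score, cutpoints %s):",
                     analysis$score_variant,
                     paste(sprintf("%.2f", analysis$cutpoints), collapse = ", ")),
             sprintf("  %-24s %-22s %s", "term", "OR (95% CI)", "p"))
    for (i in seq_len(nrow(q)))
        out <- c(out, sprintf("  %-24s %-22s %s", q$term[i],
                              .fmtOR(q$odds_ratio[i], q$ci_low[i], q$ci_high[i]),
                              .fmtP(q$p_value[i])))
    s <- analysis$snp_association
    out <- c(out, "",
             sprintf("Per-SNP association (Bonferroni threshold %.4f):",
                     analysis$bonferroni_threshold),
             sprintf("  %-11s %-7s %-8s %-24s %-22s %-10s %s",
                     "rsid", "gene", "alleles", "term", "OR (95% CI)", "p", ""))
    for (i in seq_len(nrow(s)))
        out <- c(out, sprintf("  %-11s %-7s %-8s %-24s %-22s %-10s %s",
                              s$rsid[i], s$gene[i], s$alleles[i], s$term[i],
                              .fmtOR(s$odds_ratio[i], s$ci_low[i], s$ci_high[i]),
                              .fmtP(s$p_value[i]),
                              ifelse(isTRUE(s$significant_bonferroni[i]), "*", "")))
    for (v in names(analysis$strata)) {
        sq <- analysis$strata[[v]]$quintile
        out <- c(out, "", paste0("Stratified quintile association (", v, "):"))
        for (i in seq_len(nrow(sq)))
            out <- c(out, sprintf("  %-18s %-24s %-22s %s", sq$stratum[i],
                                  sq$term[i],
                                  .fmtOR(sq$odds_ratio[i], sq$ci_low[i],
                                         sq$ci_high[i]),
                                  .fmtP(sq$p_value[i])))
    }
    out
}

.manifest <- function(command, seed, inputs = character(), options = list()) {
    digests <- if (length(inputs) > 0L)
        as.list(tools::md5sum(inputs)) else list()
    list(command = command,
         package = "teloscore",
         version = as.character(utils::packageVersion("teloscore")),
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input_digests = digests,
         options = options)
}

.writeManifest <- function(manifest, dir) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(file.path(dir, "manifest.json"))
}

#' Command: simulate a cohort to disk
#'
#' Validates the configuration, simulates a cohort, and writes the
#' genotype/phenotype TSVs, the truth sidecar and a run manifest recording
#' the seed, config snapshot and output digests.
#'
#' @param config a \code{teloSimConfig}, or a path to a YAML config file
#' @param output_dir directory to write into
#' @param seed optional seed overriding the config's
#' @return invisibly, a list with the output paths and the exit status (0
#'   success, 2 validation error is raised as a condition of class
#'   \code{teloValidationError})
#' @export
cmdSimulate <- function(config, output_dir, seed = NULL) {
    if (is.character(config)) config <- readSimConfig(config, seed = seed)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    issues <- validateSimConfig(config)
    if (length(issues) > 0L || is.null(config$seed))
        stop(structure(class = c("teloValidationError", "error", "condition"),
                       list(message = paste0(
                                "invalid simulation config:\n  ",
                                paste(c(issues,
                                        if (is.null(config$seed)) "seed must be set"),
                                      collapse = "\n  ")),
                            call = sys.call())))
    sim <- simulateCaseControl(config)
    paths <- writeSimulation(sim, output_dir)
    cfg_snapshot <- config[setdiff(names(config), c("panel", "model"))]
    cfg_snapshot$model <- unclass(config$model)
    cfg_snapshot$panel_rsids <- panelRsids(config$panel)
    manifest <- .manifest("simulate", config$seed, inputs = paths,
                          options = cfg_snapshot)
    .writeManifest(manifest, output_dir)
    invisible(list(paths = paths, status = 0L))
}

#' Command: analyze a cohort from disk
#'
#' Reads the genotype/phenotype tables, runs [analyzeCohort()], and writes
#' the results tables, report and manifest. Mirrors the pipeline's exit-code
#' contract: status 0 on success, 3 when QC aborts, 4 when any fit is
#' flagged (results are still written).
#'
#' @param genotype_path,phenotype_path input TSVs (see [readCohort()])
#' @param output_dir directory to write results into
#' @param panel the \linkS4class{TeloPanel} (default built-in)
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic)
#' @param ... passed to [analyzeCohort()]
#' @return invisibly, a list with the \code{teloAnalysis} and \code{status}
#' @export
cmdAnalyze <- function(genotype_path, phenotype_path, output_dir,
                       panel = builtinPanel(), seed = NULL, ...) {
    cohort <- readCohort(genotype_path, phenotype_path, panel)
    analysis <- tryCatch(analyzeCohort(cohort, ...),
                         error = function(e) e)
    if (inherits(analysis, "error")) {
        if (grepl("^QC abort", conditionMessage(analysis)))
            return(invisible(list(analysis = NULL, status = 3L,
                                  message = conditionMessage(analysis))))
        stop(analysis)
    }
    writeAnalysis(analysis, output_dir)
    manifest <- .manifest("analyze", seed,
                          inputs = c(genotype_path, phenotype_path),
                          options = list(min_called = analysis$min_called,
                                         score_variant = analysis$score_variant,
                                         excluded_snps = analysis$excluded_snps))
    .writeManifest(manifest, output_dir)
    status <- if (analysis$flagged_fits) 4L else 0L
    invisible(list(analysis = analysis, status = status))
}

#' Command: render the report for a results directory
#'
#' @param results_dir directory written by [cmdAnalyze()]
#' @return the report lines (also printed), invisibly
#' @export
cmdReport <- function(results_dir) {
    needed <- c("quintile_association.tsv", "snp_association.tsv",
                "report.txt")
    for (f in needed) {
        p <- file.path(results_dir, f)
        if (!file.exists(p)) stop("missing results file: ", p)
    }
    lines <- readLines(file.path(results_dir, "report.txt"))
    cat(lines, sep = "\n")
    invisible(lines)
}
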