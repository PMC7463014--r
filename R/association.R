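# Covariate-adjusted unconditional logistic regression for the score
# quintiles (categorical contrasts vs the lowest bin plus a per-quintile
# trend term) and for individual SNPs under allelic, codominant, dominant
# and recessive genetic models, with Wald CIs and Bonferroni thresholding.

#' Fit an unconditional logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via \code{stats::glm}, convergence
#' tolerance 1e-10, at most 100 iterations). The fit is flagged unreliable on
#' non-convergence or quasi-separation (any |coefficient| > 15).
#'
#' @param formula model formula; the response must be binary (logical or
#'   0/1)
#' @param data data.frame of model variables
#' @return object of class \code{teloFit}: list with \code{coefficients},
#'   \code{standard_errors}, \code{vcov}, \code{converged}, \code{flagged},
#'   \code{flag_reason}, \code{n_used}, \code{log_likelihood} and the
#'   underlying \code{glm} fit
#' @export
fitLogistic <- function(formula, data) {
    mf <- stats::model.frame(formula, data = data)
    y <- stats::model.response(mf)
    if (is.factor(y)) y <- as.integer(y) - 1L
    y <- as.numeric(y)
    if (length(unique(y)) < 2L)
        stop("degenerate outcome: only one class present")
    fit <- suppressWarnings(
        stats::glm(formula, data = data, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    coefs <- stats::coef(fit)
    vc <- stats::vcov(fit)
    se <- sqrt(diag(vc))
    flagged <- FALSE
    reason <- NA_character_
    if (!fit$converged) {
        flagged <- TRUE; reason <- "did not converge"
    } else if (any(abs(coefs[-1]) > 15, na.rm = TRUE)) {
        flagged <- TRUE; reason <- "quasi-separation (|coef| > 15)"
    }
    structure(list(coefficients = coefs, standard_errors = se, vcov = vc,
                   converged = fit$converged, flagged = flagged,
                   flag_reason = reason, n_used = stats::nobs(fit),
                   log_likelihood = as.numeric(stats::logLik(fit)),
                   glm = fit),
              class = "teloFit")
}

#' @export
print.teloFit <- function(x, ...) {
    cat("Logistic fit:", x$n_used, "subjects, logLik", round(x$log_likelihood, 2),
        if (x$flagged) paste0("[FLAGGED: ", x$flag_reason, "]") else "", "\n")
    print(round(cbind(coef = x$coefficients, se = x$standard_errors), 4))
    invisible(x)
}

# Wald OR, 95% CI and two-sided p for one fitted term
.waldRow <- function(fit, coef_name, term, model, stratum, n_cases, n_controls,
                     note = NA_character_) {
    b <- fit$coefficients[coef_name]
    se <- fit$standard_errors[coef_name]
    z <- b / se
    data.frame(stratum = stratum, model = model, term = term,
               n_cases = n_cases, n_controls = n_controls,
               odds_ratio = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p_value = 2 * stats::pnorm(-abs(z)),
               flagged = fit$flagged, note = note,
               stringsAsFactors = FALSE, row.names = NULL)
}

.emptyRow <- function(term, model, stratum, n_cases = NA_integer_,
                      n_controls = NA_integer_, note, flagged = TRUE) {
    data.frame(stratum = stratum, model = model, term = term,
               n_cases = n_cases, n_controls = n_controls,
               odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p_value = NA_real_, flagged = flagged, note = note,
               stringsAsFactors = FALSE, row.names = NULL)
}

# Phenotypes prepared for modeling: binary outcome, covariates complete-case,
# factor covariates releveled to the largest control category. Covariates
# constant across modeled subjects are inestimable and dropped with a
# message; the retained set is attached as attr "covariates".
.modelFrame <- function(cohort, covariates) {
    ph <- phenotypes(cohort)
    ph$y <- as.integer(ph$status == "case")
    unknown <- setdiff(covariates, colnames(ph))
    if (length(unknown) > 0L)
        stop("covariates not in phenotypes: ", paste(unknown, collapse = ", "))
    keep <- stats::complete.cases(ph[, covariates, drop = FALSE])
    n_dropped <- sum(!keep)
    if (n_dropped > 0L)
        message(n_dropped, " subject(s) with missing covariates excluded from the fit")
    ph <- ph[keep, , drop = FALSE]
    constant <- vapply(covariates,
                       function(v) length(unique(ph[[v]])) < 2L, logical(1))
    if (any(constant)) {
        message("constant covariate(s) dropped from the fit: ",
                paste(covariates[constant], collapse = ", "))
        covariates <- covariates[!constant]
    }
    for (v in covariates) {
        if (is.character(ph[[v]]) || is.factor(ph[[v]])) {
            tab <- table(ph[[v]][ph$status == "control"])
            ref <- if (length(tab) > 0L && sum(tab) > 0L)
                names(tab)[which.max(tab)] else levels(factor(ph[[v]]))[1]
            ph[[v]] <- stats::relevel(factor(ph[[v]]), ref = ref)
        }
    }
    attr(ph, "n_dropped_covariates") <- n_dropped
    attr(ph, "covariates") <- covariates
    ph
}

.covariateTerms <- function(covariates)
    if (length(covariates) == 0L) "1" else paste(covariates, collapse = " + ")

#' Quintile association between the teloscore and case status
#'
#' Distributes subjects into quintiles of the control score distribution and
#' fits two adjusted logistic models: a categorical model with indicator
#' terms for bins 2-5 (bin 1 reference) and a trend model entering the
#' quintile index 1-5 as a single numeric term ("per-quintile" increment).
#'
#' @param cohort a \linkS4class{TeloCohort} (already QC-filtered)
#' @param score_variant \code{"scaled"} (default: scaled teloscore, all
#'   subjects with >= 1 called genotype) or \code{"raw"} (unscaled score,
#'   subjects with a 100\% call rate only)
#' @param cutpoints optional pre-computed cutpoints; by default the
#'   20/40/60/80th percentiles of the modeled controls' scores
#' @param covariates adjustment covariates (default age, sex, country)
#' @param exclude rsids dropped from the panel before scoring
#'   (leave-one-out analyses)
#' @param stratum label recorded in the results (default "all")
#' @return data.frame of association results: one row per quintile (bin 1 =
#'   reference) plus the per-quintile trend term, with OR, 95\% Wald CI,
#'   p-value and flags; the cutpoints used are attached as attribute
#'   \code{"cutpoints"}
#' @export
quintileAssociation <- function(cohort, score_variant = c("scaled", "raw"),
                                cutpoints = NULL,
                                covariates = c("age", "sex", "country"),
                                exclude = character(), stratum = "all") {
    score_variant <- match.arg(score_variant)
    sc <- teloscores(cohort, exclude = exclude)
    ph <- .modelFrame(cohort, covariates)
    covariates <- attr(ph, "covariates")
    df <- merge(ph, sc, by = "subject_id")
    df$score <- if (score_variant == "scaled") df$scaled_score else df$raw_score
    df <- df[!is.na(df$score), , drop = FALSE]
    if (length(unique(df$y)) < 2L)
        stop("degenerate outcome: need both cases and controls with scores")
    if (is.null(cutpoints))
        cutpoints <- controlQuintileCutpoints(df$score[df$y == 0])
    df$quintile <- assignQuintile(df$score, cutpoints)
    n_cases <- sum(df$y); n_controls <- sum(1 - df$y)

    rows <- list(.emptyRow("quintile 1", "quintile", stratum,
                           sum(df$y & df$quintile == 1),
                           sum(!df$y & df$quintile == 1),
                           note = "reference", flagged = FALSE))
    rows[[1]]$odds_ratio <- 1
    present <- sort(unique(df$quintile))
    df$qf <- factor(df$quintile, levels = present)
    form <- stats::as.formula(paste("y ~ qf +", .covariateTerms(covariates)))
    fit <- fitLogistic(form, df)
    for (k in 2:5) {
        term <- paste("quintile", k)
        nk_case <- sum(df$y & df$quintile == k)
        nk_ctrl <- sum(!df$y & df$quintile == k)
        if (!k %in% present || nk_case + nk_ctrl == 0L) {
            rows[[length(rows) + 1L]] <-
                .emptyRow(term, "quintile", stratum, nk_case, nk_ctrl,
                          note = "empty quintile bin; contrast not estimable")
        } else {
            rows[[length(rows) + 1L]] <-
                .waldRow(fit, paste0("qf", k), term, "quintile", stratum,
                         nk_case, nk_ctrl)
        }
    }
    form_c <- stats::as.formula(paste("y ~ quintile +", .covariateTerms(covariates)))
    fit_c <- fitLogistic(form_c, df)
    rows[[length(rows) + 1L]] <-
        .waldRow(fit_c, "quintile", "per-quintile increment", "continuous",
                 stratum, n_cases, n_controls)
    out <- do.call(rbind, rows)
    attr(out, "cutpoints") <- cutpoints
    attr(out, "score_variant") <- score_variant
    out
}

#' Single-SNP case-control association
#'
#' Fits adjusted logistic regressions for one panel SNP under the requested
#' genetic models. Genotypes are coded on the minor allele (determined in
#' controls; a tie at 0.5 resolves to the panel's other allele), or on the
#' panel effect allele with \code{coding = "effect"}:
#' \describe{
#'   \item{allelic}{log-additive: one term counting coded-allele copies 0/1/2}
#'   \item{codominant}{two contrasts: heterozygote vs common homozygote, and
#'     rare homozygote vs common homozygote}
#'   \item{dominant}{carrier of >= 1 coded allele vs common homozygote}
#'   \item{recessive}{coded-allele homozygote vs all other subjects}
#' }
#' A codominant rare-homozygote contrast with an empty case or control cell
#' is omitted with a note rather than fitted.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param rsid panel SNP to test
#' @param models subset of allelic/codominant/dominant/recessive
#' @param covariates adjustment covariates
#' @param coding count the control-determined minor allele (default) or the
#'   panel effect allele
#' @param stratum label recorded in the results
#' @return data.frame of association results (one row per model contrast)
#' @export
snpAssociation <- function(cohort, rsid,
                           models = c("allelic", "codominant"),
                           covariates = c("age", "sex", "country"),
                           coding = c("minor", "effect"), stratum = "all") {
    coding <- match.arg(coding)
    models <- match.arg(models, c("allelic", "codominant", "dominant",
                                  "recessive"), several.ok = TRUE)
    g_all <- genotypes(cohort)
    if (!rsid %in% rownames(g_all)) stop("not a panel SNP: ", rsid)
    ph <- .modelFrame(cohort, covariates)
    covariates <- attr(ph, "covariates")
    g <- g_all[rsid, match(ph$subject_id, colnames(g_all))]
    ph$g <- as.integer(g)
    df <- ph[!is.na(ph$g), , drop = FALSE]
    if (nrow(df) == 0L || length(unique(df$g)) < 2L)
        stop("monomorphic or uncalled SNP among modeled subjects: ", rsid)
    if (length(unique(df$y)) < 2L)
        stop("degenerate outcome for ", rsid)

    prow <- panelTable(cohortPanel(cohort))
    prow <- prow[prow$rsid == rsid, ]
    ctrl_g <- df$g[df$y == 0]
    f_ea <- if (length(ctrl_g) > 0) sum(ctrl_g) / (2 * length(ctrl_g)) else 0.5
    minor_is_effect <- f_ea < 0.5   # tie -> panel other allele is minor
    if (coding == "minor") {
        df$m <- if (minor_is_effect) df$g else 2L - df$g
        coded <- if (minor_is_effect) prow$effect_allele else prow$other_allele
        common <- if (minor_is_effect) prow$other_allele else prow$effect_allele
    } else {
        df$m <- df$g
        coded <- prow$effect_allele
        common <- prow$other_allele
    }
    allele_label <- paste0(common, "/", coded)
    n_cases <- sum(df$y); n_controls <- sum(1 - df$y)
    cv <- .covariateTerms(covariates)
    rows <- list()

    if ("allelic" %in% models) {
        fit <- fitLogistic(stats::as.formula(paste("y ~ m +", cv)), df)
        rows[[length(rows) + 1L]] <-
            .waldRow(fit, "m", "per-allele", "allelic", stratum,
                     n_cases, n_controls)
    }
    if ("codominant" %in% models) {
        het_cells <- c(sum(df$y & df$m == 1L), sum(!df$y & df$m == 1L))
        hom_cells <- c(sum(df$y & df$m == 2L), sum(!df$y & df$m == 2L))
        drop_hom <- any(hom_cells == 0L)
        df$het <- as.integer(df$m == 1L)
        df$hom <- as.integer(df$m == 2L)
        form <- if (drop_hom) paste("y ~ het +", cv) else paste("y ~ het + hom +", cv)
        dfit <- if (drop_hom) df[df$m != 2L, , drop = FALSE] else df
        if (any(het_cells == 0L)) {
            rows[[length(rows) + 1L]] <-
                .emptyRow("het vs common hom", "codominant", stratum,
                          het_cells[1], het_cells[2],
                          note = "empty heterozygote cell; contrast omitted")
        } else {
            fit <- fitLogistic(stats::as.formula(form), dfit)
            rows[[length(rows) + 1L]] <-
                .waldRow(fit, "het", "het vs common hom", "codominant",
                         stratum, n_cases, n_controls)
        }
        if (drop_hom) {
            rows[[length(rows) + 1L]] <-
                .emptyRow("rare hom vs common hom", "codominant", stratum,
                          hom_cells[1], hom_cells[2],
                          note = "empty rare-homozygote cell; contrast omitted")
        } else {
            fit <- fitLogistic(stats::as.formula(form), dfit)
            rows[[length(rows) + 1L]] <-
                .waldRow(fit, "hom", "rare hom vs common hom", "codominant",
                         stratum, n_cases, n_controls)
        }
    }
    if ("dominant" %in% models) {
        df$carrier <- as.integer(df$m >= 1L)
        if (length(unique(df$carrier)) < 2L) {
            rows[[length(rows) + 1L]] <-
                .emptyRow("carrier vs common hom", "dominant", stratum,
                          note = "no contrast: all subjects same carrier status")
        } else {
            fit <- fitLogistic(stats::as.formula(paste("y ~ carrier +", cv)), df)
            rows[[length(rows) + 1L]] <-
                .waldRow(fit, "carrier", "carrier vs common hom", "dominant",
                         stratum, n_cases, n_controls)
        }
    }
    if ("recessive" %in% models) {
        df$hom2 <- as.integer(df$m == 2L)
        if (any(c(sum(df$y & df$hom2 == 1L), sum(!df$y & df$hom2 == 1L)) == 0L)) {
            rows[[length(rows) + 1L]] <-
                .emptyRow("rare hom vs others", "recessive", stratum,
                          note = "empty rare-homozygote cell; contrast omitted")
        } else {
            fit <- fitLogistic(stats::as.formula(paste("y ~ hom2 +", cv)), df)
            rows[[length(rows) + 1L]] <-
                .waldRow(fit, "hom2", "rare hom vs others", "recessive",
                         stratum, n_cases, n_controls)
        }
    }
    out <- do.call(rbind, rows)
    cbind(data.frame(rsid = rsid, gene = prow$gene, alleles = allele_label,
                     maf = min(f_ea, 1 - f_ea), stringsAsFactors = FALSE),
          out)
}

#' Per-SNP association across the whole panel
#'
#' Runs [snpAssociation()] for every panel SNP and flags Bonferroni
#' significance at \code{alpha / (n SNPs x n models)}.
#'
#' @inheritParams snpAssociation
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @return data.frame with one row per SNP and model contrast, including a
#'   \code{significant_bonferroni} flag; the threshold is attached as
#'   attribute \code{"bonferroni_threshold"}
#' @export
allSnpAssociations <- function(cohort, models = c("allelic", "codominant"),
                               covariates = c("age", "sex", "country"),
                               coding = c("minor", "effect"),
                               stratum = "all", alpha = 0.05) {
    coding <- match.arg(coding)
    rsids <- rownames(genotypes(cohort))
    res <- lapply(rsids, function(rs) {
        tryCatch(snpAssociation(cohort, rs, models = models,
                                covariates = covariates, coding = coding,
                                stratum = stratum),
                 error = function(e)
                     cbind(data.frame(rsid = rs, gene = NA_character_,
                                      alleles = NA_character_, maf = NA_real_,
                                      stringsAsFactors = FALSE),
                           .emptyRow("not tested", models[1], stratum,
                                     note = conditionMessage(e))))
    })
    out <- do.call(rbind, res)
    thr <- bonferroniThreshold(length(rsids), length(models), alpha)
    out$significant_bonferroni <- !is.na(out$p_value) & out$p_value < thr
    attr(out, "bonferroni_threshold") <- thr
    out
}

#' Bonferroni significance threshold
#'
#' @param n_snps number of SNPs tested
#' @param n_models number of genetic models per SNP
#' @param alpha family-wise error rate (default 0.05)
#' @return \code{alpha / (n_snps * n_models)}; for the 11-SNP panel under
#'   allelic + codominant models this is 0.05/22 = 0.0023 (4 dp)
#' @export
bonferroniThreshold <- function(n_snps, n_models, alpha = 0.05) {
    stopifnot(n_snps >= 1, n_models >= 1)
    alpha / (n_snps * n_models)
}

#' Stratified association analyses
#'
#' Repeats the quintile or per-SNP analysis restricting \emph{cases} to each
#' level of a stratification variable (JAK2 V617F status or MPN subtype)
#' while keeping all controls, as in stratified case-control designs with
#' shared controls. Strata with fewer than 10 cases are computed but
#' flagged; strata with no cases are reported without a fit.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param stratum_variable \code{"jak2"} or \code{"subtype"}
#' @param analysis \code{"quintile"} or \code{"snp"}
#' @param cutpoints \code{"per-stratum"} (default: quintile cutpoints
#'   re-derived from each analysis's controls) or \code{"overall"} (cutpoints
#'   fixed from the full cohort's controls)
#' @param ... passed to [quintileAssociation()] or [allSnpAssociations()]
#' @return data.frame of association results labeled by stratum
#' @export
stratifiedAssociation <- function(cohort,
                                  stratum_variable = c("jak2", "subtype"),
                                  analysis = c("quintile", "snp"),
                                  cutpoints = c("per-stratum", "overall"),
                                  ...) {
    stratum_variable <- match.arg(stratum_variable)
    analysis <- match.arg(analysis)
    cutpoints <- match.arg(cutpoints)
    ph <- phenotypes(cohort)
    vals <- ph[[stratum_variable]][ph$status == "case"]
    levels_ <- sort(unique(vals[!is.na(vals) & vals != "unknown"]))
    if (length(levels_) == 0L)
        stop("no usable case strata for ", stratum_variable)
    overall_cuts <- NULL
    if (cutpoints == "overall" && analysis == "quintile") {
        sc <- teloscores(cohort)
        overall_cuts <- controlQuintileCutpoints(
            sc$scaled_score[phenotypes(cohort)$status == "control"])
    }
    res <- lapply(levels_, function(lev) {
        label <- paste0(stratum_variable, "=", lev)
        case_ids <- ph$subject_id[ph$status == "case" &
                                  !is.na(ph[[stratum_variable]]) &
                                  ph[[stratum_variable]] == lev]
        if (length(case_ids) == 0L)
            return(.emptyRow("not tested", analysis, label,
                             n_cases = 0L, note = "no cases in stratum"))
        sub <- subsetCohort(cohort, subjects = c(
            case_ids, ph$subject_id[ph$status == "control"]))
        out <- if (analysis == "quintile")
            quintileAssociation(sub, cutpoints = overall_cuts,
                                stratum = label, ...)
        else
            allSnpAssociations(sub, stratum = label, ...)
        if (length(case_ids) < 10L) {
            out$flagged <- TRUE
            out$note <- ifelse(is.na(out$note),
                               "fewer than 10 cases in stratum", out$note)
        }
        out
    })
    common <- Reduce(intersect, lapply(res, colnames))
    do.call(rbind, lapply(res, function(x) x[, common, drop = FALSE]))
}

#' Write an association results table to TSV
#'
#' Full numeric precision; the human-readable rounding (OR to 2 dp,
#' scientific p-values) is applied by [renderReport()].
#'
#' @param results data.frame of association results
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeAssociation <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
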