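# Teloscore computation: the weighted sum over the panel of effect-allele
# counts times per-allele bp weights, its call-rate-scaled variant, and the
# control-derived quintile machinery.

#' Raw teloscore of fully genotyped subjects
#'
#' The raw score is the sum over panel SNPs of (effect-allele count x
#' per-allele effect in bp). It is defined only when every panel genotype is
#' called; partially genotyped subjects are scored with the scaled variant
#' (see [teloscores()]).
#'
#' @param counts effect-allele counts: a vector named by rsid, or a SNPs x
#'   subjects matrix with rsid row names
#' @param panel a \linkS4class{TeloPanel}
#' @return numeric score(s) in bp
#' @examples
#' g <- setNames(rep(2L, 11), panelRsids(builtinPanel()))
#' rawTeloscore(g, builtinPanel())   # 1946.4 = 2 x 973.2
#' @export
rawTeloscore <- function(counts, panel) {
    w <- panelWeights(panel)
    if (is.matrix(counts)) {
        if (!setequal(rownames(counts), names(w)))
            stop("count rows do not match the panel")
        if (anyNA(counts))
            stop("missing genotypes: the raw teloscore requires a complete panel; use the scaled teloscore")
        return(as.vector(crossprod(counts[names(w), , drop = FALSE], w)))
    }
    if (!setequal(names(counts), names(w)))
        stop("count names do not match the panel")
    if (anyNA(counts))
        stop("missing genotypes: the raw teloscore requires a complete panel; use the scaled teloscore")
    sum(counts[names(w)] * w)
}

#' Raw and scaled teloscores for a cohort
#'
#' For each subject the weighted sum of effect-allele counts is taken over
#' the \emph{called} panel SNPs and divided by the number of called
#' genotypes, giving the scaled teloscore (bp per called genotype) that is
#' defined for any subject with at least one call. The raw score (the
#' unscaled sum) is reported only for subjects with a complete panel.
#' Excluding rsids gives the leave-one-out (or leave-k-out) score over the
#' reduced panel.
#'
#' @param cohort a \linkS4class{TeloCohort}
#' @param exclude rsids to drop from the panel before scoring (must leave at
#'   least one SNP)
#' @return data.frame with \code{subject_id}, \code{n_called},
#'   \code{raw_score} (NA unless all panel SNPs called) and
#'   \code{scaled_score} (NA when no genotype is called)
#' @examples
#' \dontrun{
#' sc <- teloscores(cohort)
#' sc10 <- teloscores(cohort, exclude = "rs2736100")  # TERT left out
#' }
#' @export
teloscores <- function(cohort, exclude = character()) {
    panel <- cohortPanel(cohort)
    if (length(exclude) > 0L) {
        if (length(setdiff(panelRsids(panel), exclude)) == 0L)
            stop("excluding all panel SNPs leaves nothing to score")
        panel <- subsetPanel(panel, exclude = exclude)
    }
    w <- panelWeights(panel)
    g <- genotypes(cohort)[names(w), , drop = FALSE]
    called <- !is.na(g)
    n_called <- colSums(called)
    g0 <- g
    g0[!called] <- 0L
    total <- as.vector(crossprod(g0, w))
    scaled <- ifelse(n_called >= 1L, total / n_called, NA_real_)
    raw <- ifelse(n_called == length(w), total, NA_real_)
    if (any(n_called == 0L))
        warning(sum(n_called == 0L),
                " subject(s) with zero called genotypes have no score")
    data.frame(subject_id = colnames(g),
               n_called = as.integer(n_called),
               raw_score = raw, scaled_score = scaled,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Quintile cutpoints from the control score distribution
#'
#' The 20th/40th/60th/80th percentiles of the control scores, computed with
#' the linear-interpolation percentile definition (type 7), define the five
#' score bins into which both cases and controls are distributed.
#'
#' @param control_scores numeric scores of control subjects (NA dropped);
#'   at least 5 distinct values required
#' @return numeric vector of 4 non-decreasing thresholds, named
#'   \code{q20}..\code{q80}
#' @examples
#' controlQuintileCutpoints(1:100)  # 20.8 40.6 60.4 80.2
#' @export
controlQuintileCutpoints <- function(control_scores) {
    s <- control_scores[!is.na(control_scores)]
    if (length(s) < 5L)
        stop("degenerate control distribution: fewer than 5 control scores")
    if (length(unique(s)) < 5L)
        stop("degenerate control distribution: fewer than 5 distinct control scores")
    q <- stats::quantile(s, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                         names = FALSE)
    stats::setNames(q, c("q20", "q40", "q60", "q80"))
}

#' Assign scores to control-derived quintile bins
#'
#' Bin k collects scores in (t[k-1], t[k]] with t[0] = -Inf and t[5] = +Inf:
#' a score exactly on a threshold falls in the lower bin.
#'
#' @param score numeric score(s)
#' @param cutpoints 4 thresholds from [controlQuintileCutpoints()]
#' @return integer bin(s) in 1..5 (NA for NA scores)
#' @export
assignQuintile <- function(score, cutpoints) {
    stopifnot(length(cutpoints) == 4L, !is.unsorted(cutpoints))
    bins <- findInterval(score, cutpoints, left.open = TRUE) + 1L
    bins[is.na(score)] <- NA_integer_
    as.integer(bins)
}

#' Write per-subject scores and quintiles to TSV
#'
#' @param scores data.frame from [teloscores()]
#' @param cutpoints optional cutpoints; when given a \code{quintile} column
#'   (of the scaled score) is added
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeScores <- function(scores, path, cutpoints = NULL) {
    out <- scores
    if (!is.null(cutpoints))
        out$quintile <- assignQuintile(scores$scaled_score, cutpoints)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
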