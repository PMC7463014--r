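# Seeded case-control cohort simulator. Genotypes are drawn under HWE at the
# panel effect-allele frequencies, covariates follow the study-population
# margins, and disease status is generated prospectively on a large pool
# from a logistic model with injectable quintile-level or per-SNP effects,
# then sampled without replacement to the requested case/control counts.
# Missingness is applied last, so the disease model always acts on true
# genotypes.

#' Disease models for the cohort simulator
#'
#' \code{nullDiseaseModel} gives every subject the baseline odds;
#' \code{quintileDiseaseModel} adds log-odds for scaled-teloscore quintiles
#' 2-5 (vs quintile 1) computed on the pool's prospective controls;
#' \code{perSnpDiseaseModel} adds per-effect-allele log-odds for named SNPs.
#'
#' @param baseline_log_odds intercept of the logistic disease model (default
#'   -2; it only controls how efficiently the pool yields cases)
#' @return a \code{teloDiseaseModel} list with fields \code{kind},
#'   \code{quintile_log_or}, \code{per_snp_log_or},
#'   \code{baseline_log_odds}
#' @export
nullDiseaseModel <- function(baseline_log_odds = -2) {
    structure(list(kind = "null", quintile_log_or = NULL,
                   per_snp_log_or = NULL,
                   baseline_log_odds = baseline_log_odds),
              class = "teloDiseaseModel")
}

#' @rdname nullDiseaseModel
#' @param quintile_log_or numeric(4): log odds ratios for quintiles 2-5 vs
#'   quintile 1
#' @export
quintileDiseaseModel <- function(quintile_log_or, baseline_log_odds = -2) {
    stopifnot(length(quintile_log_or) == 4L, all(is.finite(quintile_log_or)))
    structure(list(kind = "quintile", quintile_log_or = quintile_log_or,
                   per_snp_log_or = NULL,
                   baseline_log_odds = baseline_log_odds),
              class = "teloDiseaseModel")
}

#' @rdname nullDiseaseModel
#' @param per_snp_log_or named numeric: per-effect-allele log odds ratio per
#'   rsid (unnamed SNPs have no effect)
#' @export
perSnpDiseaseModel <- function(per_snp_log_or, baseline_log_odds = -2) {
    stopifnot(length(per_snp_log_or) >= 1L, !is.null(names(per_snp_log_or)),
              all(is.finite(per_snp_log_or)))
    structure(list(kind = "per_snp", quintile_log_or = NULL,
                   per_snp_log_or = per_snp_log_or,
                   baseline_log_odds = baseline_log_odds),
              class = "teloDiseaseModel")
}

#' Simulation configuration
#'
#' Defaults emulate the multi-center MPN case-control study the pipeline is
#' designed for: 480 cases and 909 controls from four countries (control
#' margins 75 Hungary / 182 Italy / 132 Poland / 520 Spain), about half
#' male, ages roughly normal with mean 53 and SD 11 truncated to [18, 95],
#' case subtypes 149 CML / 173 ET / 36 PMF / 122 PV, a 3\% per-genotype
#' missing-call rate (a ~97\% call rate), and genotypes under HWE at the
#' built-in panel's effect-allele frequencies.
#'
#' @param n_cases,n_controls sampled group sizes
#' @param panel the \linkS4class{TeloPanel} to simulate genotypes for
#' @param country_weights named sampling weights over country labels
#' @param male_fraction probability a subject is male
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years)
#' @param missing_rate per-genotype MCAR missing probability in [0, 1]
#' @param jak2_positive_fraction fraction of cases JAK2 V617F positive
#' @param subtype_weights named sampling weights over case subtypes
#' @param model a disease model from [nullDiseaseModel()] and friends
#' @param pool_factor pool size as a multiple of n_cases + n_controls
#' @param seed integer RNG seed (required by [simulateCaseControl()])
#' @return a validated \code{teloSimConfig} list
#' @export
simConfig <- function(n_cases = 480L, n_controls = 909L,
                      panel = builtinPanel(),
                      country_weights = c(Hungary = 75, Italy = 182,
                                          Poland = 132, Spain = 520),
                      male_fraction = 0.5,
                      age_mean = 53, age_sd = 11, age_range = c(18, 95),
                      missing_rate = 0.03,
                      jak2_positive_fraction = 0.5,
                      subtype_weights = c(CML = 149, ET = 173, PMF = 36,
                                          PV = 122),
                      model = nullDiseaseModel(),
                      pool_factor = 20, seed = NULL) {
    cfg <- structure(list(n_cases = as.integer(n_cases),
                          n_controls = as.integer(n_controls),
                          panel = panel,
                          country_weights = country_weights / sum(country_weights),
                          male_fraction = male_fraction,
                          age_mean = age_mean, age_sd = age_sd,
                          age_range = age_range,
                          missing_rate = missing_rate,
                          jak2_positive_fraction = jak2_positive_fraction,
                          subtype_weights = subtype_weights / sum(subtype_weights),
                          model = model, pool_factor = pool_factor,
                          seed = if (is.null(seed)) NULL else as.integer(seed)),
                     class = "teloSimConfig")
    issues <- validateSimConfig(cfg)
    if (length(issues) > 0L)
        stop("invalid simulation config:\n  ",
             paste(issues, collapse = "\n  "))
    cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a \code{teloSimConfig}
#' @return character vector of issues (empty when valid)
#' @export
validateSimConfig <- function(cfg) {
    issues <- character()
    if (!is(cfg$panel, "TeloPanel"))
        issues <- c(issues, "panel must be a TeloPanel")
    if (is.na(cfg$n_cases) || cfg$n_cases < 1L)
        issues <- c(issues, "n_cases must be a positive count")
    if (is.na(cfg$n_controls) || cfg$n_controls < 1L)
        issues <- c(issues, "n_controls must be a positive count")
    for (nm in c("country_weights", "subtype_weights")) {
        w <- cfg[[nm]]
        if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
            issues <- c(issues, paste(nm, "must be named, non-negative and sum to 1"))
    }
    for (nm in c("male_fraction", "missing_rate", "jak2_positive_fraction")) {
        v <- cfg[[nm]]
        if (!is.numeric(v) || v < 0 || v > 1)
            issues <- c(issues, paste(nm, "must be a probability in [0, 1]"))
    }
    if (cfg$age_sd <= 0) issues <- c(issues, "age_sd must be positive")
    if (cfg$age_range[1] >= cfg$age_range[2])
        issues <- c(issues, "age_range must be increasing")
    if (!is(cfg$model, "teloDiseaseModel"))
        issues <- c(issues, "model must be a teloDiseaseModel")
    if (cfg$pool_factor < 2)
        issues <- c(issues, "pool_factor must be at least 2")
    issues
}

#' Read a simulation configuration from YAML
#'
#' Recognised keys mirror the [simConfig()] arguments; the disease model is
#' given as a \code{model:} section with \code{kind} (null, quintile or
#' per_snp), \code{baseline_log_odds}, and either \code{quintile_log_or}
#' (4 values) or \code{per_snp_log_or} (rsid: log-OR map).
#'
#' @param path YAML file
#' @param seed optional seed overriding the file's
#' @return a \code{teloSimConfig}
#' @export
readSimConfig <- function(path, seed = NULL) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    model <- nullDiseaseModel()
    if (!is.null(y$model)) {
        base <- if (is.null(y$model$baseline_log_odds)) -2 else
            y$model$baseline_log_odds
        model <- switch(
            if (is.null(y$model$kind)) "null" else y$model$kind,
            null = nullDiseaseModel(base),
            quintile = quintileDiseaseModel(unlist(y$model$quintile_log_or), base),
            per_snp = perSnpDiseaseModel(unlist(y$model$per_snp_log_or), base),
            stop("unknown disease model kind: ", y$model$kind))
    }
    args <- list(model = model)
    for (nm in c("n_cases", "n_controls", "male_fraction", "age_mean",
                 "age_sd", "missing_rate", "jak2_positive_fraction",
                 "pool_factor", "seed"))
        if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
    for (nm in c("country_weights", "subtype_weights", "age_range"))
        if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
    if (!is.null(y$panel_file)) args$panel <- readPanel(y$panel_file)
    if (!is.null(seed)) args$seed <- seed
    do.call(simConfig, args)
}

#' Simulate HWE genotypes for a panel
#'
#' Each SNP is drawn independently with genotype probabilities
#' \eqn{(1-f)^2, 2f(1-f), f^2} at its effect-allele frequency \eqn{f}
#' (a Binomial(2, f) effect-allele count).
#'
#' @param n number of subjects
#' @param panel a \linkS4class{TeloPanel}
#' @param seed optional seed (set before drawing when given)
#' @return integer matrix of effect-allele counts, SNPs x subjects
#' @export
simulateGenotypes <- function(n, panel, seed = NULL) {
    stopifnot(n >= 1)
    if (!is.null(seed)) set.seed(seed)
    df <- panelTable(panel)
    g <- vapply(df$eaf, function(f) stats::rbinom(n, 2L, f), integer(n))
    g <- t(matrix(g, nrow = n, dimnames = list(NULL, df$rsid)))
    colnames(g) <- NULL
    g
}

#' Set genotype calls missing completely at random
#'
#' @param genotypes genotype matrix
#' @param missing_rate per-call missing probability in [0, 1]
#' @param seed optional seed
#' @return the matrix with calls set to NA independently at
#'   \code{missing_rate}
#' @export
applyMissingness <- function(genotypes, missing_rate, seed = NULL) {
    stopifnot(missing_rate >= 0, missing_rate <= 1)
    if (!is.null(seed)) set.seed(seed)
    if (missing_rate == 0) return(genotypes)
    drop <- stats::runif(length(genotypes)) < missing_rate
    genotypes[drop] <- NA_integer_
    genotypes
}

# inverse-CDF truncated normal
.rtruncnorm <- function(n, mean, sd, lo, hi) {
    u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
    stats::qnorm(u, mean, sd)
}

#' Simulate a case-control cohort
#'
#' Generates a subject pool of \code{pool_factor x (n_cases + n_controls)}
#' with HWE genotypes and study-margin covariates, computes each subject's
#' disease probability from the configured logistic model, draws disease
#' status, and samples exactly \code{n_cases} cases and \code{n_controls}
#' controls without replacement. Quintile effects are anchored to scaled-
#' teloscore cutpoints of the pool's prospective controls (two passes: pool-
#' wide cutpoints give a provisional status draw whose non-cases define the
#' final cutpoints). Missing calls are injected \emph{after} status is
#' assigned, so the disease model acts on true genotypes. Cases and controls
#' draw age, sex and country from the same distributions, emulating the
#' frequency-matched design.
#'
#' @param config a \code{teloSimConfig}; \code{config$seed} must be set
#' @return list of class \code{teloSimulatedCohort}: \code{cohort} (a
#'   \linkS4class{TeloCohort}) and \code{truth} (disease model, per-subject
#'   true scaled scores and probabilities, and the cutpoints the generator
#'   used)
#' @export
simulateCaseControl <- function(config) {
    stopifnot(is(config, "teloSimConfig"))
    if (is.null(config$seed))
        stop("config$seed must be set for a reproducible simulation")
    set.seed(config$seed)
    n_target <- config$n_cases + config$n_controls
    pool_n <- ceiling(config$pool_factor * n_target)

    g <- simulateGenotypes(pool_n, config$panel)
    w <- panelWeights(config$panel)
    scaled <- as.vector(crossprod(g, w)) / length(w)

    model <- config$model
    lp <- rep(model$baseline_log_odds, pool_n)
    cutpoints <- NULL
    if (model$kind == "quintile") {
        eff <- c(0, model$quintile_log_or)
        cut1 <- stats::quantile(scaled, c(0.2, 0.4, 0.6, 0.8), type = 7,
                                names = FALSE)
        y1 <- stats::rbinom(pool_n, 1L,
                            stats::plogis(lp + eff[assignQuintile(scaled, cut1)]))
        cutpoints <- controlQuintileCutpoints(scaled[y1 == 0L])
        lp <- lp + eff[assignQuintile(scaled, cutpoints)]
    } else if (model$kind == "per_snp") {
        unknown <- setdiff(names(model$per_snp_log_or), rownames(g))
        if (length(unknown) > 0L)
            stop("per-SNP effects name SNPs outside the panel: ",
                 paste(unknown, collapse = ", "))
        for (rs in names(model$per_snp_log_or))
            lp <- lp + g[rs, ] * model$per_snp_log_or[[rs]]
    }
    prob <- stats::plogis(lp)
    y <- stats::rbinom(pool_n, 1L, prob)

    case_pool <- which(y == 1L)
    ctrl_pool <- which(y == 0L)
    if (length(case_pool) < config$n_cases ||
        length(ctrl_pool) < config$n_controls)
        stop("pool exhausted: got ", length(case_pool), " cases / ",
             length(ctrl_pool), " controls but need ", config$n_cases, "/",
             config$n_controls,
             "; increase pool_factor or move baseline_log_odds toward 0")
    idx <- c(sample(case_pool, config$n_cases),
             sample(ctrl_pool, config$n_controls))
    status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

    n <- length(idx)
    pheno <- data.frame(
        subject_id = sprintf("S%05d", seq_len(n)),
        status = status,
        age = round(.rtruncnorm(n, config$age_mean, config$age_sd,
                                config$age_range[1], config$age_range[2]), 1),
        sex = ifelse(stats::runif(n) < config$male_fraction, "male", "female"),
        country = names(config$country_weights)[
            sample.int(length(config$country_weights), n, replace = TRUE,
                       prob = config$country_weights)],
        stringsAsFactors = FALSE)
    pheno$subtype <- ifelse(
        status == "case",
        names(config$subtype_weights)[
            sample.int(length(config$subtype_weights), n, replace = TRUE,
                       prob = config$subtype_weights)],
        "none")
    pheno$jak2 <- ifelse(
        status == "case",
        ifelse(stats::runif(n) < config$jak2_positive_fraction,
               "positive", "negative"),
        "unknown")

    g_sel <- g[, idx, drop = FALSE]
    colnames(g_sel) <- pheno$subject_id
    g_obs <- applyMissingness(g_sel, config$missing_rate)

    cohort <- TeloCohort(g_obs, pheno, config$panel)
    truth <- list(model = model,
                  true_scaled_score = stats::setNames(scaled[idx],
                                                      pheno$subject_id),
                  disease_probability = stats::setNames(prob[idx],
                                                        pheno$subject_id),
                  cutpoints = cutpoints,
                  pool_n = pool_n,
                  pool_prevalence = mean(y))
    structure(list(cohort = cohort, truth = truth),
              class = "teloSimulatedCohort")
}

#' @export
print.teloSimulatedCohort <- function(x, ...) {
    cat("Simulated cohort (", x$truth$model$kind, " disease model, pool of ",
        x$truth$pool_n, ", prevalence ",
        sprintf("%.3f", x$truth$pool_prevalence), ")\n", sep = "")
    show(x$cohort)
    invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the genotype and phenotype TSVs consumed by [readCohort()] plus a
#' truth sidecar (JSON) recording the disease model, generator cutpoints and
#' per-subject true scores.
#'
#' @param sim result of [simulateCaseControl()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSimulation <- function(sim, dir) {
    stopifnot(is(sim, "teloSimulatedCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gpath <- file.path(dir, "genotypes.tsv")
    ppath <- file.path(dir, "phenotypes.tsv")
    writeCohort(sim$cohort, gpath, ppath)
    tpath <- file.path(dir, "truth.json")
    truth <- sim$truth
    jsonlite::write_json(
        list(model = truth$model[c("kind", "quintile_log_or",
                                   "per_snp_log_or", "baseline_log_odds")],
             cutpoints = truth$cutpoints,
             pool_n = truth$pool_n,
             pool_prevalence = truth$pool_prevalence,
             true_scaled_score = as.list(truth$true_scaled_score)),
        tpath, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(c(gpath, ppath, tpath))
}
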