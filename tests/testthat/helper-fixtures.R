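# Shared fixtures: tiny panels/cohorts built in code, plus independent
# oracles used by the property tests.

tinyPanel <- function(betas = c(0.10, 0.05), eafs = c(0.3, 0.6)) {
    n <- length(betas)
    TeloPanel(data.frame(
        rsid = paste0("rs", seq_len(n)),
        gene = paste0("G", seq_len(n)),
        chromosome = as.character(seq_len(n)),
        position = 1000L * seq_len(n),
        effect_allele = rep(c("A", "C"), length.out = n),
        other_allele = rep(c("G", "T"), length.out = n),
        eaf = eafs, beta = betas, beta_se = rep(0.01, n),
        bp_per_allele = betas * 1200,
        discovery_pvalue = rep(1e-8, n),
        discovery_study = rep("Codd", n),
        stringsAsFactors = FALSE))
}

# cohort with default covariates around a given genotype matrix (SNPs x subj)
makeCohort <- function(geno, status, panel = builtinPanel(),
                       age = NULL, sex = NULL, country = NULL,
                       jak2 = NULL, subtype = NULL) {
    n <- ncol(geno)
    if (is.null(colnames(geno))) colnames(geno) <- sprintf("P%04d", seq_len(n))
    stopifnot(length(status) == n)
    ph <- data.frame(
        subject_id = colnames(geno),
        status = status,
        age = if (is.null(age)) rep(55, n) else age,
        sex = if (is.null(sex)) rep(c("male", "female"), length.out = n) else sex,
        country = if (is.null(country)) rep("Spain", n) else country,
        subtype = if (is.null(subtype))
            ifelse(status == "case", "ET", "none") else subtype,
        jak2 = if (is.null(jak2))
            ifelse(status == "case", "positive", "unknown") else jak2,
        stringsAsFactors = FALSE)
    rownames(geno) <- panelRsids(panel)
    TeloCohort(geno, ph, panel)
}

# Brute-force Levene-Haldane oracle: enumerate every heterozygote count
# compatible with the observed allele counts and compute configuration
# probabilities directly from factorials (valid for allele totals <= 50).
hweOracle <- function(n_hom_ref, n_het, n_hom_alt) {
    n <- n_hom_ref + n_het + n_hom_alt
    n_alt <- 2 * n_hom_alt + n_het
    n_minor <- min(n_alt, 2 * n - n_alt)
    n_major <- 2 * n - n_minor
    hets <- seq(n_minor %% 2, n_minor, by = 2)
    w <- vapply(hets, function(h) {
        a <- (n_minor - h) / 2
        b <- (n_major - h) / 2
        factorial(n) / (factorial(a) * factorial(h) * factorial(b)) * 2^h
    }, numeric(1))
    probs <- w / sum(w)
    p_obs <- probs[hets == n_het]
    sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# expand a 2x2 exposure table into a subject-level data.frame
expand2x2 <- function(case_exposed, case_unexposed, ctrl_exposed,
                      ctrl_unexposed) {
    data.frame(
        y = rep(c(1, 1, 0, 0),
                c(case_exposed, case_unexposed, ctrl_exposed, ctrl_unexposed)),
        x = rep(c(1, 0, 1, 0),
                c(case_exposed, case_unexposed, ctrl_exposed, ctrl_unexposed)))
}

# single-SNP panel matching the OBFC1 SNP's frequency and weight
obfc1Panel <- function() {
    TeloPanel(data.frame(
        rsid = "rs9420907", gene = "OBFC1", chromosome = "10",
        position = 103916707L, effect_allele = "C", other_allele = "A",
        eaf = 0.13, beta = 0.142, beta_se = 0.014, bp_per_allele = 170.4,
        discovery_pvalue = 7e-11, discovery_study = "Levy",
        stringsAsFactors = FALSE))
}
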