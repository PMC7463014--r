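test_that("logistic fit on a saturated 2x2 equals the cross-product ratio", {
    df <- expand2x2(30, 70, 10, 90)
    fit <- fitLogistic(y ~ x, df)
    expect_equal(exp(fit$coefficients[["x"]]), 27 / 7, tolerance = 1e-7)
    expect_true(fit$converged)
    expect_false(fit$flagged)
    expect_equal(fit$n_used, 200L)

    # relabeling which level is "case" inverts the OR
    df$y2 <- 1 - df$y
    fit2 <- fitLogistic(y2 ~ x, df)
    expect_equal(fit2$coefficients[["x"]], -fit$coefficients[["x"]],
                 tolerance = 1e-9)

    expect_error(fitLogistic(y ~ x, data.frame(y = rep(1, 10), x = rnorm(10))),
                 "one class")
})

test_that("a null predictor at large n gives OR near 1 and Wald consistency", {
    set.seed(3)
    df <- data.frame(y = rbinom(4000, 1, 0.3), x = rbinom(4000, 1, 0.4))
    fit <- fitLogistic(y ~ x, df)
    or <- exp(fit$coefficients[["x"]])
    se <- fit$standard_errors[["x"]]
    lo <- exp(fit$coefficients[["x"]] - 1.96 * se)
    hi <- exp(fit$coefficients[["x"]] + 1.96 * se)
    expect_lt(abs(log(or)), 0.25)
    expect_true(lo <= or && or <= hi)
    # p < 0.05 iff 1 outside the 95% Wald CI
    z <- fit$coefficients[["x"]] / se
    p <- 2 * pnorm(-abs(z))
    expect_equal(p < 0.05, !(lo <= 1 && 1 <= hi))
})

test_that("separation is flagged, not silently reported", {
    df <- data.frame(y = rep(c(0, 1), each = 50), x = rep(c(0, 1), each = 50))
    fit <- fitLogistic(y ~ x, df)
    expect_true(fit$flagged)
})

test_that("Bonferroni threshold is alpha over SNPs x models", {
    expect_equal(round(bonferroniThreshold(11, 2), 4), 0.0023)
    expect_equal(bonferroniThreshold(1, 1), 0.05)
    expect_equal(bonferroniThreshold(22, 1), bonferroniThreshold(11, 2))
})

test_that("allelic model matches the allele-table cross-product oracle", {
    panel <- tinyPanel()
    # cases: 100 subjects, 60 minor alleles (10 hom + 40 het);
    # controls: 150 subjects, 50 minor alleles (5 hom + 40 het)
    g_case <- c(rep(2L, 10), rep(1L, 40), rep(0L, 50))
    g_ctrl <- c(rep(2L, 5), rep(1L, 40), rep(0L, 105))
    g <- rbind(rs1 = c(g_case, g_ctrl),
               rs2 = rep(c(0L, 1L), 125))
    cohort <- makeCohort(g, status = rep(c("case", "control"), c(100, 150)),
                         panel = panel)
    res <- snpAssociation(cohort, "rs1", models = "allelic",
                          covariates = character())
    oracle <- (60 * 250) / (140 * 50)   # 2.143
    expect_equal(res$odds_ratio, oracle, tolerance = 0.1)
    # the reported MAF is the control-stratum minor-allele frequency
    expect_equal(res$maf, 50 / 300)
})

test_that("dominant and recessive contrasts equal their saturated 2x2 oracles", {
    panel <- tinyPanel()
    g_case <- c(rep(2L, 12), rep(1L, 38), rep(0L, 50))
    g_ctrl <- c(rep(2L, 6), rep(1L, 44), rep(0L, 100))
    g <- rbind(rs1 = c(g_case, g_ctrl), rs2 = rep(c(0L, 1L), 125))
    cohort <- makeCohort(g, status = rep(c("case", "control"), c(100, 150)),
                         panel = panel)
    res <- snpAssociation(cohort, "rs1",
                          models = c("dominant", "recessive"),
                          covariates = character())
    dom <- res[res$model == "dominant", ]
    rec <- res[res$model == "recessive", ]
    # dominant: carriers (>=1 minor) vs common hom
    expect_equal(dom$odds_ratio, (50 * 100) / (50 * 50), tolerance = 1e-6)
    # recessive: minor homozygotes vs everyone else
    expect_equal(rec$odds_ratio, (12 * 144) / (88 * 6), tolerance = 1e-6)
})

test_that("codominant fits report both contrasts and omit empty cells", {
    panel <- tinyPanel()
    g_case <- c(rep(2L, 10), rep(1L, 40), rep(0L, 50))
    g_ctrl <- c(rep(2L, 5), rep(1L, 40), rep(0L, 105))
    g <- rbind(rs1 = c(g_case, g_ctrl), rs2 = rep(c(0L, 1L), 125))
    cohort <- makeCohort(g, status = rep(c("case", "control"), c(100, 150)),
                         panel = panel)
    res <- snpAssociation(cohort, "rs1", models = "codominant",
                          covariates = character())
    expect_setequal(res$term, c("het vs common hom", "rare hom vs common hom"))
    # het contrast is a saturated 3-level model: equals its 2x2 cross-product
    het <- res[res$term == "het vs common hom", ]
    expect_equal(het$odds_ratio, (40 * 105) / (50 * 40), tolerance = 1e-6)

    # no rare homozygotes at all -> contrast omitted with a note
    g2 <- g; g2["rs1", g2["rs1", ] == 2L] <- 1L
    cohort2 <- makeCohort(g2, status = rep(c("case", "control"), c(100, 150)),
                          panel = panel)
    res2 <- snpAssociation(cohort2, "rs1", models = "codominant",
                           covariates = character())
    hom2 <- res2[res2$term == "rare hom vs common hom", ]
    expect_true(is.na(hom2$odds_ratio))
    expect_match(hom2$note, "empty rare-homozygote")
})

test_that("monomorphic SNPs and missing-genotype subjects are handled", {
    panel <- tinyPanel()
    g <- rbind(rs1 = rep(0L, 40),
               rs2 = c(rep(c(0L, 1L, 2L), 13), NA_integer_))
    cohort <- makeCohort(g, status = rep(c("case", "control"), 20),
                         panel = panel)
    expect_error(snpAssociation(cohort, "rs1", covariates = character()),
                 "monomorphic")
    res <- snpAssociation(cohort, "rs2", models = "allelic",
                          covariates = character())
    # the subject with a missing call is excluded from this SNP's fit
    expect_equal(res$n_cases + res$n_controls, 39L)
})

test_that("quintile association recovers the reference row and a null score", {
    set.seed(21)
    cfg <- simConfig(n_cases = 250, n_controls = 400, seed = 77)
    sim <- simulateCaseControl(cfg)
    q <- suppressMessages(quintileAssociation(sim$cohort))
    expect_equal(q$term[1], "quintile 1")
    expect_equal(q$odds_ratio[1], 1)
    expect_equal(q$note[1], "reference")
    expect_equal(nrow(q), 6L)   # 5 quintile rows + trend
    # null model: no quintile should be extreme
    ors <- q$odds_ratio[2:5]
    expect_true(all(q$ci_low[2:5] < 1.6 & q$ci_high[2:5] > 0.8))
    # trend term near null
    expect_lt(abs(log(q$odds_ratio[q$model == "continuous"])), 0.35)
    # cutpoints come from controls and are increasing
    expect_false(is.unsorted(attr(q, "cutpoints")))
})

test_that("minor-allele and effect-allele codings are reciprocal", {
    set.seed(5)
    cfg <- simConfig(n_cases = 200, n_controls = 300, seed = 13)
    sim <- simulateCaseControl(cfg)
    # rs3027234 has EAF 0.78, so its minor allele is the other allele
    a_minor <- suppressMessages(
        snpAssociation(sim$cohort, "rs3027234", models = "allelic"))
    a_eff <- suppressMessages(
        snpAssociation(sim$cohort, "rs3027234", models = "allelic",
                       coding = "effect"))
    expect_equal(a_minor$odds_ratio, 1 / a_eff$odds_ratio, tolerance = 1e-9)
})

test_that("stratified analysis recovers effects only in the stratum carrying them", {
    # JAK2+ cases carry a strong score effect; JAK2- cases are null
    # rare disease (baseline -4) so the injected quintiles anchored to the
    # effect model's controls coincide with population quintiles
    eff <- simulateCaseControl(simConfig(
        n_cases = 250, n_controls = 50, pool_factor = 60,
        model = quintileDiseaseModel(log(c(1.6, 2.2, 2.8, 3.5)),
                                     baseline_log_odds = -4), seed = 101))
    nul <- simulateCaseControl(simConfig(
        n_cases = 250, n_controls = 909, seed = 102))
    # JAK2+ cases from the effect model; JAK2- cases and all shared controls
    # from the null model
    ph_e <- phenotypes(eff$cohort); ph_n <- phenotypes(nul$cohort)
    g_e <- genotypes(eff$cohort); g_n <- genotypes(nul$cohort)
    keep_e <- ph_e$status == "case"
    ph_e <- ph_e[keep_e, ]; g_e <- g_e[, keep_e, drop = FALSE]
    ph_e$jak2 <- "positive"
    ph_n$jak2[ph_n$status == "case"] <- "negative"
    ph_e$subject_id <- paste0("E", ph_e$subject_id)
    colnames(g_e) <- ph_e$subject_id
    combined <- TeloCohort(cbind(g_e, g_n), rbind(ph_e, ph_n), builtinPanel())

    res <- suppressMessages(
        stratifiedAssociation(combined, "jak2", "quintile"))
    trend <- res[res$model == "continuous", ]
    pos <- trend[trend$stratum == "jak2=positive", ]
    neg <- trend[trend$stratum == "jak2=negative", ]
    expect_lt(pos$p_value, 0.01)
    expect_gt(pos$odds_ratio, 1.15)
    expect_gt(neg$p_value, 0.01)
    expect_lt(abs(log(neg$odds_ratio)), 0.3)

    # a single-stratum cohort reproduces the unstratified analysis
    only_pos <- subsetCohort(combined, subjects = phenotypes(combined)$subject_id[
        phenotypes(combined)$jak2 != "negative"])
    solo <- suppressMessages(stratifiedAssociation(only_pos, "jak2", "quintile"))
    direct <- suppressMessages(quintileAssociation(only_pos))
    expect_equal(solo$odds_ratio, direct$odds_ratio, tolerance = 1e-12)

    # tiny stratum is computed but flagged
    few <- phenotypes(combined)
    few$jak2[few$status == "case"] <- "negative"
    few$jak2[few$subject_id %in% few$subject_id[few$status == "case"][1:5]] <-
        "positive"
    few_cohort <- TeloCohort(genotypes(combined), few, builtinPanel())
    res_few <- suppressMessages(
        stratifiedAssociation(few_cohort, "jak2", "quintile"))
    expect_true(all(res_few$flagged[res_few$stratum == "jak2=positive"]))
})
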