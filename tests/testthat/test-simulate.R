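test_that("genotype simulation follows HWE at the panel frequencies", {
    p <- tinyPanel(betas = c(0.1, 0.1), eafs = c(0.5, 0.999999))
    g <- simulateGenotypes(10000, p, seed = 1)
    # eaf ~ 1: essentially all genotypes homozygous effect
    expect_true(all(g["rs2", ] %in% c(1L, 2L)))
    # eaf = 0.5: genotype fractions 0.25 / 0.50 / 0.25 within 3 binomial SEs
    fr <- table(factor(g["rs1", ], levels = 0:2)) / 10000
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
    expect_true(all(abs(fr - c(0.25, 0.5, 0.25)) <= 3 * se))

    # allele frequencies converge to the panel EAFs (large n, 3 SEs)
    big <- simulateGenotypes(1e5, builtinPanel(), seed = 2)
    eaf_hat <- rowMeans(big) / 2
    eaf <- panelTable(builtinPanel())$eaf
    se_f <- sqrt(eaf * (1 - eaf) / (2 * 1e5))
    expect_true(all(abs(eaf_hat - eaf) <= 3 * se_f))
})

test_that("simulated control genotypes pass the exact HWE check across seeds", {
    panel <- builtinPanel()
    ok <- vapply(1:100, function(s) {
        g <- simulateGenotypes(909, panel, seed = s)
        p <- vapply(seq_len(nrow(g)), function(i) {
            x <- g[i, ]
            hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
        }, numeric(1))
        sum(p >= 0.001) >= 10L
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("missingness is MCAR at the requested rate", {
    g <- simulateGenotypes(1000, builtinPanel(), seed = 4)
    expect_identical(applyMissingness(g, 0), g)
    expect_true(all(is.na(applyMissingness(g, 1))))
    gm <- applyMissingness(g, 0.03, seed = 5)
    call_rate <- mean(!is.na(gm))
    se <- sqrt(0.03 * 0.97 / length(g))
    expect_lt(abs(call_rate - 0.97), 3 * se)
})

test_that("cohort simulation is deterministic and hits exact margins", {
    cfg <- simConfig(n_cases = 120, n_controls = 200, seed = 9)
    s1 <- simulateCaseControl(cfg)
    s2 <- simulateCaseControl(cfg)
    expect_identical(genotypes(s1$cohort), genotypes(s2$cohort))
    expect_identical(phenotypes(s1$cohort), phenotypes(s2$cohort))
    expect_identical(s1$truth$true_scaled_score, s2$truth$true_scaled_score)

    expect_equal(nCases(s1$cohort), 120L)
    expect_equal(nControls(s1$cohort), 200L)
    ph <- phenotypes(s1$cohort)
    expect_true(all(ph$subtype[ph$status == "control"] == "none"))
    expect_true(all(ph$subtype[ph$status == "case"] %in%
                    c("CML", "ET", "PMF", "PV")))
    expect_true(all(ph$age >= 18 & ph$age <= 95))
    # truth is sufficient to recompute disease probabilities
    expect_equal(unname(s1$truth$disease_probability),
                 rep(plogis(-2), 320))
})

test_that("a null disease model leaves case and control scores exchangeable", {
    for (s in c(31, 32)) {
        sim <- simulateCaseControl(simConfig(seed = s))
        sc <- suppressWarnings(teloscores(sim$cohort))
        st <- phenotypes(sim$cohort)$status
        p <- t.test(sc$scaled_score[st == "case"],
                    sc$scaled_score[st == "control"])$p.value
        expect_gt(p, 0.001)
    }
})

test_that("per-SNP effects do not leak into other panel SNPs", {
    cfg <- simConfig(model = perSnpDiseaseModel(c(rs9420907 = log(1.8))),
                     seed = 55)
    sim <- simulateCaseControl(cfg)
    res <- suppressMessages(
        allSnpAssociations(sim$cohort, models = "allelic",
                           covariates = character()))
    target <- res[res$rsid == "rs9420907", ]
    others <- res[res$rsid != "rs9420907", ]
    expect_lt(target$p_value, 0.01)
    # null SNPs: no Bonferroni-level hits, ORs near 1
    expect_true(all(others$p_value > 0.001, na.rm = TRUE))
    expect_true(all(abs(log(others$odds_ratio)) < 0.45, na.rm = TRUE))
})

test_that("an exhausted pool raises an actionable error", {
    cfg <- simConfig(n_cases = 400, n_controls = 500, pool_factor = 2,
                     model = nullDiseaseModel(baseline_log_odds = -6),
                     seed = 8)
    expect_error(simulateCaseControl(cfg), "pool exhausted")
})

test_that("configs validate and round-trip through YAML", {
    expect_error(simConfig(n_cases = 0), "n_cases")
    expect_error(simConfig(missing_rate = 1.5), "missing_rate")
    expect_error(quintileDiseaseModel(c(0.1, 0.2)), "length")

    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("n_cases: 50",
                 "n_controls: 80",
                 "missing_rate: 0.05",
                 "seed: 11",
                 "model:",
                 "  kind: quintile",
                 "  baseline_log_odds: -1.5",
                 "  quintile_log_or: [0.1, 0.2, 0.3, 0.4]"), path)
    cfg <- readSimConfig(path)
    expect_equal(cfg$n_cases, 50L)
    expect_equal(cfg$model$kind, "quintile")
    expect_equal(cfg$model$quintile_log_or, c(0.1, 0.2, 0.3, 0.4))
    expect_equal(cfg$model$baseline_log_odds, -1.5)
    cfg2 <- readSimConfig(path, seed = 99)
    expect_equal(cfg2$seed, 99L)
})
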