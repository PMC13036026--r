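.statsAtlas <- function(n_regions = 6L)
    makeToyAtlas(n_regions, c(24L, 24L, 24L), c(10, 10, 10), seed = 2)

.cohortFor <- function(atlas, effect_map = list(), seed = 1,
                       baseline = 5000, groups = defaultGroups(),
                       sigma_mouse = 0.1 * baseline,
                       sigma_resid = 0.15 * baseline) {
    leaves <- structures(atlas)$acronym[structures(atlas)$is_gray_matter]
    cs <- cohortSpec(groups = groups,
                     baseline_density = setNames(rep(baseline,
                                                     length(leaves)),
                                                 leaves),
                     effect_map = effect_map,
                     sigma_mouse = sigma_mouse, sigma_resid = sigma_resid)
    simulateCohort(atlas, cs, seed = seed)
}

test_that("random forest selection ranks the true signal region first", {
    a <- .statsAtlas(10L)
    sim <- .cohortFor(a, effect_map = list(R05 = c(3, 0, 0)), seed = 8)
    sel <- selectRegions(sim$dm, a@ontology, seed = 3)
    s <- structures(a)
    top <- names(sel$importances)[which.max(sel$importances)]
    expect_identical(s$acronym[s$id == as.integer(top)], "R05")
    expect_true(all(sel$pruned %in% sel$selected))
    expect_equal(sum(sel$importances), 1)
})

test_that("constant region columns get exactly zero importance", {
    a <- .statsAtlas(6L)
    sim <- .cohortFor(a, seed = 9)
    mat <- SummarizedExperiment::assay(sim$dm, "density")
    mat["R03", ] <- 42                   # constant across animals
    rd <- SummarizedExperiment::rowData(sim$dm)
    dm <- densityMatrix(mat, rd$id, rd$acronym,
                        as.data.frame(SummarizedExperiment::colData(sim$dm)))
    sel <- selectRegions(dm, a@ontology, seed = 3)
    s <- structures(a)
    id_r03 <- as.character(s$id[s$acronym == "R03"])
    expect_identical(unname(sel$importances[id_r03]), 0)
    expect_false(as.integer(id_r03) %in% sel$selected)
    ## single treatment class errors
    cd <- as.data.frame(SummarizedExperiment::colData(sim$dm))
    cd$treatment <- "morphine"
    dm_bad <- densityMatrix(mat, rd$id, rd$acronym, cd)
    expect_error(selectRegions(dm_bad, a@ontology), "design error")
})

test_that("zero-noise cohorts give zero effect coefficients", {
    a <- .statsAtlas(4L)
    leaves <- structures(a)$acronym[structures(a)$is_gray_matter]
    cs <- cohortSpec(baseline_density = setNames(rep(700, 4), leaves),
                     sigma_mouse = 0, sigma_resid = 0)
    sim <- simulateCohort(a, cs, seed = 1)
    fit <- fitRegionLmm(sim$dm, "R01")
    expect_true(all(abs(fit$beta[-1]) < 1e-8))
    ## total variance is zero -> d undefined, loud error
    expect_error(effectSizes(fit), "degenerate-variance")
})

test_that("coefficients are recovered within 3 SE on seeded cohorts", {
    a <- .statsAtlas(4L)
    sim <- .cohortFor(a, effect_map = list(R01 = c(1.5, -0.8, 0.6)),
                      seed = 21)
    total_sd <- sqrt((0.1 * 5000)^2 + (0.15 * 5000)^2)
    fit <- fitRegionLmm(sim$dm, "R01")
    want <- c("treatmentmorphine" = 1.5 * total_sd,
              "treatmentmorphine:time4h" = -0.8 * total_sd,
              "treatmentmorphine:sexfemale" = 0.6 * total_sd)
    for (nm in names(want)) {
        se <- sqrt(fit$cov_beta[nm, nm])
        expect_lt(abs(fit$beta[nm] - want[[nm]]), 3 * se)
    }
    ## empty cells are named in the error
    cd <- as.data.frame(SummarizedExperiment::colData(sim$dm))
    keep <- !(cd$treatment == "morphine" & cd$time == "4h" &
              cd$sex == "female")
    mat <- SummarizedExperiment::assay(sim$dm, "density")[, keep]
    rd <- SummarizedExperiment::rowData(sim$dm)
    dm_bad <- densityMatrix(mat, rd$id, rd$acronym, cd[keep, ])
    expect_error(fitRegionLmm(dm_bad, "R01"), "empty cell")
})

test_that("variance sum matches the fixed-effects-only oracle", {
    a <- .statsAtlas(4L)
    ## balanced design so OLS mean squared residual is the clean oracle
    groups <- expand.grid(treatment = c("morphine", "saline"),
                          time = c("1h", "4h"),
                          sex = c("male", "female"),
                          stringsAsFactors = FALSE)
    groups$n <- 6L
    sim <- .cohortFor(a, seed = 31, groups = groups)
    fit <- fitRegionLmm(sim$dm, "R02")
    cd <- as.data.frame(SummarizedExperiment::colData(sim$dm))
    cd$y <- as.numeric(
        SummarizedExperiment::assay(sim$dm, "density")["R02", ])
    ols <- lm(y ~ treatment * time * sex, data = cd)
    mse <- sum(resid(ols)^2) / ols$df.residual
    total <- fit$sigma2_resid + fit$sigma2_intercept
    expect_lt(abs(total - mse) / mse, 0.10)
})

test_that("Cohen's d standardizes by the summed variance components", {
    fit <- structure(list(
        region = "toy",
        beta = c("(Intercept)" = 0, "treatmentmorphine" = 2,
                 "time4h" = 0, "sexfemale" = 0,
                 "treatmentmorphine:time4h" = 0,
                 "treatmentmorphine:sexfemale" = 0,
                 "time4h:sexfemale" = 0,
                 "treatmentmorphine:time4h:sexfemale" = 0),
        cov_beta = diag(0.25, 8,
                        names = TRUE) |>
            `dimnames<-`(list(names(standardContrasts()[[1]]),
                              names(standardContrasts()[[1]]))),
        sigma2_resid = 0.64, sigma2_intercept = 0.36,
        converged = TRUE, n = 27), class = "fosmap_lmm")
    es <- effectSizes(fit)
    row <- es[es$contrast == "treat@M1h", ]
    expect_equal(row$d, 2 / sqrt(0.64 + 0.36))        # = 2.0
    expect_equal(row$d_lower, (2 - 1.96 * 0.5) / 1)
    expect_equal(row$d_upper, (2 + 1.96 * 0.5) / 1)
    expect_true(row$large_effect)
    ## a zero contrast has d = 0 with a CI symmetric about 0
    row0 <- es[es$contrast == "treat:time@M", ]
    expect_equal(row0$d, 0)
    expect_equal(row0$d_lower, -row0$d_upper)
    ## d is invariant to the variance split at fixed sum
    fit2 <- fit; fit2$sigma2_resid <- 0.1; fit2$sigma2_intercept <- 0.9
    expect_equal(effectSizes(fit2)$d, es$d)
})

test_that("bhFdr equals the brute-force step-up definition", {
    expect_equal(bhFdr(0.3), 0.3)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    set.seed(14)
    for (rep in 1:40) {
        p <- runif(sample(1:50, 1))
        q <- bhFdr(p)
        expect_equal(q, bruteForceBH(p))
        ## monotone: ordering of q follows ordering of p
        expect_true(all(diff(q[order(p)]) >= -1e-12))
        expect_true(all(q >= 0 & q <= 1))
    }
    expect_error(bhFdr(c(0.5, 1.2)), "argument error")
    expect_error(bhFdr(c(0.5, -0.1)), "argument error")
})

test_that("star notation follows the q thresholds", {
    expect_identical(starsFromQ(c(0.3, 0.04, 0.009, 0.0009, 0.0167)),
                     c("", "*", "**", "***", "*"))
})

test_that("response classification applies the d and CI rules", {
    mk <- function(region, contrast, d, lo, hi, p) {
        data.frame(region = region, contrast = contrast, beta = d, d = d,
                   d_lower = lo, d_upper = hi, p = p,
                   large_effect = abs(d) > 0.8, stringsAsFactors = FALSE)
    }
    all_ct <- names(standardContrasts())
    rows <- list()
    for (r in c("R1", "R2", "R3")) {
        for (ct in all_ct) rows[[paste(r, ct)]] <-
            mk(r, ct, 0, -1, 1, 0.9)
    }
    eff <- do.call(rbind, rows)
    ## R1: d = 0.5 -> never responsive regardless of CI
    eff[eff$region == "R1" & eff$contrast == "treat@M1h",
        c("d", "d_lower", "d_upper", "p")] <- c(0.5, 0.2, 0.8, 0.01)
    ## R2: d = 1.0 with CI excluding 0 -> responsive
    eff[eff$region == "R2" & eff$contrast == "treat@F4h",
        c("d", "d_lower", "d_upper", "p")] <- c(1.0, 0.1, 1.9, 0.004)
    eff$large_effect <- abs(eff$d) > 0.8
    ## R3: d = 1.0 but CI contains 0 -> not responsive
    eff[eff$region == "R3" & eff$contrast == "treat@M4h",
        c("d", "d_lower", "d_upper", "p")] <- c(1.0, -0.1, 2.1, 0.06)
    rep_ <- classifyResponses(eff, analysisConfig())
    expect_identical(rep_$responsive_regions, "R2")
    expect_identical(rep_$responsive_by_group[["treat@F4h"]], "R2")
    expect_length(rep_$time_difference$male, 0)
    ## missing contrasts are a consistency error
    expect_error(classifyResponses(eff[-1, ], analysisConfig()),
                 "consistency error")
})

test_that("interaction-rule sets land in time/sex difference reports", {
    a <- .statsAtlas(6L)
    sim <- .cohortFor(a, effect_map = list(R02 = c(0, 4, 0),
                                           R04 = c(0, 0, -4)),
                      seed = 77, sigma_mouse = 250, sigma_resid = 375)
    rep_ <- analyzeCohort(sim$dm, a@ontology,
                          analysisConfig(rng_seed = 5),
                          regions = structures(a)$id[
                              structures(a)$is_gray_matter])
    expect_true("R02" %in% rep_$time_difference$male)
    expect_true("R04" %in% rep_$sex_difference[["1h"]])
})
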