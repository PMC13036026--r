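test_that("toy atlas volumes equal voxel counts times voxel volume", {
    a <- makeToyAtlas(2L, c(32L, 32L, 32L), c(10, 10, 10), seed = 5)
    s <- structures(a)
    lab <- labelVolume(a)
    voxvol <- 10^3 * 1e-9
    expect_equal(s$volume_mm3[s$acronym == "root"],
                 sum(lab > 0) * voxvol)
    for (id in s$id[s$is_gray_matter])
        expect_equal(s$volume_mm3[s$id == id], sum(lab == id) * voxvol)
})

test_that("toy atlas is mirror-labeled and seed-deterministic", {
    a <- makeToyAtlas(5L, c(24L, 24L, 25L), c(8, 8, 8), seed = 9)
    lab <- labelVolume(a)
    nx <- dim(lab)[3]
    expect_identical(lab, lab[, , nx:1])
    b <- makeToyAtlas(5L, c(24L, 24L, 25L), c(8, 8, 8), seed = 9)
    expect_identical(lab, labelVolume(b))
    expect_error(makeToyAtlas(50L, c(16L, 16L, 16L), c(8, 8, 8)),
                 "capacity")
})

test_that("phantom truth counts follow the Poisson means per region", {
    a <- makeToyAtlas(2L, c(20L, 24L, 24L), c(10, 5, 5), seed = 1)
    s <- structures(a)
    leaf <- s$id[s$is_gray_matter]
    rate <- 50000
    spec <- phantomSpec(spacing_um = spacing(a), noise_sd = 0,
                        artifact_spec = c(),
                        region_rates = setNames(rep(rate, 2), leaf))
    vols <- s$volume_mm3[match(leaf, s$id)]
    lambda <- rate * sum(vols)
    n <- vapply(1:400, function(i)
        nrow(spots(simulateVolume(a, spec, seed = i)$truth)), numeric(1))
    ## mean within 4 standard errors of the Poisson mean
    expect_lt(abs(mean(n) - lambda), 4 * sqrt(lambda / 400))
    ## chi-square GOF of the count distribution against Poisson(lambda)
    br <- qpois(c(0.1, 0.3, 0.5, 0.7, 0.9), lambda)
    cuts <- unique(c(-Inf, br, Inf))
    obs <- table(cut(n, cuts))
    expctd <- diff(ppois(cuts, lambda)) * 400
    chi2 <- sum((as.numeric(obs) - expctd)^2 / expctd)
    expect_lt(chi2, qchisq(0.99, df = length(expctd) - 1))
})

test_that("zero rates give an empty truth table and pure background", {
    a <- makeToyAtlas(2L, c(20L, 24L, 24L), c(10, 5, 5), seed = 1)
    leaf <- structures(a)$id[structures(a)$is_gray_matter]
    spec <- phantomSpec(spacing_um = spacing(a), noise_sd = 0,
                        background_level = 2, artifact_spec = c(),
                        region_rates = setNames(rep(0, 2), leaf))
    sim <- simulateVolume(a, spec, seed = 3)
    expect_identical(nrow(spots(sim$truth)), 0L)
    expect_equal(max(sim$volume), 2)    # background only
    ## determinism
    sim2 <- simulateVolume(a, spec, seed = 3)
    expect_identical(sim$volume, sim2$volume)
})

test_that("phantom generation is bit-for-bit seed-deterministic", {
    a <- makeToyAtlas(2L, c(20L, 24L, 24L), c(10, 5, 5), seed = 1)
    leaf <- structures(a)$id[structures(a)$is_gray_matter]
    spec <- phantomSpec(spacing_um = spacing(a),
                        region_rates = setNames(rep(30000, 2), leaf))
    s1 <- simulateVolume(a, spec, seed = 11)
    s2 <- simulateVolume(a, spec, seed = 11)
    expect_identical(s1$volume, s2$volume)
    expect_identical(spots(s1$truth), spots(s2$truth))
    s3 <- simulateVolume(a, spec, seed = 12)
    expect_false(identical(s1$volume, s3$volume))
})

test_that("noiseless zero-effect cohorts reproduce the baseline exactly", {
    a <- makeToyAtlas(4L, c(24L, 24L, 24L), c(10, 10, 10), seed = 2)
    leaves <- structures(a)$acronym[structures(a)$is_gray_matter]
    base <- setNames(c(100, 200, 300, 400), leaves)
    cs <- cohortSpec(baseline_density = base, sigma_mouse = 0,
                     sigma_resid = 0)
    sim <- simulateCohort(a, cs, seed = 1)
    mat <- SummarizedExperiment::assay(sim$dm, "density")
    for (r in leaves)
        expect_true(all(mat[r, ] == base[[r]]))
    expect_true(all(sim$truth_effects[, 2:4] == 0))
})

test_that("default cohort design has 27 animals in 8 groups", {
    a <- makeToyAtlas(3L, c(24L, 24L, 24L), c(10, 10, 10), seed = 2)
    leaves <- structures(a)$acronym[structures(a)$is_gray_matter]
    cs <- cohortSpec(baseline_density = setNames(rep(500, 3), leaves))
    sim <- simulateCohort(a, cs, seed = 5)
    cd <- SummarizedExperiment::colData(sim$dm)
    expect_identical(ncol(sim$dm), 27L)
    expect_identical(sum(cd$sex == "male"), 15L)
    expect_identical(sum(cd$sex == "female"), 12L)
    tab <- table(cd$treatment, cd$time, cd$sex)
    expect_identical(as.integer(tab["morphine", "1h", "male"]), 5L)
    expect_identical(as.integer(tab["saline", "4h", "female"]), 4L)
})

test_that("injected standardized effects appear in the sample contrast", {
    ## large balanced groups: the sample standardized mean difference in
    ## (male, 1h) should sit near the injected d
    a <- makeToyAtlas(2L, c(24L, 24L, 24L), c(10, 10, 10), seed = 2)
    leaves <- structures(a)$acronym[structures(a)$is_gray_matter]
    groups <- data.frame(treatment = rep(c("morphine", "saline"), 2),
                         time = "1h",
                         sex = rep(c("male", "female"), each = 2),
                         n = 40L)
    cs <- cohortSpec(groups = groups,
                     baseline_density = setNames(rep(5000, 2), leaves),
                     effect_map = list(R01 = c(2, 0, 0)),
                     sigma_mouse = 500, sigma_resid = 750)
    ds <- vapply(1:60, function(i) {
        sim <- simulateCohort(a, cs, seed = 100 + i)
        mat <- SummarizedExperiment::assay(sim$dm, "density")
        cd <- SummarizedExperiment::colData(sim$dm)
        m <- cd$treatment == "morphine" & cd$sex == "male"
        s <- cd$treatment == "saline" & cd$sex == "male"
        x <- mat["R01", m]; y <- mat["R01", s]
        sp <- sqrt((var(x) * (length(x) - 1) + var(y) * (length(y) - 1)) /
                   (length(x) + length(y) - 2))
        (mean(x) - mean(y)) / sp
    }, numeric(1))
    expect_lt(abs(mean(ds) - 2), 0.3)
})

test_that("negative densities are clipped with a warning", {
    a <- makeToyAtlas(2L, c(24L, 24L, 24L), c(10, 10, 10), seed = 2)
    leaves <- structures(a)$acronym[structures(a)$is_gray_matter]
    cs <- cohortSpec(baseline_density = setNames(rep(1, 2), leaves),
                     sigma_mouse = 10, sigma_resid = 10)
    expect_warning(sim <- simulateCohort(a, cs, seed = 4), "clipped")
    expect_true(all(SummarizedExperiment::assay(sim$dm, "density") >= 0))
})

test_that("deformation modes honour their contracts", {
    a <- makeToyAtlas(2L, c(20L, 24L, 24L), c(10, 5, 5), seed = 1)
    idf <- simulateDeformation(a, "identity")
    expect_true(all(idf@displacements == 0))
    st <- spotTable(x_um = c(10, 50), y_um = c(20, 60), z_um = c(30, 70))
    expect_identical(spots(transformSpots(st, idf))[, 1:3], spots(st)[, 1:3])
    tr <- simulateDeformation(a, "translation", vector_um = c(10, 0, 0))
    moved <- spots(transformSpots(st, tr))
    expect_equal(moved$z_um, spots(st)$z_um + 10)
    expect_equal(moved$x_um, spots(st)$x_um)
    for (seed in 1:5) {
        w <- simulateDeformation(a, "smooth_warp", magnitude_um = 20,
                                 seed = seed)
        mags <- sqrt(apply(w@displacements^2, 1:3, sum))
        expect_lte(max(mags), 20)
        expect_gt(max(mags), 0)
    }
    expect_error(simulateDeformation(a, "banana"), "arg")
})
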