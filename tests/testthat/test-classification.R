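test_that("features separate puncta, edge planes and constant patches", {
    sp <- c(5.33, 1.5, 1.5)
    ## isotropic punctum on an isotropic grid: anisotropy near 1, low
    ## planarity
    spi <- c(2, 2, 2)
    vol <- array(0, c(40, 40, 40))
    cen <- c(20, 20, 20) * spi
    vol <- fosmap:::.renderBlob(vol, cen, c(3, 3, 3), 10, spi)
    st <- spotTable(x_um = cen[3], y_um = cen[2], z_um = cen[1])
    f <- extractFeatures(vol, spi, st, patch_radius_um = 10)
    expect_lt(abs(f$anisotropy - 1), 0.3)
    expect_lt(f$planarity, 0.5)
    ## point on a bright edge plane: planarity high
    vol2 <- array(0, c(30, 40, 40))
    vol2[1, , ] <- 10
    st2 <- spotTable(x_um = 20 * sp[3], y_um = 20 * sp[2], z_um = 0)
    f2 <- extractFeatures(vol2, sp, st2, patch_radius_um = 10)
    expect_gt(f2$planarity, 0.8)
    expect_equal(f2$border_distance_um, 0)
    ## constant patch: contrast 1, sd 0
    vol3 <- array(4, c(20, 20, 20))
    st3 <- spotTable(x_um = 10 * sp[3], y_um = 10 * sp[2],
                     z_um = 10 * sp[1])
    f3 <- extractFeatures(vol3, sp, st3, patch_radius_um = 10)
    expect_equal(f3$contrast_ratio, 1)
    expect_equal(f3$local_sd, 0)
    ## outside the volume errors
    st4 <- spotTable(x_um = -50, y_um = 0, z_um = 0)
    expect_error(extractFeatures(vol3, sp, st4), "outside")
})

test_that("feature extraction is translation-equivariant away from borders", {
    fx <- singleBlobVolume(center_vox = c(14, 18, 18))
    f1 <- extractFeatures(fx$volume, fx$spacing,
                          spotTable(x_um = fx$center_um[3],
                                    y_um = fx$center_um[2],
                                    z_um = fx$center_um[1]))
    shift_vox <- c(2, 4, 4)
    fx2 <- singleBlobVolume(center_vox = c(14, 18, 18) + shift_vox)
    f2 <- extractFeatures(fx2$volume, fx2$spacing,
                          spotTable(x_um = fx2$center_um[3],
                                    y_um = fx2$center_um[2],
                                    z_um = fx2$center_um[1]))
    for (col in c("peak_intensity", "local_mean", "local_sd",
                  "contrast_ratio", "anisotropy", "planarity"))
        expect_equal(f1[[col]], f2[[col]], tolerance = 1e-8, info = col)
})

test_that("training demands both classes and separates separable data", {
    set.seed(5)
    n <- 60
    feats <- data.frame(peak_intensity = c(rnorm(n, 10), rnorm(n, 0)),
                        local_mean = rnorm(2 * n),
                        local_sd = rnorm(2 * n, 5),
                        contrast_ratio = c(rnorm(n, 8), rnorm(n, 1)),
                        anisotropy = 1 + abs(rnorm(2 * n)),
                        border_distance_um = runif(2 * n, 0, 50),
                        planarity = runif(2 * n, 0, 0.4))
    labels <- rep(c("cell", "non_cell"), each = n)
    expect_error(trainClassifier(feats[1:n, ], labels[1:n]),
                 "both classes")
    model <- trainClassifier(feats, labels, seed = 1)
    acc <- mean((predictCellProb(model, feats) >= 0.5) ==
                (labels == "cell"))
    expect_equal(acc, 1)
    ## determinism given seed
    model2 <- trainClassifier(feats, labels, seed = 1)
    expect_equal(predictCellProb(model, feats),
                 predictCellProb(model2, feats))
})

test_that("conflicting duplicate examples give probabilities near 0.5", {
    ## the same feature point (up to measurement jitter) labeled half
    ## cell, half non-cell: the classifier cannot take sides
    set.seed(6)
    one <- data.frame(peak_intensity = 1, local_mean = 1, local_sd = 1,
                      contrast_ratio = 1, anisotropy = 1,
                      border_distance_um = 1, planarity = 0.2)
    feats <- one[rep(1, 80), ] +
        matrix(rnorm(80 * 7, 0, 1e-6), 80, 7)
    labels <- rep(c("cell", "non_cell"), 40)
    model <- trainClassifier(feats, labels, seed = 2)
    p <- predictCellProb(model, one)
    expect_gt(p, 0.3)
    expect_lt(p, 0.7)
})

test_that("phantom-trained classifier reaches held-out F1 >= 0.9", {
    ph <- smallPhantom()
    model <- smallClassifier()      # trained on seed 99 phantom
    sp <- spacing(ph$atlas)
    mask <- foregroundMask(ph$volume, sp)
    cons <- consolidateSpots(spotBind(
        detectConventional(ph$volume, sp,
                           sigma_um = ph$spec$puncta_sigma_um, mask = mask),
        detectMatched(ph$volume, sp,
                      template_sigma_um = ph$spec$puncta_sigma_um,
                      mask = mask)), 5)
    cls <- classifySpots(model, ph$volume, sp, cons)
    cells <- cellsOnly(cls)
    mr <- matchSpots(cells, ph$truth, 5)
    expect_gte(mr@f1, 0.9)
    ## classification is deterministic given the fitted model
    cls2 <- classifySpots(model, ph$volume, sp, cons)
    expect_identical(spots(cls), spots(cls2))
    ## downstream count is in the right range for ~150 true puncta
    n_truth <- nrow(spots(ph$truth))
    expect_gt(nrow(spots(cells)), 0.8 * n_truth)
    expect_lt(nrow(spots(cells)), 1.3 * n_truth)
})

test_that("decision threshold corners behave as documented", {
    ph <- smallPhantom()
    model <- smallClassifier()
    sp <- spacing(ph$atlas)
    st <- spotTable(x_um = c(30, 60), y_um = c(30, 60), z_um = c(50, 100))
    m0 <- model; m0@decision_threshold <- 0
    all_in <- classifySpots(m0, ph$volume, sp, st)
    expect_true(all(spots(all_in)$is_cell))
    m1 <- model; m1@decision_threshold <- 1
    only_sure <- classifySpots(m1, ph$volume, sp, st)
    expect_identical(spots(only_sure)$is_cell,
                     spots(only_sure)$score == 1)
})

test_that("fine-tuning with no examples is a no-op and adapts otherwise", {
    model <- smallClassifier()
    same <- fineTune(model, data.frame(), character(0))
    expect_identical(same@manifest, model@manifest)
    ## shifted-intensity phantom: the base model degrades, fine-tuning on
    ## ~100 local examples restores the acceptance gate
    ph <- smallPhantom()
    sp <- spacing(ph$atlas)
    shifted <- ph$volume * 0.12        # much dimmer acquisition
    mask <- foregroundMask(shifted, sp)
    cons <- consolidateSpots(spotBind(
        detectConventional(shifted, sp,
                           sigma_um = ph$spec$puncta_sigma_um, mask = mask),
        detectMatched(shifted, sp,
                      template_sigma_um = ph$spec$puncta_sigma_um,
                      mask = mask)), 5)
    f1_of <- function(m) {
        cells <- cellsOnly(classifySpots(m, shifted, sp, cons))
        matchSpots(cells, ph$truth, 5)@f1
    }
    base_f1 <- f1_of(model)
    expect_lt(base_f1, 0.8)            # the gate fails on this brain
    lab <- fosmap:::.labelAgainstTruth(cons, ph$truth, 5)
    feats <- extractFeatures(shifted, sp, cons)
    set.seed(41)
    pick <- sample(nrow(feats), 100)
    tuned <- fineTune(model, feats[pick, ], lab[pick], seed = 4)
    expect_gte(f1_of(tuned), 0.8)
    ## tuning never hurts accuracy on the extra examples
    acc <- function(m) mean((predictCellProb(m, feats[pick, ]) >= 0.5) ==
                            (lab[pick] == "cell"))
    expect_gte(acc(tuned), acc(model))
})
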