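#' The reference detection phantom
#'
#' A fixed synthetic benchmark for the end-to-end detection gate: a
#' 100 x 512 x 512 voxel volume at the anisotropic acquisition spacing
#' (5.33 x 0.361 x 0.361 um in z/y/x), with a puncta rate chosen to place
#' roughly 250 Gaussian puncta (expected count >= 200) in the tissue block
#' at SNR 8, plus one edge plane, two vessel tubes and ten noise spikes.
#'
#' @param seed integer seed.
#' @param shape_vox volume shape; the default is the benchmark size, tests
#'   may pass something smaller.
#' @param rate puncta intensity, cells/mm^3.
#' @return list with \code{atlas}, \code{spec}, \code{volume},
#'   \code{truth}.
#' @export
referencePhantom <- function(seed = 1L,
                             shape_vox = c(100L, 512L, 512L),
                             rate = 15000) {
    spacing <- c(5.33, 0.361, 0.361)
    atlas <- makeToyAtlas(4L, shape_vox, spacing, seed = seed,
                          margin_vox = 2L)
    s <- structures(atlas)
    leaf_ids <- s$id[s$is_gray_matter]
    spec <- phantomSpec(
        spacing_um = spacing,
        puncta_sigma_um = c(4, 1.5, 1.5),
        puncta_amplitude = 10, background_level = 1, noise_sd = 1.25,
        artifact_spec = c(edge_plane = 1L, vessel_tube = 2L,
                          noise_spike = 10L),
        region_rates = setNames(rep(rate, length(leaf_ids)), leaf_ids))
    sim <- simulateVolume(atlas, spec, seed = seed)
    list(atlas = atlas, spec = spec, volume = sim$volume,
         truth = sim$truth)
}

#' End-to-end detection gate on the reference phantom
#'
#' Runs the full detection stack — foreground masking, dual detection
#' (Laplacian-of-Gaussian and matched filter), DBSCAN consolidation,
#' cell/non-cell classification with a model trained on a disjoint seeded
#' phantom — and scores the surviving cells against the generator's truth
#' table with one-to-one optimal matching at a 5-micrometre radius.
#'
#' @param seed integer seed for the evaluation phantom; the training
#'   phantom uses \code{seed + 1}.
#' @param shape_vox evaluation phantom shape.
#' @param train_shape_vox training phantom shape (disjoint, smaller).
#' @param rate puncta rate, cells/mm^3.
#' @return list with \code{f1}, \code{precision}, \code{recall},
#'   \code{n_truth}, \code{n_cells}, \code{match} (a [MatchResult]).
#' @export
detectionGateF1 <- function(seed = 1L,
                            shape_vox = c(100L, 512L, 512L),
                            train_shape_vox = c(60L, 256L, 256L),
                            rate = 15000) {
    ref <- referencePhantom(seed, shape_vox, rate)
    sp <- ref$spec$spacing_um
    ## classifier trained on a disjoint phantom (own atlas, own seed)
    train_atlas <- makeToyAtlas(4L, train_shape_vox, sp, seed = seed + 1L,
                                margin_vox = 2L)
    ts <- structures(train_atlas)
    tspec <- phantomSpec(
        spacing_um = sp, puncta_sigma_um = ref$spec$puncta_sigma_um,
        puncta_amplitude = ref$spec$puncta_amplitude,
        background_level = ref$spec$background_level,
        noise_sd = ref$spec$noise_sd,
        artifact_spec = ref$spec$artifact_spec,
        region_rates = setNames(rep(rate, sum(ts$is_gray_matter)),
                                ts$id[ts$is_gray_matter]))
    model <- .trainOnPhantom(train_atlas, tspec, seed = seed + 1L)

    mask <- foregroundMask(ref$volume, sp)
    det_c <- detectConventional(ref$volume, sp,
                                sigma_um = ref$spec$puncta_sigma_um,
                                mask = mask)
    det_m <- detectMatched(ref$volume, sp,
                           template_sigma_um = ref$spec$puncta_sigma_um,
                           mask = mask)
    cons <- consolidateSpots(spotBind(det_c, det_m), 5)
    cls <- classifySpots(model, ref$volume, sp, cons)
    cells <- cellsOnly(cls)
    mr <- matchSpots(cells, ref$truth, 5)
    list(f1 = mr@f1, precision = mr@precision, recall = mr@recall,
         n_truth = nrow(spots(ref$truth)),
         n_cells = nrow(spots(cells)), match = mr)
}
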