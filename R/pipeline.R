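#' Default pipeline configuration
#'
#' Describes an end-to-end desk-scale run: a toy atlas, a small number of
#' imaged synthetic brains that flow through detection, consolidation,
#' classification, mapping and aggregation, and a full factorial cohort at
#' the density level whose imaged animals take their measured densities
#' from the imaging track. Stages write their artifacts plus a JSON
#' manifest (parameters and input checksums); re-running with unchanged
#' inputs skips completed stages.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n_imaged_brains number of brains pushed through the imaging
#'   track.
#' @param atlas list: \code{n_regions}, \code{shape_vox}, \code{spacing_um}.
#' @param phantom_rate mean puncta density (cells/mm^3) for imaged brains.
#' @param phantom overrides for [phantomSpec()] fields.
#' @param cohort overrides for [cohortSpec()] fields
#'   (\code{baseline_density}, \code{effect_map}, ...).
#' @param analysis an [analysisConfig()].
#' @return a nested list with class \code{"fosmap_pipeline_config"}.
#' @export
pipelineConfig <- function(out_dir, seed = 1L, n_imaged_brains = 2L,
                           atlas = list(n_regions = 4L,
                                        shape_vox = c(48L, 72L, 72L),
                                        spacing_um = c(5, 2, 2)),
                           phantom_rate = 60000,
                           phantom = list(),
                           cohort = list(),
                           analysis = analysisConfig(rng_seed = seed)) {
    cfg <- list(out_dir = out_dir, seed = as.integer(seed),
                n_imaged_brains = as.integer(n_imaged_brains),
                atlas = atlas, phantom_rate = phantom_rate,
                phantom = phantom, cohort = cohort, analysis = analysis)
    class(cfg) <- "fosmap_pipeline_config"
    cfg
}

.manifestPath <- function(out_dir, stage)
    file.path(out_dir, sprintf("manifest_%s.json", stage))

.writeManifest <- function(out_dir, stage, params, inputs, outputs,
                           counts = NULL) {
    man <- list(stage = stage, params = params,
                input_md5 = as.list(tools::md5sum(inputs)),
                outputs = outputs,
                output_md5 = as.list(tools::md5sum(outputs)),
                counts = counts)
    jsonlite::write_json(man, .manifestPath(out_dir, stage),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
}

.stageCurrent <- function(out_dir, stage, params, inputs) {
    mp <- .manifestPath(out_dir, stage)
    if (!file.exists(mp)) return(FALSE)
    man <- try(jsonlite::fromJSON(mp), silent = TRUE)
    if (inherits(man, "try-error")) return(FALSE)
    if (!identical(jsonlite::toJSON(man$params, auto_unbox = TRUE,
                                    digits = NA),
                   jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)))
        return(FALSE)
    cur <- as.list(tools::md5sum(names(man$input_md5)))
    if (!identical(unname(unlist(cur)), unname(unlist(man$input_md5))))
        return(FALSE)
    all(file.exists(unlist(man$outputs)))
}

.log <- function(out_dir, fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = file.path(out_dir, "pipeline.log"),
        append = TRUE, sep = "")
    message(line)
}

#' Run the end-to-end pipeline
#'
#' Executes, in dependency order: atlas simulation; per-brain phantom
#' simulation, dual detection, consolidation, classifier training (on a
#' disjoint training phantom) and classification, per-brain validation
#' against the truth patch, deformation-field transform, region assignment
#' and aggregation; cohort density-matrix assembly (imaged animals take
#' their measured densities); and the inference stack, which writes the
#' effects CSV and a JSON response report. Each stage writes a manifest
#' and is skipped when its inputs are unchanged; counts are logged at
#' every stage and conservation (cells <= consolidated <= detected union)
#' is asserted.
#'
#' @param config a [pipelineConfig()].
#' @return list of stage manifests, invisibly.
#' @export
runPipeline <- function(config) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    manifests <- list()

    ## stage: atlas -----------------------------------------------------
    atlas_dir <- file.path(od, "atlas")
    params <- c(config$atlas, seed = seed)
    if (!.stageCurrent(od, "atlas", params, character(0))) {
        atlas <- makeToyAtlas(config$atlas$n_regions,
                              config$atlas$shape_vox,
                              config$atlas$spacing_um, seed = seed)
        writeAtlas(atlas, atlas_dir)
        manifests$atlas <- .writeManifest(
            od, "atlas", params, character(0),
            file.path(atlas_dir, c("ontology.json", "labels.tif")))
        .log(od, "atlas: %d structures", nrow(structures(atlas)))
    } else .log(od, "atlas: up to date, skipped")
    atlas <- readAtlas(atlas_dir)
    s <- structures(atlas)
    leaves <- s$acronym[s$is_gray_matter]

    ## stage: classifier training phantom -------------------------------
    spec0 <- do.call(phantomSpec, utils::modifyList(
        list(spacing_um = config$atlas$spacing_um,
             region_rates = setNames(
                 rep(config$phantom_rate, length(leaves)),
                 s$id[match(leaves, s$acronym)])),
        config$phantom))
    model_path <- file.path(od, "classifier.rds.json")
    params <- list(seed = seed + 1000L, rate = config$phantom_rate)
    if (!.stageCurrent(od, "train", params,
                       file.path(atlas_dir, "labels.tif"))) {
        model <- .trainOnPhantom(atlas, spec0, seed = seed + 1000L)
        .saveClassifier(model, model_path)
        manifests$train <- .writeManifest(
            od, "train", params, file.path(atlas_dir, "labels.tif"),
            model_path)
        .log(od, "classifier: %d cell / %d non-cell training examples",
             model@manifest$n_cell, model@manifest$n_non_cell)
    } else .log(od, "classifier: up to date, skipped")
    model <- .loadClassifier(model_path)

    ## per-brain imaging track ------------------------------------------
    imaged <- character(0)
    counts_list <- list()
    for (b in seq_len(config$n_imaged_brains)) {
        bid <- sprintf("brain%02d", b)
        bdir <- file.path(od, bid)
        dir.create(bdir, showWarnings = FALSE)
        bseed <- seed + 10L * b
        stage <- paste0("image_", bid)
        cells_csv <- file.path(bdir, "cells.csv")
        counts_csv <- file.path(bdir, "region_counts.csv")
        params <- list(seed = bseed, rate = config$phantom_rate)
        if (!.stageCurrent(od, stage, params,
                           file.path(atlas_dir, "labels.tif"))) {
            sim <- simulateVolume(atlas, spec0, seed = bseed)
            writeSpots(sim$truth, file.path(bdir, "truth.csv"))
            sp <- spacing(atlas)
            mask <- foregroundMask(sim$volume, sp)
            det_c <- detectConventional(sim$volume, sp,
                                        sigma_um = spec0$puncta_sigma_um,
                                        mask = mask)
            det_m <- detectMatched(sim$volume, sp,
                                   template_sigma_um = spec0$puncta_sigma_um,
                                   mask = mask)
            uni <- spotBind(det_c, det_m)
            cons <- consolidateSpots(uni,
                                     config$analysis$consolidation_eps_um)
            cls <- classifySpots(model, sim$volume, sp, cons)
            cells <- cellsOnly(cls)
            stopifnot(nrow(spots(cells)) <= nrow(spots(cons)),
                      nrow(spots(cons)) <= nrow(spots(uni)))
            field <- simulateDeformation(atlas, "identity")
            mapped <- assignRegions(transformSpots(cells, field), atlas)
            writeSpots(mapped, cells_csv)
            rc <- aggregateRegions(mapped, atlas@ontology, animal_id = bid)
            stopifnot(attr(rc, "n_assigned") + attr(rc, "n_unassigned") ==
                      nrow(spots(cells)))
            write.csv(rc, counts_csv, row.names = FALSE)
            .log(od, "%s: detected %d+%d, consolidated %d, cells %d, assigned %d",
                 bid, nrow(spots(det_c)), nrow(spots(det_m)),
                 nrow(spots(cons)), nrow(spots(cells)),
                 attr(rc, "n_assigned"))
            manifests[[stage]] <- .writeManifest(
                od, stage, params, file.path(atlas_dir, "labels.tif"),
                c(cells_csv, counts_csv), counts = list(
                    detected = nrow(spots(uni)),
                    consolidated = nrow(spots(cons)),
                    cells = nrow(spots(cells))))
        } else .log(od, "%s: up to date, skipped", bid)
        rc <- read.csv(counts_csv, stringsAsFactors = FALSE)
        attr(rc, "animal_id") <- bid
        counts_list[[bid]] <- rc
        imaged <- c(imaged, bid)
    }

    ## stage: cohort densities ------------------------------------------
    dm_csv <- file.path(od, "density_matrix.csv")
    stage_in <- vapply(imaged, function(b)
        file.path(od, b, "region_counts.csv"), character(1))
    params <- list(seed = seed + 2000L)
    if (!.stageCurrent(od, "cohort", params, stage_in)) {
        baseline <- setNames(rep(config$phantom_rate, length(leaves)),
                             leaves)
        cspec <- do.call(cohortSpec, utils::modifyList(
            list(baseline_density = baseline), config$cohort))
        sim <- simulateCohort(atlas, cspec, seed = seed + 2000L)
        dm <- sim$dm
        ## imaged animals contribute their measured densities (first rows
        ## of the design, leaf regions only)
        mat <- SummarizedExperiment::assay(dm, "density")
        rd <- SummarizedExperiment::rowData(dm)
        for (j in seq_along(imaged)) {
            rc <- counts_list[[imaged[j]]]
            m <- match(rd$id, rc$id)
            mat[, j] <- rc$density[m]
        }
        dm2 <- densityMatrix(mat, region_id = rd$id, acronym = rd$acronym,
                             meta = as.data.frame(
                                 SummarizedExperiment::colData(dm)))
        writeDensityMatrix(dm2, dm_csv)
        manifests$cohort <- .writeManifest(od, "cohort", params, stage_in,
                                           dm_csv)
        .log(od, "cohort: %d animals x %d regions", ncol(mat), nrow(mat))
    } else .log(od, "cohort: up to date, skipped")

    ## stage: stats ------------------------------------------------------
    eff_csv <- file.path(od, "effects.csv")
    rep_json <- file.path(od, "report.json")
    params <- list(seed = config$analysis$rng_seed,
                   d = config$analysis$d_threshold,
                   q = config$analysis$q_threshold)
    if (!.stageCurrent(od, "stats", params, dm_csv)) {
        rd_ids <- s$id[match(leaves, s$acronym)]
        dm <- readDensityMatrix(dm_csv, region_ids = rd_ids)
        rep_ <- analyzeCohort(dm, atlas@ontology, config$analysis)
        write.csv(rep_$effects, eff_csv, row.names = FALSE)
        jsonlite::write_json(
            list(responsive_regions = rep_$responsive_regions,
                 responsive_by_group = rep_$responsive_by_group,
                 time_difference = rep_$time_difference,
                 sex_difference = rep_$sex_difference,
                 significant_regions = rep_$significant_regions,
                 rf_cv_f1 = rep_$selection$cv_f1),
            rep_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        manifests$stats <- .writeManifest(od, "stats", params, dm_csv,
                                          c(eff_csv, rep_json))
        .log(od, "stats: %d regions analyzed, %d responsive",
             length(unique(rep_$effects$region)),
             length(rep_$responsive_regions))
    } else .log(od, "stats: up to date, skipped")
    invisible(manifests)
}

## train the classifier on a disjoint seeded phantom: truth puncta are cell
## examples; artifact and off-target detections (unmatched at the 5-um
## radius) are non-cell examples
.trainOnPhantom <- function(atlas, spec, seed, n_trees = 200L) {
    sim <- simulateVolume(atlas, spec, seed = seed)
    sp <- spec$spacing_um
    det <- spotBind(
        detectConventional(sim$volume, sp, sigma_um = spec$puncta_sigma_um),
        detectMatched(sim$volume, sp,
                      template_sigma_um = spec$puncta_sigma_um))
    cons <- consolidateSpots(det, 5)
    lab <- .labelAgainstTruth(cons, sim$truth, 5)
    feats <- extractFeatures(sim$volume, sp, cons)
    if (length(unique(lab)) < 2L)
        stop("training phantom produced a single class; adjust artifacts")
    trainClassifier(feats, lab, seed = seed, n_trees = n_trees)
}

## greedy radius labeling is enough for training labels (not scoring)
.labelAgainstTruth <- function(pred, truth, radius_um) {
    P <- .spotXYZ(pred)
    T_ <- .spotXYZ(truth)
    lab <- rep("non_cell", nrow(P))
    if (nrow(T_)) {
        pairs <- .feasiblePairs(P, T_, radius_um)
        lab[unique(pairs[, 1])] <- "cell"
    }
    factor(lab, levels = c("cell", "non_cell"))
}

.saveClassifier <- function(model, path) {
    ## JSON manifest + base64 serialized fit in one text file
    blob <- jsonlite::base64_enc(serialize(model@fit, NULL))
    jsonlite::write_json(
        list(manifest = model@manifest,
             decision_threshold = model@decision_threshold,
             features = model@features,
             labels = as.character(model@labels),
             fit_b64 = blob),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

.loadClassifier <- function(path) {
    obj <- jsonlite::fromJSON(path)
    fit <- unserialize(jsonlite::base64_dec(obj$fit_b64))
    new("CellClassifier", fit = fit,
        decision_threshold = obj$decision_threshold,
        features = as.data.frame(obj$features),
        labels = factor(obj$labels, levels = c("cell", "non_cell")),
        manifest = obj$manifest)
}

#' Validate a brain's detections against a ground-truth patch
#'
#' Ground truth is annotated in a small region of interest; predicted spots
#' are scored only within the patch bounds (predictions outside are
#' ignored), with one-to-one matching at the configured radius. The brain
#' is accepted iff F1 strictly exceeds the acceptance gate (default 0.80);
#' on rejection the returned record notes that classifier fine-tuning is
#' required.
#'
#' @param pred a [SpotTable] of predicted cells (whole brain or patch).
#' @param truth_patch a [SpotTable] of ground-truth spots inside the patch.
#' @param patch_bounds list with \code{z}, \code{y}, \code{x}, each a
#'   c(lo, hi) in world micrometres.
#' @param config an [analysisConfig()].
#' @return list with \code{accept}, \code{f1}, \code{match} (a
#'   [MatchResult]), \code{fine_tune_required}.
#' @export
validateBrain <- function(pred, truth_patch, patch_bounds,
                          config = analysisConfig()) {
    tdf <- spots(truth_patch)
    if (nrow(tdf) == 0L) stop("validation error: empty truth patch")
    inb <- function(df) df$z_um >= patch_bounds$z[1] &
        df$z_um <= patch_bounds$z[2] &
        df$y_um >= patch_bounds$y[1] & df$y_um <= patch_bounds$y[2] &
        df$x_um >= patch_bounds$x[1] & df$x_um <= patch_bounds$x[2]
    pred_in <- spotSubset(pred, inb(spots(pred)))
    truth_in <- spotSubset(truth_patch, inb(tdf))
    if (nrow(spots(truth_in)) == 0L)
        stop("validation error: no truth spots inside the patch bounds")
    mr <- matchSpots(pred_in, truth_in, config$match_radius_um)
    accept <- mr@f1 > config$f1_acceptance
    list(accept = accept, f1 = mr@f1, match = mr,
         fine_tune_required = !accept)
}
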