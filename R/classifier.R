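#' Train the binary cell / non-cell classifier
#'
#' Fits a random forest on [extractFeatures()] rows. This plays the role a
#' raw-patch deep classifier plays at datacenter scale: a binary
#' discriminator between real puncta and detection artifacts, with the same
#' train / fine-tune / predict contract. Training is deterministic given
#' \code{seed}.
#'
#' @param features data.frame of patch features.
#' @param labels factor or character vector with levels \code{cell} /
#'   \code{non_cell}.
#' @param seed integer seed.
#' @param n_trees forest size.
#' @param decision_threshold probability cut used by [classifySpots()].
#' @return a [CellClassifier].
#' @export
trainClassifier <- function(features, labels, seed = 1L, n_trees = 200L,
                            decision_threshold = 0.5) {
    labels <- factor(as.character(labels), levels = c("cell", "non_cell"))
    if (anyNA(labels)) stop("labels must be 'cell' or 'non_cell'")
    if (nlevels(droplevels(labels)) < 2L)
        stop("training error: both classes must be present")
    stopifnot(nrow(features) == length(labels))
    set.seed(seed)
    fit <- randomForest::randomForest(x = features, y = labels,
                                      ntree = n_trees)
    new("CellClassifier", fit = fit,
        decision_threshold = decision_threshold,
        features = as.data.frame(features), labels = labels,
        manifest = list(n_cell = sum(labels == "cell"),
                        n_non_cell = sum(labels == "non_cell"),
                        n_extra = 0L, seed = as.integer(seed),
                        n_trees = as.integer(n_trees)))
}

#' Fine-tune a classifier on a handful of local examples
#'
#' Some brains differ enough from the training distribution (staining
#' intensity, background) that the base classifier drops below the
#' acceptance gate; a small number of locally annotated examples (tens to a
#' couple of hundred) then adapts it. The model is refit on the original
#' training set plus the extra examples, with the extra examples weighted
#' x5 (by replication) so a small local sample can shift the decision
#' boundary without erasing what the base model learned. The original model
#' is not modified.
#'
#' @param model a [CellClassifier].
#' @param extra_features,extra_labels the local annotated examples.
#' @param seed integer seed.
#' @param weight replication factor for the extra examples.
#' @return a new [CellClassifier].
#' @export
fineTune <- function(model, extra_features, extra_labels, seed = 1L,
                     weight = 5L) {
    stopifnot(is(model, "CellClassifier"))
    if (NROW(extra_features) == 0L) return(model)
    extra_labels <- factor(as.character(extra_labels),
                           levels = c("cell", "non_cell"))
    rep_idx <- rep(seq_len(NROW(extra_features)), each = weight)
    feats <- rbind(model@features,
                   as.data.frame(extra_features)[rep_idx, , drop = FALSE])
    labs <- factor(c(as.character(model@labels),
                     as.character(extra_labels)[rep_idx]),
                   levels = c("cell", "non_cell"))
    tuned <- trainClassifier(feats, labs, seed = seed,
                             n_trees = model@manifest$n_trees,
                             decision_threshold = model@decision_threshold)
    tuned@manifest$n_cell <- model@manifest$n_cell
    tuned@manifest$n_non_cell <- model@manifest$n_non_cell
    tuned@manifest$n_extra <- model@manifest$n_extra +
        NROW(extra_features)
    tuned
}

#' Probability that feature rows are cells
#'
#' @param model a [CellClassifier].
#' @param features data.frame of patch features.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictCellProb <- function(model, features) {
    if (!is(model@fit, "randomForest")) stop("state error: model not fitted")
    as.numeric(predict(model@fit, newdata = features,
                       type = "prob")[, "cell"])
}

#' Classify consolidated spots as cells or artifacts
#'
#' Each spot gains \code{score} = probability(cell) and \code{is_cell} =
#' \code{score >= decision_threshold}. Only spots with \code{is_cell} should
#' proceed to atlas mapping; border-flagged spots are classified like any
#' other (the features carry the border distance).
#'
#' @param model a [CellClassifier].
#' @param volume 3D array the spots were detected in.
#' @param spacing_um numeric(3) micrometres per voxel.
#' @param st a [SpotTable] of consolidated spots.
#' @param patch_radius_um feature patch radius.
#' @return the [SpotTable] with \code{score} and \code{is_cell} filled in.
#' @export
classifySpots <- function(model, volume, spacing_um, st,
                          patch_radius_um = 10) {
    df <- spots(st)
    if (nrow(df) == 0L) return(st)
    feats <- extractFeatures(volume, spacing_um, st, patch_radius_um)
    df$score <- predictCellProb(model, feats)
    df$is_cell <- df$score >= model@decision_threshold
    new("SpotTable", spots = df)
}

#' Keep only spots classified as cells
#'
#' @param st a classified [SpotTable].
#' @return a [SpotTable] restricted to \code{is_cell} spots.
#' @export
cellsOnly <- function(st) spotSubset(st, !is.na(spots(st)$is_cell) &
                                         spots(st)$is_cell)
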