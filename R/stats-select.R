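#' Random-forest region pre-selection
#'
#' Screens regions before model fitting: a random forest is trained to
#' discriminate treatment groups from the wide density table (animals x
#' regions), stratified k-fold cross-validated F1 is reported, a final
#' forest is fit on the full data, and regions with nonzero impurity
#' importance are selected. Ancestors of selected regions are then pruned
#' with [excludeParents()], since parent and child densities are correlated
#' and would inject multicollinearity into the per-region models.
#'
#' @param dm a [DensityMatrix].
#' @param ontology the [BrainOntology] used for ancestor pruning.
#' @param n_trees forest size (default 300).
#' @param cv_folds requested folds; capped at the smaller treatment class
#'   size so every fold holds both classes.
#' @param seed integer seed.
#' @return list with \code{importances} (named, normalized to sum 1),
#'   \code{selected} (ids with importance > 0), \code{pruned} (after
#'   ancestor exclusion), \code{cv_f1}.
#' @export
selectRegions <- function(dm, ontology, n_trees = 300L, cv_folds = 10L,
                          seed = 1L) {
    mat <- t(SummarizedExperiment::assay(dm, "density"))  # animals x regions
    cd <- SummarizedExperiment::colData(dm)
    y <- factor(cd$treatment)
    if (nlevels(y) < 2L) stop("design error: single treatment class")
    if (min(table(y)) < 2L)
        stop("design error: need >= 2 animals per treatment class")
    rid <- SummarizedExperiment::rowData(dm)$id
    colnames(mat) <- as.character(rid)
    set.seed(seed)
    k <- min(cv_folds, min(table(y)))
    ## stratified fold assignment
    fold <- integer(length(y))
    for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k)) {
        tr <- fold != f
        fit <- randomForest::randomForest(x = mat[tr, , drop = FALSE],
                                          y = y[tr], ntree = n_trees)
        pred[!tr] <- predict(fit, mat[!tr, , drop = FALSE])
    }
    pos <- levels(y)[1]
    tp <- sum(pred == pos & y == pos)
    fp <- sum(pred == pos & y != pos)
    fn <- sum(pred != pos & y == pos)
    cv_f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    final <- randomForest::randomForest(x = mat, y = y, ntree = n_trees,
                                        importance = FALSE)
    imp <- randomForest::importance(final, type = 2)[, 1]
    if (sum(imp) > 0) imp <- imp / sum(imp)
    selected <- as.integer(names(imp)[imp > 0])
    pruned <- excludeParents(selected, ontology)
    list(importances = imp, selected = sort(selected), pruned = pruned,
         cv_f1 = cv_f1)
}
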