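#' @import methods
#' @importFrom stats median mad rnorm rpois runif rbinom sd var lm vcov coef
#'   pnorm predict setNames aggregate quantile p.adjust ave dnorm resid
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom Matrix bandSparse Diagonal rowSums
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite fromJSON write_json toJSON base64_enc base64_dec
#' @importFrom igraph make_graph components
#' @importFrom lme4 lmer VarCorr fixef
#' @importFrom randomForest randomForest importance
#' @importFrom tools md5sum
#' @importFrom yaml read_yaml
NULL

#' Hierarchical brain-structure ontology
#'
#' An atlas ontology is a rooted tree of brain structures. Each structure
#' carries a numeric id, a unique acronym, a display name, its parent id
#' (\code{NA} for the single root), its annotated volume in mm^3, a
#' gray-matter flag, and its depth in the tree (root = 0). The tree encodes
#' the recursive subdivision of broad anatomical divisions into nuclei and
#' layers, and drives descendant aggregation, the leaf/volume region filter
#' and ancestor pruning during region selection.
#'
#' @slot structures a \code{data.frame} with columns \code{id},
#'   \code{acronym}, \code{name}, \code{parent_id}, \code{volume_mm3},
#'   \code{is_gray_matter}, \code{depth}; one row per structure.
#'
#' @seealso [loadOntology()], [descendants()], [excludeParents()],
#'   [leafFilter()]
#' @export
setClass("BrainOntology", representation(structures = "data.frame"))

.validOntology <- function(object) {
    s <- object@structures
    need <- c("id", "acronym", "name", "parent_id", "volume_mm3",
              "is_gray_matter", "depth")
    if (!all(need %in% names(s)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(s)), collapse = ", ")))
    if (anyDuplicated(s$id)) return("structure ids must be unique")
    if (anyDuplicated(s$acronym)) return("structure acronyms must be unique")
    root <- is.na(s$parent_id)
    if (sum(root) != 1L) return("ontology must have exactly one root")
    if (any(!is.na(s$parent_id) & !(s$parent_id %in% s$id)))
        return("parent_id refers to unknown structure")
    if (any(s$volume_mm3 < 0)) return("volumes must be non-negative")
    ## depth consistency (also catches cycles: a cycle never gets a depth)
    d <- .computeDepths(s$id, s$parent_id)
    if (anyNA(d)) return("parent links contain a cycle")
    if (!identical(as.integer(s$depth), as.integer(d)))
        return("depth column inconsistent with parent links")
    TRUE
}
setValidity("BrainOntology", .validOntology)

## breadth-first depth computation; NA marks nodes never reached (cycles)
.computeDepths <- function(ids, parents) {
    depth <- rep(NA_integer_, length(ids))
    names(depth) <- as.character(ids)
    frontier <- ids[is.na(parents)]
    depth[as.character(frontier)] <- 0L
    level <- 0L
    while (length(frontier)) {
        children <- ids[!is.na(parents) & parents %in% frontier &
                        is.na(depth[as.character(ids)])]
        level <- level + 1L
        depth[as.character(children)] <- level
        frontier <- children
    }
    unname(depth[as.character(ids)])
}

#' Atlas bundle: ontology plus annotated label volume
#'
#' Pairs a [BrainOntology] with the 3D integer label volume that realizes it
#' and the voxel spacing in micrometres. Arrays are ordered (z, y, x) with z
#' the anterior-posterior axis; label 0 is background and never appears in
#' the ontology. Label volumes are mirror-labeled: left and right hemisphere
#' positions carry the same structure id, so left/right counterparts are
#' combined automatically during aggregation.
#'
#' @slot ontology a [BrainOntology].
#' @slot labels 3D integer array of structure ids (0 = background).
#' @slot spacing_um numeric(3), micrometres per voxel in (z, y, x) order.
#' @export
setClass("AtlasBundle", representation(ontology = "BrainOntology",
                                       labels = "array",
                                       spacing_um = "numeric"))

setValidity("AtlasBundle", function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (length(object@spacing_um) != 3L || any(object@spacing_um <= 0))
        return("spacing_um must be 3 positive values (z,y,x)")
    lab <- unique(as.integer(object@labels))
    lab <- lab[lab != 0L]
    if (!all(lab %in% object@ontology@structures$id))
        return("label volume contains ids absent from the ontology")
    if (0L %in% object@ontology@structures$id)
        return("label 0 is reserved for background")
    TRUE
})

#' Table of detected or ground-truth puncta
#'
#' Thin S4 wrapper around a spot \code{data.frame} in world micrometre
#' coordinates. Columns: \code{x_um}, \code{y_um}, \code{z_um},
#' \code{intensity}, \code{source} (one of \code{conventional},
#' \code{matched}, \code{consolidated}, \code{truth}), \code{score}
#' (classifier probability, \code{NA} until classified), \code{is_cell}
#' (\code{NA} until classified), \code{region_id} (\code{NA} until mapped),
#' and logical flags \code{border} and \code{out_of_grid}.
#'
#' @slot spots the spot \code{data.frame}.
#' @export
setClass("SpotTable", representation(spots = "data.frame"))

.spotCols <- c("x_um", "y_um", "z_um", "intensity", "source", "score",
               "is_cell", "region_id", "border", "out_of_grid")

setValidity("SpotTable", function(object) {
    s <- object@spots
    if (!all(.spotCols %in% names(s)))
        return(paste("missing columns:",
                     paste(setdiff(.spotCols, names(s)), collapse = ", ")))
    xyz <- as.matrix(s[, c("x_um", "y_um", "z_um")])
    if (nrow(s) && !all(is.finite(xyz)))
        return("spot coordinates must be finite")
    TRUE
})

#' Gridded deformation field (sample space to atlas space)
#'
#' Displacement vectors on a regular grid covering the sample volume. Adding
#' the (trilinearly interpolated) displacement to a sample world coordinate
#' yields the atlas world coordinate; the inverse direction is unsupported.
#'
#' @slot displacements 4D numeric array (z, y, x, 3); the last axis holds
#'   (dz, dy, dx) in micrometres.
#' @slot grid_spacing_um numeric(3), grid node spacing in micrometres (z,y,x).
#' @export
setClass("DeformationField", representation(displacements = "array",
                                            grid_spacing_um = "numeric"))

setValidity("DeformationField", function(object) {
    d <- dim(object@displacements)
    if (length(d) != 4L || d[4] != 3L)
        return("displacements must be a (z,y,x,3) array")
    if (!all(is.finite(object@displacements)))
        return("displacements must be finite")
    if (length(object@grid_spacing_um) != 3L ||
        any(object@grid_spacing_um <= 0))
        return("grid_spacing_um must be 3 positive values")
    TRUE
})

#' Cohort density matrix
#'
#' A \code{SummarizedExperiment} whose single assay \code{"density"} holds
#' c-Fos-positive cell densities (cells/mm^3), with brain regions as rows and
#' animals as columns. \code{colData} carries \code{animal_id},
#' \code{treatment}, \code{time} and \code{sex}; \code{rowData} carries the
#' region \code{id} and \code{acronym}. This is the wide-format table behind
#' region selection and the per-region linear models (one row per animal once
#' transposed for model fitting).
#'
#' @export
setClass("DensityMatrix", contains = "SummarizedExperiment")

#' Binary cell/non-cell classifier
#'
#' A fitted random-forest discriminator over [extractFeatures()] patch
#' features, replacing the raw-patch deep classifier of large-scale runs
#' while keeping the same train / fine-tune / predict contract. The training
#' set is retained so that fine-tuning can refit on the union of the original
#' and the new examples.
#'
#' @slot fit the fitted \code{randomForest} object.
#' @slot decision_threshold probability cut for calling a spot a cell.
#' @slot features training feature \code{data.frame} (retained for
#'   fine-tuning).
#' @slot labels training label factor (\code{cell}/\code{non_cell}).
#' @slot manifest list with training example counts.
#' @export
setClass("CellClassifier", representation(fit = "ANY",
                                          decision_threshold = "numeric",
                                          features = "data.frame",
                                          labels = "factor",
                                          manifest = "list"))

#' Result of radius-constrained one-to-one spot matching
#'
#' @slot n_truth,n_pred,n_matched counts.
#' @slot precision,recall,f1 scores in [0, 1]; \code{f1 = 2PR/(P+R)} when
#'   \code{P + R > 0}, else 0.
#' @export
setClass("MatchResult", representation(n_truth = "integer",
                                       n_pred = "integer",
                                       n_matched = "integer",
                                       precision = "numeric",
                                       recall = "numeric",
                                       f1 = "numeric"))

setValidity("MatchResult", function(object) {
    if (object@n_matched > min(object@n_truth, object@n_pred))
        return("n_matched exceeds min(n_truth, n_pred)")
    TRUE
})
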