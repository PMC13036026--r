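#' @rdname BrainOntology-class
#' @param object,x a package object
#' @export
setGeneric("structures", function(object) standardGeneric("structures"))

#' @rdname SpotTable-class
#' @export
setGeneric("spots", function(object) standardGeneric("spots"))

#' @rdname AtlasBundle-class
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))

#' @rdname AtlasBundle-class
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @export
#' @rdname BrainOntology-class
setMethod("structures", "BrainOntology", function(object) object@structures)

#' @export
#' @rdname AtlasBundle-class
setMethod("structures", "AtlasBundle",
          function(object) object@ontology@structures)

#' @export
#' @rdname SpotTable-class
setMethod("spots", "SpotTable", function(object) object@spots)

#' @export
#' @rdname AtlasBundle-class
setMethod("labelVolume", "AtlasBundle", function(object) object@labels)

#' @export
#' @rdname AtlasBundle-class
setMethod("spacing", "AtlasBundle", function(object) object@spacing_um)

#' @export
#' @rdname DeformationField-class
setMethod("spacing", "DeformationField",
          function(object) object@grid_spacing_um)

setMethod("show", "BrainOntology", function(object) {
    s <- object@structures
    cat(sprintf("BrainOntology: %d structures, max depth %d, %d leaves\n",
                nrow(s), max(s$depth), sum(!(s$id %in% s$parent_id))))
})

setMethod("show", "AtlasBundle", function(object) {
    d <- dim(object@labels)
    cat(sprintf("AtlasBundle: %dx%dx%d voxels (z,y,x) at %.3g/%.3g/%.3g um, %d structures\n",
                d[1], d[2], d[3], object@spacing_um[1], object@spacing_um[2],
                object@spacing_um[3], nrow(object@ontology@structures)))
})

setMethod("show", "SpotTable", function(object) {
    s <- object@spots
    cat(sprintf("SpotTable: %d spots (%s)\n", nrow(s),
                if (nrow(s)) paste(names(table(s$source)), table(s$source),
                                   sep = "=", collapse = ", ") else "empty"))
})

setMethod("show", "DeformationField", function(object) {
    d <- dim(object@displacements)
    cat(sprintf("DeformationField: %dx%dx%d grid, spacing %s um, max |d| %.3g um\n",
                d[1], d[2], d[3],
                paste(signif(object@grid_spacing_um, 3), collapse = "/"),
                max(abs(object@displacements))))
})

setMethod("show", "MatchResult", function(object) {
    cat(sprintf("MatchResult: %d/%d pred, %d/%d truth matched; P=%.3f R=%.3f F1=%.3f\n",
                object@n_matched, object@n_pred, object@n_matched,
                object@n_truth, object@precision, object@recall, object@f1))
})

setMethod("show", "CellClassifier", function(object) {
    cat(sprintf("CellClassifier: trained on %d cell / %d non-cell examples, threshold %.2f\n",
                object@manifest$n_cell, object@manifest$n_non_cell,
                object@decision_threshold))
})
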