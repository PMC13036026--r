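#' Construct an ontology from a structure table
#'
#' Builds and validates a [BrainOntology] from a flat table of structure
#' records. Depth is always recomputed from the parent links, never trusted
#' from the caller.
#'
#' @param df data.frame with columns \code{id}, \code{acronym}, \code{name},
#'   \code{parent_id}, \code{volume_mm3}, \code{is_gray_matter}.
#' @param child_volume_tol tolerance (mm^3) by which the summed child volumes
#'   may exceed their parent's. Parents may legitimately exceed their
#'   children (unannotated interior volume); the opposite direction beyond
#'   the tolerance is an error.
#' @return a validated [BrainOntology].
#' @export
ontologyFromTable <- function(df, child_volume_tol = 1e-6) {
    df <- as.data.frame(df)
    df$id <- as.integer(df$id)
    df$parent_id <- as.integer(df$parent_id)
    if (anyDuplicated(df$id))
        stop("ontology format error: duplicate structure id")
    if (anyDuplicated(df$acronym))
        stop("ontology format error: duplicate acronym")
    if (sum(is.na(df$parent_id)) != 1L)
        stop("ontology format error: must have exactly one root")
    depth <- .computeDepths(df$id, df$parent_id)
    if (anyNA(depth))
        stop("ontology format error: parent links contain a cycle")
    df$depth <- as.integer(depth)
    df <- df[order(df$depth, df$acronym), , drop = FALSE]
    rownames(df) <- NULL
    ## parent >= sum(children) - tol
    kidsum <- tapply(df$volume_mm3, df$parent_id, sum)
    for (pid in names(kidsum)) {
        pv <- df$volume_mm3[df$id == as.integer(pid)]
        if (kidsum[[pid]] > pv + child_volume_tol)
            stop(sprintf(
                "ontology format error: children of structure %s sum to %.6g mm^3, exceeding parent volume %.6g",
                pid, kidsum[[pid]], pv))
    }
    new("BrainOntology",
        structures = df[, c("id", "acronym", "name", "parent_id",
                            "volume_mm3", "is_gray_matter", "depth")])
}

#' Read an ontology from structure-graph style JSON
#'
#' The on-disk dialect is a flat JSON array of objects with fields
#' \code{id}, \code{acronym}, \code{name}, \code{parent_structure_id}
#' (\code{null} at the root), \code{volume_mm3} and \code{gray_matter}.
#'
#' @param path path to the JSON file.
#' @return a validated [BrainOntology]; depth is computed, not read.
#' @export
loadOntology <- function(path) {
    if (!file.exists(path)) stop("ontology file not found: ", path)
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    need <- c("id", "acronym", "name", "parent_structure_id", "volume_mm3",
              "gray_matter")
    if (!all(need %in% names(recs)))
        stop("ontology format error: missing fields ",
             paste(setdiff(need, names(recs)), collapse = ", "))
    ontologyFromTable(data.frame(
        id = recs$id, acronym = recs$acronym, name = recs$name,
        parent_id = recs$parent_structure_id,
        volume_mm3 = recs$volume_mm3,
        is_gray_matter = as.logical(recs$gray_matter),
        stringsAsFactors = FALSE))
}

#' Write an ontology as structure-graph style JSON
#'
#' @param ontology a [BrainOntology].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOntology <- function(ontology, path) {
    s <- structures(ontology)
    jsonlite::write_json(
        data.frame(id = s$id, acronym = s$acronym, name = s$name,
                   parent_structure_id = s$parent_id,
                   volume_mm3 = s$volume_mm3,
                   gray_matter = s$is_gray_matter),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}

.childrenMap <- function(s) split(s$id, factor(s$parent_id, levels = s$id))

#' Transitive descendants of a structure
#'
#' @param ontology a [BrainOntology].
#' @param id structure id.
#' @return integer vector of all strict descendants (empty for a leaf).
#' @export
descendants <- function(ontology, id) {
    s <- structures(ontology)
    id <- as.integer(id)
    if (!(id %in% s$id)) stop("unknown structure id: ", id)
    out <- integer(0)
    frontier <- s$id[!is.na(s$parent_id) & s$parent_id == id]
    while (length(frontier)) {
        out <- c(out, frontier)
        frontier <- s$id[!is.na(s$parent_id) & s$parent_id %in% frontier]
    }
    sort(out)
}

#' Drop structures whose descendants are already selected
#'
#' Region pre-selection can return both a parent and (some of) its children;
#' parent and child densities are strongly correlated, so keeping both
#' injects multicollinearity into downstream models. This removes every
#' selected structure that has at least one selected strict descendant,
#' leaving an ancestry antichain. "Descendant" means any depth, not only
#' direct children. Idempotent.
#'
#' @param selected integer vector of selected structure ids.
#' @param ontology a [BrainOntology].
#' @return the pruned id set (sorted).
#' @export
excludeParents <- function(selected, ontology) {
    selected <- unique(as.integer(selected))
    s <- structures(ontology)
    if (!all(selected %in% s$id))
        stop("selected contains ids absent from the ontology")
    drop <- vapply(selected, function(id)
        any(descendants(ontology, id) %in% selected), logical(1))
    sort(selected[!drop])
}

#' Leaf structures above a volume threshold
#'
#' Returns the deepest (childless) structures whose annotated volume is
#' strictly greater than \code{min_volume_mm3}, sorted by acronym. The
#' default threshold of 0.25 mm^3 drops leaves too small for stable density
#' estimates at typical registration accuracy.
#'
#' @param ontology a [BrainOntology].
#' @param min_volume_mm3 strict lower bound on leaf volume (mm^3).
#' @return integer vector of structure ids.
#' @export
leafFilter <- function(ontology, min_volume_mm3 = 0.25) {
    s <- structures(ontology)
    leaf <- !(s$id %in% s$parent_id[!is.na(s$parent_id)])
    keep <- leaf & s$volume_mm3 > min_volume_mm3
    s$id[keep][order(s$acronym[keep])]
}

#' Analysis configuration
#'
#' Collects the tunable constants of the workflow in one validated list:
#' the large-effect threshold |d| > 0.8, the significance threshold
#' q < 0.05, the leaf volume filter (> 0.25 mm^3), the random-forest
#' settings (300 trees, 10-fold CV), the 5-micron matching radius and
#' consolidation eps, the F1 acceptance gate (0.80), and the heatmap slab
#' (1000 um) and smoothing kernel (100 um).
#'
#' @param d_threshold,q_threshold,leaf_min_volume_mm3,rf_n_trees,rf_cv_folds
#'   see description.
#' @param match_radius_um,consolidation_eps_um,f1_acceptance see description.
#' @param heatmap_slab_um,heatmap_sigma_um,rng_seed see description.
#' @return a list with class \code{"fosmap_config"}.
#' @export
analysisConfig <- function(d_threshold = 0.8, q_threshold = 0.05,
                           leaf_min_volume_mm3 = 0.25, rf_n_trees = 300L,
                           rf_cv_folds = 10L, match_radius_um = 5,
                           consolidation_eps_um = 5, f1_acceptance = 0.80,
                           heatmap_slab_um = 1000, heatmap_sigma_um = 100,
                           rng_seed = 1L) {
    cfg <- list(d_threshold = d_threshold, q_threshold = q_threshold,
                leaf_min_volume_mm3 = leaf_min_volume_mm3,
                rf_n_trees = as.integer(rf_n_trees),
                rf_cv_folds = as.integer(rf_cv_folds),
                match_radius_um = match_radius_um,
                consolidation_eps_um = consolidation_eps_um,
                f1_acceptance = f1_acceptance,
                heatmap_slab_um = heatmap_slab_um,
                heatmap_sigma_um = heatmap_sigma_um,
                rng_seed = as.integer(rng_seed))
    num <- cfg[setdiff(names(cfg), "rng_seed")]
    if (any(unlist(num) <= 0)) stop("all thresholds must be strictly positive")
    if (f1_acceptance > 1) stop("f1_acceptance must be in (0, 1]")
    class(cfg) <- "fosmap_config"
    cfg
}
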