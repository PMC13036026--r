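#' Aggregate assigned spots into per-region counts and densities
#'
#' Direct counts are spots whose voxel label is exactly the structure;
#' cumulative counts add every descendant's direct count, so a parent's
#' cumulative equals its own direct plus the sum of its children's
#' cumulatives. Density is cumulative count over the structure's annotated
#' volume (cells/mm^3). Unassigned spots appear only in the
#' \code{n_unassigned} attribute, never in region rows.
#'
#' @param st a region-assigned [SpotTable].
#' @param ontology a [BrainOntology].
#' @param animal_id identifier stored with the result.
#' @param gray_only restrict rows to gray-matter structures.
#' @return data.frame with columns \code{id}, \code{acronym},
#'   \code{direct_count}, \code{cumulative_count}, \code{volume_mm3},
#'   \code{density}; attributes \code{animal_id}, \code{n_assigned},
#'   \code{n_unassigned}.
#' @export
aggregateRegions <- function(st, ontology, animal_id = "animal",
                             gray_only = FALSE) {
    s <- structures(ontology)
    df <- spots(st)
    known <- df$region_id[!is.na(df$region_id)]
    if (!all(known %in% s$id))
        stop("consistency error: spot labeled with unknown region id")
    direct <- table(factor(known, levels = s$id))
    direct <- as.integer(direct)
    cum <- direct
    for (i in seq_along(s$id)) {
        dd <- descendants(ontology, s$id[i])
        if (length(dd))
            cum[i] <- direct[i] + sum(direct[match(dd, s$id)])
    }
    out <- data.frame(id = s$id, acronym = s$acronym,
                      direct_count = direct, cumulative_count = cum,
                      volume_mm3 = s$volume_mm3,
                      density = ifelse(s$volume_mm3 > 0,
                                       cum / s$volume_mm3, 0),
                      stringsAsFactors = FALSE)
    if (gray_only) out <- out[s$is_gray_matter, , drop = FALSE]
    attr(out, "animal_id") <- animal_id
    attr(out, "n_assigned") <- length(known)
    attr(out, "n_unassigned") <- sum(is.na(df$region_id))
    out
}

## depth-first ontology order (children under their parent, by acronym)
.dfsOrder <- function(ontology) {
    s <- structures(ontology)
    out <- integer(0)
    visit <- function(id) {
        out <<- c(out, id)
        kids <- s$id[!is.na(s$parent_id) & s$parent_id == id]
        for (k in kids[order(s$acronym[match(kids, s$id)])]) visit(k)
    }
    visit(s$id[is.na(s$parent_id)])
    out
}

#' Construct a DensityMatrix
#'
#' @param mat numeric matrix, regions x animals.
#' @param region_id,acronym row annotation vectors.
#' @param meta data.frame with \code{animal_id}, \code{treatment},
#'   \code{time}, \code{sex} (one row per column of \code{mat}).
#' @return a [DensityMatrix].
#' @export
densityMatrix <- function(mat, region_id, acronym, meta) {
    stopifnot(nrow(meta) == ncol(mat),
              all(c("animal_id", "treatment", "time", "sex") %in%
                  names(meta)))
    if (anyDuplicated(meta$animal_id))
        stop("consistency error: duplicate animal_id")
    rownames(mat) <- acronym
    colnames(mat) <- meta$animal_id
    new("DensityMatrix", SummarizedExperiment::SummarizedExperiment(
        assays = list(density = mat),
        rowData = S4Vectors::DataFrame(id = as.integer(region_id),
                                       acronym = acronym),
        colData = S4Vectors::DataFrame(meta, row.names = meta$animal_id)))
}

#' Assemble per-animal region counts into the cohort density matrix
#'
#' Rows (regions) follow a deterministic depth-first ontology order;
#' columns are animals with their treatment/time/sex labels. A region
#' missing for an animal is a region with no detected spots and becomes
#' density 0, never a missing value.
#'
#' @param counts_list named list of [aggregateRegions()] results, one per
#'   animal (names = animal ids).
#' @param meta data.frame with \code{animal_id}, \code{treatment},
#'   \code{time}, \code{sex}.
#' @param ontology the shared [BrainOntology].
#' @param gray_only restrict to gray-matter structures.
#' @return a [DensityMatrix].
#' @export
buildDensityMatrix <- function(counts_list, meta, ontology,
                               gray_only = FALSE) {
    stopifnot(all(meta$animal_id %in% names(counts_list)))
    s <- structures(ontology)
    ord <- .dfsOrder(ontology)
    if (gray_only) ord <- ord[s$is_gray_matter[match(ord, s$id)]]
    mat <- matrix(0, length(ord), nrow(meta))
    for (j in seq_len(nrow(meta))) {
        rc <- counts_list[[meta$animal_id[j]]]
        m <- match(ord, rc$id)
        mat[, j] <- ifelse(is.na(m), 0, rc$density[m])
    }
    densityMatrix(mat, region_id = ord,
                  acronym = s$acronym[match(ord, s$id)], meta = meta)
}

#' Read / write a DensityMatrix as a wide CSV
#'
#' Wide format: one row per animal; columns \code{animal_id},
#' \code{treatment}, \code{time}, \code{sex}, then one density column per
#' region acronym (in the matrix's row order).
#'
#' @param dm a [DensityMatrix].
#' @param path CSV path.
#' @return \code{writeDensityMatrix} returns \code{path} invisibly;
#'   \code{readDensityMatrix} returns a [DensityMatrix].
#' @export
writeDensityMatrix <- function(dm, path) {
    mat <- SummarizedExperiment::assay(dm, "density")
    cd <- as.data.frame(SummarizedExperiment::colData(dm))
    wide <- cbind(cd[, c("animal_id", "treatment", "time", "sex")],
                  as.data.frame(t(mat)))
    write.csv(wide, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDensityMatrix
#' @param region_ids optional integer ids for the regions (recovered from
#'   the column order when omitted).
#' @export
readDensityMatrix <- function(path, region_ids = NULL) {
    wide <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    metacols <- c("animal_id", "treatment", "time", "sex")
    acrs <- setdiff(names(wide), metacols)
    mat <- t(as.matrix(wide[, acrs, drop = FALSE]))
    if (is.null(region_ids)) region_ids <- seq_along(acrs)
    densityMatrix(mat, region_id = region_ids, acronym = acrs,
                  meta = wide[, metacols])
}
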