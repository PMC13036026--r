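#' Generate a toy mirror-symmetric atlas
#'
#' Builds a desk-scale stand-in for a hierarchical reference atlas: a
#' (z, y, x) label volume with a background margin and an interior tissue
#' block partitioned into \code{n_regions} leaf slabs along the
#' anterior-posterior axis, plus a 3-level ontology (root, lobes, leaves).
#' Slab boundaries are drawn randomly (seeded) so region volumes differ.
#' Left and right hemispheres carry identical labels (mirror labeling), so
#' left/right counterparts of a structure are pooled automatically.
#' Ontology volumes are computed exactly as voxel count times voxel volume.
#'
#' @param n_regions number of leaf structures (>= 2).
#' @param shape_vox integer(3) volume shape (z, y, x), each >= 16.
#' @param spacing_um numeric(3) voxel spacing in micrometres (z, y, x).
#' @param seed integer seed; fixes the output bit-for-bit.
#' @param margin_vox background margin at each face, in voxels.
#' @param n_lobes number of intermediate lobe structures.
#' @return an [AtlasBundle].
#' @export
makeToyAtlas <- function(n_regions, shape_vox = c(32L, 32L, 32L),
                         spacing_um = c(10, 10, 10), seed = 1L,
                         margin_vox = 2L, n_lobes = NULL) {
    stopifnot(n_regions >= 2, length(shape_vox) == 3L)
    if (any(shape_vox < 16L)) stop("shape must be at least 16 voxels per axis")
    nz <- shape_vox[1]
    inner <- (margin_vox + 1L):(nz - margin_vox)
    if (length(inner) < n_regions)
        stop("capacity error: z extent too small to host ", n_regions,
             " regions")
    set.seed(seed)
    ## random slab boundaries, at least 1 voxel per leaf
    w <- runif(n_regions, 0.5, 1.5)
    sizes <- pmax(1L, floor(w / sum(w) * length(inner)))
    while (sum(sizes) > length(inner)) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    sizes[n_regions] <- sizes[n_regions] + (length(inner) - sum(sizes))
    leaf_ids <- 100L + seq_len(n_regions)
    labels <- array(0L, shape_vox)
    zcur <- inner[1]
    yr <- (margin_vox + 1L):(shape_vox[2] - margin_vox)
    xr <- (margin_vox + 1L):(shape_vox[3] - margin_vox)
    for (i in seq_len(n_regions)) {
        zr <- zcur:(zcur + sizes[i] - 1L)
        labels[zr, yr, xr] <- leaf_ids[i]
        zcur <- zcur + sizes[i]
    }
    ## mirror labeling is automatic here (slabs span the full x extent), but
    ## enforce it explicitly so the invariant survives future partitions
    nx <- shape_vox[3]
    half <- seq_len(floor(nx / 2))
    labels[, , nx + 1L - half] <- labels[, , half, drop = FALSE]

    if (is.null(n_lobes)) n_lobes <- max(2L, ceiling(n_regions / 3))
    n_lobes <- min(n_lobes, n_regions)
    lobe_of <- sort(rep_len(seq_len(n_lobes), n_regions))
    lobe_ids <- 10L + seq_len(n_lobes)
    voxvol <- prod(spacing_um) * 1e-9   # um^3 -> mm^3
    leaf_vol <- vapply(leaf_ids, function(id)
        sum(labels == id) * voxvol, numeric(1))
    lobe_vol <- vapply(seq_len(n_lobes), function(l)
        sum(leaf_vol[lobe_of == l]), numeric(1))
    df <- rbind(
        data.frame(id = 1L, acronym = "root", name = "toy brain",
                   parent_id = NA_integer_, volume_mm3 = sum(lobe_vol),
                   is_gray_matter = FALSE),
        data.frame(id = lobe_ids, acronym = sprintf("LOBE%d", seq_len(n_lobes)),
                   name = sprintf("toy lobe %d", seq_len(n_lobes)),
                   parent_id = 1L, volume_mm3 = lobe_vol,
                   is_gray_matter = FALSE),
        data.frame(id = leaf_ids,
                   acronym = sprintf("R%02d", seq_len(n_regions)),
                   name = sprintf("toy region %d", seq_len(n_regions)),
                   parent_id = lobe_ids[lobe_of], volume_mm3 = leaf_vol,
                   is_gray_matter = TRUE))
    new("AtlasBundle", ontology = ontologyFromTable(df), labels = labels,
        spacing_um = as.numeric(spacing_um))
}
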