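## Multi-page TIFF I/O for 3D arrays, (z, y, x) order: one page per z plane.
## Pixel data are stored normalized to [0,1]; the affine de-normalization
## (value_offset, value_scale) and the anisotropic voxel spacing travel in a
## sidecar JSON next to the TIFF, because baseline TIFF tags cannot carry
## either reliably.

#' Read / write 3D volumes as multi-page TIFF with a spacing sidecar
#'
#' Volumes are stored one z-plane per TIFF page, 32-bit, min-max normalized;
#' label volumes are stored as 16-bit unsigned integers. The voxel spacing
#' (micrometres, z/y/x order) and the value scaling live in
#' \code{<path>.json}.
#'
#' @param vol 3D array (z, y, x).
#' @param path TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param spacing_um numeric(3) micrometres per voxel (z, y, x).
#' @param integer_labels write as 16-bit integer labels instead of
#'   normalized float.
#' @return \code{writeVolume} returns \code{path} invisibly;
#'   \code{readVolume} returns a list with \code{data} (3D array) and
#'   \code{spacing_um}.
#' @export
writeVolume <- function(vol, path, spacing_um, integer_labels = FALSE) {
    stopifnot(length(dim(vol)) == 3L, length(spacing_um) == 3L)
    if (integer_labels) {
        if (max(vol) > 65535L) stop("label ids exceed 16-bit range")
        pages <- lapply(seq_len(dim(vol)[1]),
                        function(i) vol[i, , , drop = TRUE] / 65535)
        tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
        meta <- list(spacing_um = spacing_um, kind = "labels")
    } else {
        off <- min(vol)
        sc <- max(vol) - off
        if (sc == 0) sc <- 1
        pages <- lapply(seq_len(dim(vol)[1]),
                        function(i) (vol[i, , , drop = TRUE] - off) / sc)
        tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
        meta <- list(spacing_um = spacing_um, kind = "intensity",
                     value_offset = off, value_scale = sc)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vol <- aperm(simplify2array(pages), c(3, 1, 2))
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("missing sidecar JSON for ", path)
    meta <- jsonlite::fromJSON(side)
    if (identical(as.character(meta$kind), "labels")) {
        vol <- array(as.integer(round(vol * 65535)), dim(vol))
    } else {
        vol <- vol * meta$value_scale + meta$value_offset
    }
    list(data = vol, spacing_um = as.numeric(meta$spacing_um))
}

#' Read / write an AtlasBundle directory
#'
#' An atlas directory contains \code{ontology.json} (structure-graph style),
#' \code{labels.tif} (16-bit multi-page TIFF) and its spacing sidecar.
#'
#' @param atlas an [AtlasBundle].
#' @param dir directory path (created if missing).
#' @return \code{writeAtlas} returns \code{dir} invisibly; \code{readAtlas}
#'   returns an [AtlasBundle].
#' @export
writeAtlas <- function(atlas, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeOntology(atlas@ontology, file.path(dir, "ontology.json"))
    writeVolume(labelVolume(atlas), file.path(dir, "labels.tif"),
                spacing(atlas), integer_labels = TRUE)
    invisible(dir)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(dir) {
    ont <- loadOntology(file.path(dir, "ontology.json"))
    lv <- readVolume(file.path(dir, "labels.tif"))
    new("AtlasBundle", ontology = ont, labels = lv$data,
        spacing_um = lv$spacing_um)
}

#' Read / write deformation fields
#'
#' Stored as a multi-page TIFF with pages ordered (z-plane, component): for
#' each grid z-plane, three consecutive pages hold dz, dy, dx (micrometres,
#' min-max normalized like intensity volumes). Grid spacing and the value
#' scaling live in the sidecar JSON.
#'
#' @param field a [DeformationField].
#' @param path TIFF path.
#' @return \code{writeDeformationField} returns \code{path} invisibly;
#'   \code{readDeformationField} returns a [DeformationField].
#' @export
writeDeformationField <- function(field, path) {
    d <- field@displacements
    dm <- dim(d)
    off <- min(d)
    sc <- max(d) - off
    if (sc == 0) sc <- 1
    pages <- list()
    for (i in seq_len(dm[1]))
        for (k in 1:3)
            pages[[length(pages) + 1L]] <-
                matrix((d[i, , , k] - off) / sc, dm[2], dm[3])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(grid_spacing_um = field@grid_spacing_um,
                              grid_dim = dm[1:3], value_offset = off,
                              value_scale = sc),
                         paste0(path, ".json"), digits = NA,
                         auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writeDeformationField
#' @export
readDeformationField <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    side <- jsonlite::fromJSON(paste0(path, ".json"))
    dm <- as.integer(side$grid_dim)
    d <- array(0, c(dm, 3L))
    idx <- 1L
    for (i in seq_len(dm[1]))
        for (k in 1:3) {
            d[i, , , k] <- pages[[idx]] * side$value_scale + side$value_offset
            idx <- idx + 1L
        }
    new("DeformationField", displacements = d,
        grid_spacing_um = as.numeric(side$grid_spacing_um))
}
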