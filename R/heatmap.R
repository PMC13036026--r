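#' Cohort coronal heatmaps
#'
#' Partitions the atlas anterior-posterior (z) axis into slabs (default
#' 1 mm), builds a 2D (dorsoventral x mediolateral) histogram of all cell
#' positions per slab at atlas voxel resolution, divides by the number of
#' animals so maps are per-animal averages, and finally smooths with a
#' Gaussian kernel. Before smoothing, the mass of each slab equals
#' (spots in slab) / n_animals exactly; smoothing with a renormalized
#' kernel conserves that mass away from the map borders.
#'
#' @param st a [SpotTable] of cells pooled across a group, in atlas world
#'   micrometres.
#' @param atlas an [AtlasBundle] (defines slab extent and map resolution).
#' @param n_animals number of animals pooled (>= 1).
#' @param slab_um slab thickness along z, micrometres (> 0).
#' @param sigma_um Gaussian smoothing SD in micrometres (0 = no smoothing;
#'   the kernel width is a display choice, not a measurement).
#' @return list of 2D matrices (one per slab), each with attributes
#'   \code{z_range_um} and \code{mass} (pre-smoothing).
#' @export
coronalHeatmaps <- function(st, atlas, n_animals, slab_um = 1000,
                            sigma_um = 100) {
    if (slab_um <= 0) stop("slab_um must be positive")
    stopifnot(n_animals >= 1)
    d <- dim(labelVolume(atlas))
    sp <- spacing(atlas)
    zmax <- d[1] * sp[1]
    breaks <- seq(0, zmax + slab_um, by = slab_um)
    df <- spots(st)
    maps <- vector("list", length(breaks) - 1L)
    for (s in seq_along(maps)) {
        sel <- df$z_um >= breaks[s] & df$z_um < breaks[s + 1L]
        m <- matrix(0, d[2], d[3])
        if (any(sel)) {
            iy <- pmin(pmax(round(df$y_um[sel] / sp[2]) + 1L, 1L), d[2])
            ix <- pmin(pmax(round(df$x_um[sel] / sp[3]) + 1L, 1L), d[3])
            for (k in seq_along(iy))
                m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
            m <- m / n_animals
        }
        mass <- sum(m)
        if (sigma_um > 0 && mass > 0) {
            sv <- sigma_um / sp[2:3]
            m <- .filterAxis2d(m, .gaussKernel1d(sv[1]), 1)
            m <- .filterAxis2d(m, .gaussKernel1d(sv[2]), 2)
        }
        attr(m, "z_range_um") <- c(breaks[s], breaks[s + 1L])
        attr(m, "mass") <- mass
        maps[[s]] <- m
    }
    maps
}

.filterAxis2d <- function(m, kernel, axis) {
    if (length(kernel) == 1L) return(m)
    if (axis == 2L) return(t(.filterAxis2d(t(m), kernel, 1L)))
    K <- .bandMatrix(nrow(m), kernel, normalize = TRUE)
    as.matrix(K %*% m)
}

#' Write heatmaps as a multi-page TIFF
#'
#' @param maps result of [coronalHeatmaps()].
#' @param path TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeHeatmaps <- function(maps, path) {
    mx <- max(1e-12, max(vapply(maps, max, numeric(1))))
    tiff::writeTIFF(lapply(maps, function(m) m / mx), path,
                    bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(value_scale = mx,
                              z_ranges_um = lapply(maps, attr, "z_range_um")),
                         paste0(path, ".json"), digits = NA)
    invisible(path)
}
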