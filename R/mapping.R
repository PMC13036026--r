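#' Transform spots through a deformation field into atlas space
#'
#' For each spot the displacement is trilinearly interpolated at its sample
#' world position and added, mapping it into atlas world coordinates (the
#' field direction is sample-to-atlas; the inverse is unsupported). Spots
#' outside the grid extent are clamped to the nearest grid border for
#' interpolation and flagged \code{out_of_grid} rather than dropped, since
#' registration edges are imperfect and silent dropping would bias border
#' regions.
#'
#' @param st a [SpotTable] in sample world micrometres.
#' @param field a [DeformationField].
#' @return the transformed [SpotTable].
#' @export
transformSpots <- function(st, field) {
    d <- dim(field@displacements)
    if (any(d[1:3] < 2L))
        stop("format error: deformation grid needs at least 2 nodes per axis")
    df <- spots(st)
    if (nrow(df) == 0L) return(st)
    gs <- field@grid_spacing_um
    ## grid coordinates (0-based, continuous), clamped to the grid box
    gz <- df$z_um / gs[1]; gy <- df$y_um / gs[2]; gx <- df$x_um / gs[3]
    out <- gz < 0 | gz > d[1] - 1 | gy < 0 | gy > d[2] - 1 |
        gx < 0 | gx > d[3] - 1
    gz <- pmin(pmax(gz, 0), d[1] - 1)
    gy <- pmin(pmax(gy, 0), d[2] - 1)
    gx <- pmin(pmax(gx, 0), d[3] - 1)
    z0 <- pmin(floor(gz), d[1] - 2); fz <- gz - z0
    y0 <- pmin(floor(gy), d[2] - 2); fy <- gy - y0
    x0 <- pmin(floor(gx), d[3] - 2); fx <- gx - x0
    disp <- matrix(0, nrow(df), 3)
    for (k in 1:3) {
        acc <- 0
        for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
            w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
                (if (dx) fx else 1 - fx)
            acc <- acc + w * field@displacements[
                cbind(z0 + dz + 1, y0 + dy + 1, x0 + dx + 1, k)]
        }
        disp[, k] <- acc
    }
    df$z_um <- df$z_um + disp[, 1]
    df$y_um <- df$y_um + disp[, 2]
    df$x_um <- df$x_um + disp[, 3]
    df$out_of_grid <- df$out_of_grid | out
    new("SpotTable", spots = df)
}

#' Assign atlas regions by nearest-voxel label lookup
#'
#' Labels are categorical, so no interpolation: each spot takes the label of
#' the nearest atlas voxel. Spots falling on background (label 0) or outside
#' the label volume stay unassigned (\code{region_id = NA}); they are kept
#' in whole-brain totals but excluded from region statistics. Left and right
#' hemisphere positions map to the same id by atlas construction.
#'
#' @param st a [SpotTable] in atlas world micrometres.
#' @param atlas an [AtlasBundle].
#' @return the [SpotTable] with \code{region_id} filled in.
#' @export
assignRegions <- function(st, atlas) {
    df <- spots(st)
    if (nrow(df) == 0L) return(st)
    d <- dim(labelVolume(atlas))
    sp <- spacing(atlas)
    iz <- round(df$z_um / sp[1]) + 1L
    iy <- round(df$y_um / sp[2]) + 1L
    ix <- round(df$x_um / sp[3]) + 1L
    inside <- iz >= 1L & iz <= d[1] & iy >= 1L & iy <= d[2] &
        ix >= 1L & ix <= d[3]
    lab <- rep(NA_integer_, nrow(df))
    lab[inside] <- labelVolume(atlas)[cbind(iz[inside], iy[inside],
                                            ix[inside])]
    lab[!is.na(lab) & lab == 0L] <- NA_integer_
    df$region_id <- lab
    new("SpotTable", spots = df)
}
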