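#' Generate a synthetic deformation field
#'
#' Test fixture for the spot-transformation stage. \code{identity} gives an
#' all-zero displacement grid; \code{translation} a constant vector of
#' length \code{magnitude_um} along z (or the supplied \code{vector_um});
#' \code{smooth_warp} a seeded low-frequency random field whose maximum
#' displacement magnitude is bounded by \code{magnitude_um}.
#'
#' @param atlas an [AtlasBundle]; the grid covers its world extent.
#' @param mode one of \code{"identity"}, \code{"translation"},
#'   \code{"smooth_warp"}.
#' @param magnitude_um displacement magnitude bound (>= 0).
#' @param seed integer seed (smooth_warp only).
#' @param nodes_per_axis approximate grid resolution.
#' @param vector_um optional explicit (dz, dy, dx) for translation mode.
#' @return a [DeformationField].
#' @export
simulateDeformation <- function(atlas, mode = c("identity", "translation",
                                                "smooth_warp"),
                                magnitude_um = 0, seed = 1L,
                                nodes_per_axis = 6L, vector_um = NULL) {
    mode <- match.arg(mode)
    stopifnot(magnitude_um >= 0)
    d <- dim(labelVolume(atlas))
    extent <- (d - 1) * spacing(atlas)
    n <- pmax(2L, pmin(nodes_per_axis, d))
    grid_spacing <- extent / (n - 1)
    grid_spacing[extent == 0] <- 1
    disp <- array(0, c(n, 3L))
    if (mode == "translation") {
        if (is.null(vector_um)) vector_um <- c(magnitude_um, 0, 0)
        for (k in 1:3) disp[, , , k] <- vector_um[k]
    } else if (mode == "smooth_warp") {
        set.seed(seed)
        for (k in 1:3) {
            raw <- array(rnorm(prod(n)), n)
            disp[, , , k] <- gaussianSmooth3d(raw, pmax(1, n / 4))
        }
        mx <- max(sqrt(apply(disp^2, 1:3, sum)))
        if (mx > 0) disp <- disp * (0.9 * magnitude_um / mx)
    }
    new("DeformationField", displacements = disp,
        grid_spacing_um = as.numeric(grid_spacing))
}
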