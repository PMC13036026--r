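.featureNames <- c("peak_intensity", "local_mean", "local_sd",
                   "contrast_ratio", "anisotropy", "border_distance_um",
                   "planarity")

#' Patch features for cell / artifact discrimination
#'
#' Deterministic features of the world-micrometre ball of radius
#' \code{patch_radius_um} around a spot centroid, designed to separate real
#' puncta from the named artifact classes: a bright plane at a volume edge
#' concentrates its energy in a single patch plane (\code{planarity} high),
#' an autofluorescent vessel is strongly elongated (\code{anisotropy} high),
#' and a noise spike has an anomalous peak relative to its local spread.
#'
#' Features: \code{peak_intensity} (maximum in the core), \code{local_mean}
#' and \code{local_sd} (patch statistics), \code{contrast_ratio} (peak over
#' the annulus background, > 0), \code{anisotropy} (ratio of largest to
#' smallest eigenvalue of the intensity second-moment matrix in micrometre
#' coordinates, >= 1), \code{border_distance_um} (distance of the centroid
#' to the nearest volume face) and \code{planarity} (largest fraction of
#' patch energy carried by a single plane along any axis, in [0, 1]).
#'
#' @param volume 3D array (z, y, x).
#' @param spacing_um numeric(3) micrometres per voxel.
#' @param st a [SpotTable] (or data.frame with \code{x_um,y_um,z_um}).
#' @param patch_radius_um patch radius in micrometres.
#' @return data.frame, one row per spot, columns as above.
#' @export
extractFeatures <- function(volume, spacing_um, st, patch_radius_um = 10) {
    xyz <- if (is(st, "SpotTable")) .spotXYZ(st) else
        as.matrix(st[, c("x_um", "y_um", "z_um")])
    d <- dim(volume)
    extent <- (d - 1) * spacing_um
    out <- matrix(NA_real_, nrow(xyz), length(.featureNames),
                  dimnames = list(NULL, .featureNames))
    r_vox <- pmax(1L, round(patch_radius_um / spacing_um))
    for (i in seq_len(nrow(xyz))) {
        ## world (x,y,z) -> voxel (z,y,x), 0-based centers
        cv <- c(xyz[i, 3], xyz[i, 2], xyz[i, 1]) / spacing_um
        ci <- round(cv) + 1L
        if (any(ci < 1L) || any(ci > d))
            stop("coordinate error: spot ", i, " lies outside the volume")
        lo <- pmax(ci - r_vox, 1L)
        hi <- pmin(ci + r_vox, d)
        patch <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        ## distances of patch voxels to the centroid, in um
        gz <- ((lo[1]:hi[1]) - 1) * spacing_um[1] - xyz[i, 3]
        gy <- ((lo[2]:hi[2]) - 1) * spacing_um[2] - xyz[i, 2]
        gx <- ((lo[3]:hi[3]) - 1) * spacing_um[3] - xyz[i, 1]
        dz2 <- array(gz^2, dim(patch))
        dy2 <- aperm(array(gy^2, dim(patch)[c(2, 1, 3)]), c(2, 1, 3))
        dx2 <- aperm(array(gx^2, dim(patch)[c(3, 2, 1)]), c(3, 2, 1))
        dist2 <- dz2 + dy2 + dx2
        r2 <- patch_radius_um^2
        core <- dist2 <= (patch_radius_um / 3)^2
        annulus <- dist2 > r2 / 4 & dist2 <= r2
        peak <- if (any(core)) max(patch[core]) else max(patch)
        lmean <- mean(patch)
        lsd <- sd(as.vector(patch))
        if (is.na(lsd)) lsd <- 0
        bg <- if (any(annulus)) mean(patch[annulus]) else lmean
        contrast <- if (lsd == 0) 1 else
            max(peak - min(patch), 1e-12) / max(bg - min(patch), 1e-12)
        ## second moments of the background-floored intensity, um coords
        w <- pmax(patch - stats::quantile(patch, 0.25), 0)
        tw <- sum(w)
        if (tw > 0 && lsd > 0) {
            zc <- rep(gz, times = prod(dim(patch)[2:3]))
            yc <- rep(rep(gy, each = dim(patch)[1]), times = dim(patch)[3])
            xc <- rep(gx, each = prod(dim(patch)[1:2]))
            wv <- as.vector(w) / tw
            mz <- sum(wv * zc); my <- sum(wv * yc); mx <- sum(wv * xc)
            cz <- zc - mz; cy <- yc - my; cx <- xc - mx
            M <- matrix(c(sum(wv * cz * cz), sum(wv * cz * cy),
                          sum(wv * cz * cx),
                          sum(wv * cy * cz), sum(wv * cy * cy),
                          sum(wv * cy * cx),
                          sum(wv * cx * cz), sum(wv * cx * cy),
                          sum(wv * cx * cx)), 3, 3)
            ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
            aniso <- if (min(ev) > 1e-9) max(ev) / min(ev) else
                max(ev) / 1e-9
            ## plane energy fractions along each axis
            e2 <- w^2
            te <- sum(e2)
            plan <- if (te > 0) max(
                max(apply(e2, 1, sum)) / te,
                max(apply(e2, 2, sum)) / te,
                max(apply(e2, 3, sum)) / te) else 1 / min(dim(patch))
        } else {
            aniso <- 1
            plan <- 1 / min(dim(patch))
        }
        bdist <- min(xyz[i, 3], extent[1] - xyz[i, 3],
                     xyz[i, 2], extent[2] - xyz[i, 2],
                     xyz[i, 1], extent[3] - xyz[i, 1])
        out[i, ] <- c(peak, lmean, lsd, contrast, aniso, bdist, plan)
    }
    as.data.frame(out)
}
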