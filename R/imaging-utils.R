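## Separable filtering on 3D arrays via sparse band matrices. All filters
## operate along one axis at a time; volumes are (z, y, x). Edge handling is
## renormalized (kernel rows truncated at the border are rescaled to sum 1),
## which keeps a constant volume exactly constant under smoothing.

.bandMatrix <- function(n, kernel, normalize = TRUE) {
    r <- (length(kernel) - 1L) %/% 2L
    K <- Matrix::bandSparse(n, n, k = -r:r,
                            diagonals = lapply(r:-r, function(k)
                                rep(kernel[k + r + 1L],
                                    n - abs(k))))
    if (normalize) {
        rs <- Matrix::rowSums(K)
        K <- Matrix::Diagonal(n, 1 / rs) %*% K
    }
    K
}

## apply a 1D kernel along the given axis of a 3D array
.filterAxis <- function(vol, kernel, axis, normalize = TRUE) {
    if (length(kernel) == 1L)
        return(vol * if (normalize) 1 else kernel)
    d <- dim(vol)
    perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                   `3` = c(3L, 1L, 2L))
    v <- if (axis == 1L) vol else aperm(vol, perm)
    dv <- dim(v)
    K <- .bandMatrix(dv[1], kernel, normalize)
    m <- as.matrix(K %*% matrix(v, nrow = dv[1]))
    v <- array(m, dv)
    if (axis == 1L) v else aperm(v, order(perm))
}

.gaussKernel1d <- function(sigma) {
    if (sigma <= 0) return(1)
    r <- max(1L, ceiling(3 * sigma))
    k <- dnorm(-r:r, sd = sigma)
    k / sum(k)
}

#' Separable 3D Gaussian smoothing
#'
#' @param vol 3D array (z, y, x).
#' @param sigma_vox numeric(3), Gaussian SD per axis in voxels; 0 skips an
#'   axis.
#' @param normalize renormalize truncated kernels at the borders (keeps a
#'   constant volume constant).
#' @return smoothed array of the same dimensions.
#' @export
gaussianSmooth3d <- function(vol, sigma_vox, normalize = TRUE) {
    for (ax in 1:3)
        vol <- .filterAxis(vol, .gaussKernel1d(sigma_vox[ax]), ax, normalize)
    vol
}

## running box sums (not means) over a (2r+1) window per axis, zero padded
.boxSum3d <- function(vol, r_vox) {
    for (ax in 1:3) {
        r <- r_vox[ax]
        if (r > 0)
            vol <- .filterAxis(vol, rep(1, 2L * r + 1L), ax,
                               normalize = FALSE)
    }
    vol
}

## second difference along an axis (unit voxel steps), zero-gradient edges
.secondDiffAxis <- function(vol, axis) {
    d <- dim(vol)
    perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                   `3` = c(3L, 1L, 2L))
    v <- if (axis == 1L) vol else aperm(vol, perm)
    dv <- dim(v)
    n <- dv[1]
    m <- matrix(v, nrow = n)
    up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
    v <- array(up + dn - 2 * m, dv)
    if (axis == 1L) v else aperm(v, order(perm))
}

## Scale-normalized negated Laplacian-of-Gaussian response: positive at blob
## centers. sigma_vox is per-axis (anisotropic grids): each axis's second
## derivative is weighted by its own sigma^2, expressed in voxel units so the
## response is spacing-consistent.
.logResponse <- function(vol, sigma_vox) {
    sm <- gaussianSmooth3d(vol, sigma_vox)
    resp <- 0
    for (ax in 1:3) {
        s2 <- max(sigma_vox[ax], 0.5)^2
        resp <- resp - s2 * .secondDiffAxis(sm, ax)
    }
    list(response = resp, smoothed = sm)
}

## Local maxima (26-connectivity) restricted to voxels above a threshold.
## Candidates on the 1-voxel border shell are compared only against in-range
## neighbours. Returns an integer matrix of (z, y, x) voxel indices.
.localMaxima3d <- function(vol, threshold) {
    d <- dim(vol)
    cand <- which(vol > threshold)
    if (!length(cand)) return(matrix(integer(0), 0, 3))
    ijk <- arrayInd(cand, d)
    keep <- rep(TRUE, length(cand))
    vals <- vol[cand]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        nz <- ijk[, 1] + dz; ny <- ijk[, 2] + dy; nx <- ijk[, 3] + dx
        inb <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
            nx >= 1L & nx <= d[3]
        sel <- which(keep & inb)
        if (!length(sel)) next
        nb <- vol[cbind(nz[sel], ny[sel], nx[sel])]
        keep[sel[nb > vals[sel]]] <- FALSE
    }
    ijk[keep, , drop = FALSE]
}

## Intensity-weighted sub-voxel centroid around voxel peaks. Weights are the
## (background-floored) smoothed intensities in a per-axis radius window.
## Returns world-um coordinates: voxel centers sit at (index - 1) * spacing.
.subvoxelCentroids <- function(sm, peaks_ijk, radius_vox, spacing_um) {
    d <- dim(sm)
    r <- pmax(1L, ceiling(radius_vox))
    out <- matrix(NA_real_, nrow(peaks_ijk), 3)
    for (i in seq_len(nrow(peaks_ijk))) {
        p <- peaks_ijk[i, ]
        lo <- pmax(p - r, 1L)
        hi <- pmin(p + r, d)
        patch <- sm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        w <- patch - min(patch)
        tw <- sum(w)
        if (tw == 0) {
            out[i, ] <- (p - 1) * spacing_um
            next
        }
        zi <- (lo[1]:hi[1]) - 1; yi <- (lo[2]:hi[2]) - 1
        xi <- (lo[3]:hi[3]) - 1
        out[i, 1] <- sum(apply(w, 1, sum) * zi) / tw * spacing_um[1]
        out[i, 2] <- sum(apply(w, 2, sum) * yi) / tw * spacing_um[2]
        out[i, 3] <- sum(apply(w, 3, sum) * xi) / tw * spacing_um[3]
    }
    out
}

.robustSd <- function(x) mad(x, constant = 1.4826)
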