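#' Background / foreground tissue mask
#'
#' Otsu threshold on a Gaussian-smoothed copy of the volume, followed by
#' keeping the largest connected foreground component. Detections outside
#' the mask are discarded downstream. A degenerate volume (no intensity
#' spread, or an empty threshold result) returns an all-true mask with a
#' warning rather than failing.
#'
#' @param volume 3D array (z, y, x).
#' @param spacing_um numeric(3) voxel spacing in micrometres.
#' @param smooth_um isotropic smoothing scale before thresholding.
#' @param keep_largest keep only the largest 6-connected component.
#' @return logical 3D array.
#' @export
foregroundMask <- function(volume, spacing_um, smooth_um = 5,
                           keep_largest = TRUE) {
    stopifnot(all(is.finite(volume)))
    if (max(volume) == min(volume)) {
        warning("degenerate volume: returning all-true mask")
        return(array(TRUE, dim(volume)))
    }
    sm <- gaussianSmooth3d(volume, smooth_um / spacing_um)
    ## winsorize so sparse bright puncta cannot dominate the histogram:
    ## the threshold must separate tissue from empty background, not
    ## puncta from tissue
    sm <- pmin(sm, quantile(sm, 0.90))
    thr <- .otsu(sm)
    mask <- sm > thr
    if (!any(mask) || all(mask)) {
        warning("degenerate threshold: returning all-true mask")
        return(array(TRUE, dim(volume)))
    }
    if (keep_largest) mask <- .largestComponent(mask)
    ## one-voxel 6-connectivity dilation recovers the boundary layer the
    ## pre-threshold smoothing eroded
    .dilate6(mask)
}

.dilate6 <- function(mask) {
    d <- dim(mask)
    out <- mask
    n <- d[1]
    out[2:n, , ] <- out[2:n, , ] | mask[1:(n - 1), , ]
    out[1:(n - 1), , ] <- out[1:(n - 1), , ] | mask[2:n, , ]
    n <- d[2]
    out[, 2:n, ] <- out[, 2:n, ] | mask[, 1:(n - 1), ]
    out[, 1:(n - 1), ] <- out[, 1:(n - 1), ] | mask[, 2:n, ]
    n <- d[3]
    out[, , 2:n] <- out[, , 2:n] | mask[, , 1:(n - 1)]
    out[, , 1:(n - 1)] <- out[, , 1:(n - 1)] | mask[, , 2:n]
    out
}

## Otsu threshold on a 256-bin histogram
.otsu <- function(x) {
    rng <- range(x)
    h <- tabulate(pmin(255L, floor((x - rng[1]) / diff(rng) * 256)) + 1L,
                  256L)
    p <- h / sum(h)
    omega <- cumsum(p)
    mu <- cumsum(p * seq_len(256L))
    mu_t <- mu[256L]
    sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    sigma_b[!is.finite(sigma_b)] <- 0
    k <- which.max(sigma_b)
    rng[1] + k / 256 * diff(rng)
}

## Largest 6-connected foreground component. For large volumes the mask is
## block-downsampled (logical any-pooling) to <= max_cells cells first; the
## kept component is then upsampled and intersected with the original mask.
## The downsampling only affects morphological cleanup at the few-voxel
## scale, not tissue-scale geometry.
.largestComponent <- function(mask, max_cells = 2e6) {
    d <- dim(mask)
    f <- ceiling((prod(d) / max_cells)^(1 / 3))
    if (f > 1) {
        coarse <- .poolAny(mask, f)
        keep <- .largestComponentExact(coarse)
        up <- .upsampleLogical(keep, f, d)
        return(mask & up)
    }
    .largestComponentExact(mask)
}

.poolAny <- function(mask, f) {
    d <- dim(mask)
    nd <- ceiling(d / f)
    idx <- lapply(1:3, function(a) rep(seq_len(nd[a]), each = f)[seq_len(d[a])])
    out <- array(FALSE, nd)
    w <- which(mask)
    ijk <- arrayInd(w, d)
    ci <- cbind(idx[[1]][ijk[, 1]], idx[[2]][ijk[, 2]], idx[[3]][ijk[, 3]])
    out[unique(ci[, 1] + (ci[, 2] - 1) * nd[1] +
               (ci[, 3] - 1) * nd[1] * nd[2])] <- TRUE
    out
}

.upsampleLogical <- function(mask, f, target_dim) {
    d <- dim(mask)
    zi <- pmin(d[1], ((seq_len(target_dim[1]) - 1L) %/% f) + 1L)
    yi <- pmin(d[2], ((seq_len(target_dim[2]) - 1L) %/% f) + 1L)
    xi <- pmin(d[3], ((seq_len(target_dim[3]) - 1L) %/% f) + 1L)
    mask[zi, yi, xi, drop = FALSE]
}

.largestComponentExact <- function(mask) {
    d <- dim(mask)
    idx <- which(mask)
    if (!length(idx)) return(mask)
    pos <- integer(prod(d))
    pos[idx] <- seq_along(idx)
    ijk <- arrayInd(idx, d)
    edges <- integer(0)
    for (ax in 1:3) {
        step <- c(1L, d[1], d[1] * d[2])[ax]
        ok <- ijk[, ax] < d[ax]
        nb <- idx[ok] + step
        ok2 <- mask[nb]
        from <- pos[idx[ok][ok2]]
        to <- pos[nb[ok2]]
        edges <- c(edges, rbind(from, to))
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    comp <- igraph::components(g)
    keep <- comp$membership == which.max(comp$csize)
    out <- array(FALSE, d)
    out[idx[keep]] <- TRUE
    out
}

.spotsFromPeaks <- function(volume, sm, peaks, sigma_vox, spacing_um,
                            source, mask = NULL, border_um = NULL) {
    if (!nrow(peaks))
        return(spotTable(source = source))
    if (!is.null(mask)) {
        inside <- mask[peaks]
        peaks <- peaks[inside, , drop = FALSE]
        if (!nrow(peaks)) return(spotTable(source = source))
    }
    cen <- .subvoxelCentroids(sm, peaks, sigma_vox, spacing_um)
    d <- dim(volume)
    if (is.null(border_um)) border_um <- 2 * max(sigma_vox * spacing_um)
    extent <- (d - 1) * spacing_um
    bdist <- pmin(cen[, 1], extent[1] - cen[, 1],
                  cen[, 2], extent[2] - cen[, 2],
                  cen[, 3], extent[3] - cen[, 3])
    spotTable(x_um = cen[, 3], y_um = cen[, 2], z_um = cen[, 1],
              intensity = volume[peaks], source = source,
              border = bdist < border_um)
}

#' Conventional blob detection (Laplacian of Gaussian)
#'
#' 3D scale-normalized LoG local-maxima detection, purposely biased towards
#' over-detection: the default threshold sits only 2 robust background SDs
#' (median absolute deviation x 1.4826 of the response map) above the
#' response median, favouring recall over precision so that the
#' consolidation and classification stages see every real cell. Sub-voxel
#' centroids are intensity-weighted means over a 1-sigma neighbourhood; all
#' coordinates are world micrometres (spacing-aware).
#'
#' @param volume 3D array (z, y, x).
#' @param spacing_um numeric(3) micrometres per voxel.
#' @param sigma_um blob scale per axis (z, y, x), micrometres.
#' @param threshold_sd response threshold in robust-SD units above the
#'   median.
#' @param mask optional logical foreground mask; peaks outside are dropped.
#' @return a [SpotTable] with \code{source = "conventional"}; spots within
#'   two blob scales of a volume face carry \code{border = TRUE}.
#' @export
detectConventional <- function(volume, spacing_um,
                               sigma_um = c(4, 1.5, 1.5),
                               threshold_sd = 2, mask = NULL) {
    stopifnot(all(spacing_um > 0))
    if (any(sigma_um <= 0)) stop("sigma_um must be positive")
    sigma_vox <- sigma_um / spacing_um
    lr <- .logResponse(volume, sigma_vox)
    resp <- lr$response
    ## the absolute floor keeps numerically flat volumes (response ripple
    ## at machine precision) from producing spurious maxima
    floor_eps <- 1e-8 * max(abs(lr$smoothed))
    thr <- median(resp) +
        max(threshold_sd * .robustSd(as.vector(resp)), floor_eps)
    peaks <- .localMaxima3d(resp, thr)
    .spotsFromPeaks(volume, lr$smoothed, peaks, sigma_vox, spacing_um,
                    "conventional", mask)
}

#' Matched-filter detection (normalized cross-correlation)
#'
#' Correlates the volume with a Gaussian template at the expected punctum
#' scale and takes local maxima of the normalized cross-correlation map.
#' Because the score is a correlation it is independent of the intensity
#' scale, which makes small and dim puncta detectable where an intensity
#' threshold fails; this complements [detectConventional()] in the
#' over-detection-biased detector pair.
#'
#' @param volume 3D array (z, y, x).
#' @param spacing_um numeric(3) micrometres per voxel.
#' @param template_sigma_um Gaussian template SD per axis (z, y, x),
#'   micrometres.
#' @param corr_threshold minimum correlation for a candidate (scale-free).
#' @param mask optional logical foreground mask.
#' @return a [SpotTable] with \code{source = "matched"}.
#' @export
detectMatched <- function(volume, spacing_um,
                          template_sigma_um = c(4, 1.5, 1.5),
                          corr_threshold = 0.5, mask = NULL) {
    stopifnot(all(spacing_um > 0))
    if (any(template_sigma_um <= 0)) stop("template sigma must be positive")
    sv <- template_sigma_um / spacing_um
    d <- dim(volume)
    r <- pmax(1L, ceiling(3 * sv))
    if (any(2L * r + 1L > d)) stop("template does not fit in the volume")
    ks <- lapply(1:3, function(a) {
        k <- dnorm(seq(-r[a], r[a]), sd = max(sv[a], 1e-6))
        k / sum(k)
    })
    tmean <- prod(vapply(ks, mean, numeric(1)))
    nbox <- prod(2L * r + 1L)
    ## correlation of I with zero-mean template, all separable passes
    conv_t <- volume
    for (ax in 1:3) conv_t <- .filterAxis(conv_t, ks[[ax]], ax,
                                          normalize = FALSE)
    s1 <- .boxSum3d(volume, r)
    num <- conv_t - tmean * s1
    rm(conv_t)
    s2 <- .boxSum3d(volume^2, r)
    var_loc <- pmax(s2 - s1^2 / nbox, 0)
    rm(s1, s2); gc(FALSE)
    ## ||t0||^2 = sum(t^2) - n * mean(t)^2 for the separable template
    sum_t2 <- prod(vapply(ks, function(k) sum(k^2), numeric(1)))
    norm_t0 <- sqrt(max(sum_t2 - nbox * tmean^2, 0))
    denom <- sqrt(var_loc) * norm_t0
    rm(var_loc)
    ncc <- array(0, d)
    pos <- denom > 1e-12 * max(denom)
    ncc[pos] <- num[pos] / denom[pos]
    rm(num, denom, pos); gc(FALSE)
    peaks <- .localMaxima3d(ncc, corr_threshold)
    rm(ncc); gc(FALSE)
    sm <- gaussianSmooth3d(volume, sv)
    .spotsFromPeaks(volume, sm, peaks, sv, spacing_um, "matched", mask)
}
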