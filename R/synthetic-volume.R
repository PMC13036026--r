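#' Phantom specification
#'
#' Parameters of the synthetic fluorescence phantom. Defaults emulate the
#' acquisition geometry of ribbon-scanning confocal data (0.361 x 0.361 x
#' 5.33 um in x/y/z) and nucleus-sized c-Fos puncta blurred by an
#' axially-elongated PSF. Puncta vary in size and intensity (multiplicative
#' jitter), and three artifact classes mirror what real cleared-brain data
#' contain: bright planes at volume edges, autofluorescent vessel-like
#' tubes, and single-voxel noise spikes.
#'
#' @param spacing_um voxel spacing (z, y, x) in micrometres.
#' @param puncta_sigma_um Gaussian blob SD per axis (z, y, x), micrometres.
#' @param puncta_amplitude mean peak amplitude above background.
#' @param background_level additive tissue background level.
#' @param noise_sd additive Gaussian noise SD (SNR = amplitude / noise_sd).
#' @param size_jitter,intensity_jitter half-width of the multiplicative
#'   uniform jitter on blob size and amplitude.
#' @param artifact_spec named counts of \code{edge_plane},
#'   \code{vessel_tube}, \code{noise_spike} artifacts.
#' @param region_rates named numeric: homogeneous Poisson intensity
#'   (cells/mm^3) per region id.
#' @return a list with class \code{"fosmap_phantom_spec"}.
#' @export
phantomSpec <- function(spacing_um = c(5.33, 0.361, 0.361),
                        puncta_sigma_um = c(4, 1.5, 1.5),
                        puncta_amplitude = 10, background_level = 1,
                        noise_sd = 1.25, size_jitter = 0.2,
                        intensity_jitter = 0.3,
                        artifact_spec = c(edge_plane = 1L, vessel_tube = 2L,
                                          noise_spike = 10L),
                        region_rates = numeric(0)) {
    stopifnot(all(puncta_sigma_um > 0), noise_sd >= 0,
              background_level >= 0, all(region_rates >= 0))
    structure(list(spacing_um = spacing_um,
                   puncta_sigma_um = puncta_sigma_um,
                   puncta_amplitude = puncta_amplitude,
                   background_level = background_level, noise_sd = noise_sd,
                   size_jitter = size_jitter,
                   intensity_jitter = intensity_jitter,
                   artifact_spec = artifact_spec,
                   region_rates = region_rates),
              class = "fosmap_phantom_spec")
}

## patch for one axis-aligned anisotropic Gaussian blob (center in world
## um); returned as indices + values so the caller can add it in place
## without copying the full volume
.blobPatch <- function(d, center_um, sigma_um, amplitude, spacing_um) {
    cv <- center_um / spacing_um           # voxel units, 0-based
    sv <- sigma_um / spacing_um
    lo <- pmax(floor(cv - 3 * sv), 0)
    hi <- pmin(ceiling(cv + 3 * sv), d - 1)
    if (any(hi < lo)) return(NULL)
    ax <- lapply(1:3, function(a) {
        i <- lo[a]:hi[a]
        exp(-((i - cv[a])^2) / (2 * sv[a]^2))
    })
    list(zi = (lo[1]:hi[1]) + 1L, yi = (lo[2]:hi[2]) + 1L,
         xi = (lo[3]:hi[3]) + 1L,
         blob = amplitude * (ax[[1]] %o% ax[[2]] %o% ax[[3]]))
}

.renderBlob <- function(vol, center_um, sigma_um, amplitude, spacing_um) {
    p <- .blobPatch(dim(vol), center_um, sigma_um, amplitude, spacing_um)
    if (!is.null(p))
        vol[p$zi, p$yi, p$xi] <- vol[p$zi, p$yi, p$xi] + p$blob
    vol
}

.renderArtifacts <- function(vol, spec, tissue_mask) {
    counts <- spec$artifact_spec
    d <- dim(vol)
    amp <- spec$puncta_amplitude
    nep <- if ("edge_plane" %in% names(counts)) counts[["edge_plane"]] else 0L
    for (i in seq_len(nep)) {
        axis <- sample.int(3, 1)
        at_end <- sample(c(TRUE, FALSE), 1)
        idx <- if (at_end) d[axis] else 1L
        if (axis == 1L) vol[idx, , ] <- vol[idx, , ] + amp
        else if (axis == 2L) vol[, idx, ] <- vol[, idx, ] + amp
        else vol[, , idx] <- vol[, , idx] + amp
    }
    nvt <- if ("vessel_tube" %in% names(counts)) counts[["vessel_tube"]] else 0L
    for (i in seq_len(nvt)) {
        axis <- sample.int(3, 1)            # tube runs along this axis
        others <- setdiff(1:3, axis)
        c1 <- runif(1, 0.2, 0.8) * (d[others[1]] - 1) * spec$spacing_um[others[1]]
        c2 <- runif(1, 0.2, 0.8) * (d[others[2]] - 1) * spec$spacing_um[others[2]]
        r_um <- 2
        g1 <- ((seq_len(d[others[1]]) - 1) * spec$spacing_um[others[1]] - c1)
        g2 <- ((seq_len(d[others[2]]) - 1) * spec$spacing_um[others[2]] - c2)
        prof <- exp(-outer(g1^2, g2^2, "+") / (2 * r_um^2))
        tube <- array(0, d)
        if (axis == 1L) for (z in seq_len(d[1])) tube[z, , ] <- prof
        else if (axis == 2L) tube <- aperm(
            array(rep(prof, d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
        else tube <- array(rep(prof, d[3]), c(d[1], d[2], d[3]))
        vol <- vol + 0.8 * amp * tube
    }
    nsp <- if ("noise_spike" %in% names(counts)) counts[["noise_spike"]] else 0L
    if (nsp > 0) {
        idx <- sample(which(tissue_mask), min(nsp, sum(tissue_mask)))
        vol[idx] <- vol[idx] + 3 * amp
    }
    vol
}

#' Simulate a fluorescence phantom with ground truth
#'
#' Puncta counts per region are independent Poisson draws with mean
#' \code{rate * region volume (mm^3)}; each punctum is placed uniformly
#' within its region and rendered as an anisotropic Gaussian blob with
#' jittered size and amplitude. Artifacts (edge planes, vessel tubes, noise
#' spikes) are rendered on top, then tissue background and additive Gaussian
#' noise. The truth table lists every punctum's world-micrometre centroid
#' and region id; artifacts are never in the truth table.
#'
#' @param atlas an [AtlasBundle]; \code{names(spec$region_rates)} must be
#'   ids present in its ontology.
#' @param spec a [phantomSpec()]; its \code{spacing_um} must match the
#'   atlas for region lookup to be meaningful.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return list with \code{volume} (3D array) and \code{truth}
#'   (a [SpotTable] with \code{source = "truth"}).
#' @export
simulateVolume <- function(atlas, spec, seed = 1L) {
    set.seed(seed)
    labels <- labelVolume(atlas)
    spacing <- spec$spacing_um
    d <- dim(labels)
    voxvol <- prod(spacing) * 1e-9
    rates <- spec$region_rates
    ids <- as.integer(names(rates))
    if (length(ids) && !all(ids %in% structures(atlas)$id))
        stop("region_rates names must be ontology ids")
    vol <- array(0, d)
    xs <- ys <- zs <- rid <- numeric(0)
    for (k in seq_along(ids)) {
        vox <- which(labels == ids[k])
        if (!length(vox)) next
        n <- rpois(1, rates[k] * length(vox) * voxvol)
        if (n == 0) next
        at <- sample(vox, n, replace = TRUE)
        ijk <- arrayInd(at, d)
        ## uniform jitter inside the voxel; voxel centers at (i-1)*spacing
        pz <- (ijk[, 1] - 1 + runif(n, -0.5, 0.5)) * spacing[1]
        py <- (ijk[, 2] - 1 + runif(n, -0.5, 0.5)) * spacing[2]
        px <- (ijk[, 3] - 1 + runif(n, -0.5, 0.5)) * spacing[3]
        zs <- c(zs, pz); ys <- c(ys, py); xs <- c(xs, px)
        rid <- c(rid, rep(ids[k], n))
    }
    amp <- numeric(length(zs))
    for (i in seq_along(zs)) {
        s_mult <- runif(1, 1 - spec$size_jitter, 1 + spec$size_jitter)
        a_mult <- runif(1, 1 - spec$intensity_jitter,
                        1 + spec$intensity_jitter)
        amp[i] <- spec$puncta_amplitude * a_mult
        p <- .blobPatch(d, c(zs[i], ys[i], xs[i]),
                        spec$puncta_sigma_um * s_mult, amp[i], spacing)
        if (!is.null(p))
            vol[p$zi, p$yi, p$xi] <- vol[p$zi, p$yi, p$xi] + p$blob
    }
    tissue <- labels > 0L
    vol <- .renderArtifacts(vol, spec, tissue)
    vol <- vol + spec$background_level * tissue
    if (spec$noise_sd > 0)
        vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), d)
    truth <- spotTable(x_um = xs, y_um = ys, z_um = zs,
                       intensity = if (length(amp)) amp else NA_real_,
                       source = "truth", region_id = rid)
    list(volume = vol, truth = truth)
}
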