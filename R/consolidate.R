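## Grid-hashed DBSCAN over 3D points in world micrometres. Cells of side eps
## limit neighbour search to the 27 surrounding cells. With min_samples = 1
## every point is a core point and clusters are the connected components of
## the eps-graph, which is exactly what duplicate-detection merging needs.

.epsNeighbours <- function(xyz, eps) {
    n <- nrow(xyz)
    cell <- floor(sweep(xyz, 2, eps, "/"))
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    bucket <- split(seq_len(n), key)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    lapply(seq_len(n), function(i) {
        cand <- integer(0)
        for (o in seq_len(nrow(off))) {
            k <- paste(cell[i, 1] + off[o, 1], cell[i, 2] + off[o, 2],
                       cell[i, 3] + off[o, 3])
            b <- bucket[[k]]
            if (!is.null(b)) cand <- c(cand, b)
        }
        d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
            (xyz[cand, 3] - xyz[i, 3])^2
        cand[d2 <= eps^2]
    })
}

## DBSCAN labels: 0 = noise, 1..k = cluster. Neighbourhoods include the
## point itself, so min_samples counts the point.
.dbscan <- function(xyz, eps, min_samples) {
    n <- nrow(xyz)
    if (n == 0L) return(integer(0))
    nb <- .epsNeighbours(xyz, eps)
    core <- lengths(nb) >= min_samples
    labels <- rep(0L, n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (labels[i] != 0L || !core[i]) next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- nb[[i]]
        while (length(queue)) {
            j <- queue[[1]]
            queue <- queue[-1]
            if (labels[j] == 0L) {
                labels[j] <- cl
                if (core[j]) queue <- c(queue, nb[[j]])
            }
        }
    }
    labels
}

#' Consolidate duplicate detections into single points
#'
#' Both detectors are biased towards over-detection, so the same cell is
#' typically found more than once. DBSCAN clustering in world-micrometre
#' space (default eps = 5 um, matching the 5-micron intersection radius used
#' for validation; min_samples = 1 so singletons survive) groups duplicated
#' detections, and each cluster is replaced by a single point: the
#' unweighted centroid of its members, with the maximum member intensity.
#' Idempotent for well-separated clusters, and never increases the number of
#' spots.
#'
#' @param st a [SpotTable] (typically the union of both detectors' outputs).
#' @param eps_um DBSCAN reachability radius in micrometres (> 0).
#' @param min_samples minimum neighbourhood size for a core point; points
#'   failing it are treated as noise and dropped.
#' @return a [SpotTable] with \code{source = "consolidated"}.
#' @export
consolidateSpots <- function(st, eps_um = 5, min_samples = 1L) {
    stopifnot(eps_um > 0, min_samples >= 1L)
    df <- spots(st)
    if (nrow(df) == 0L) return(spotTable(source = "consolidated"))
    xyz <- .spotXYZ(st)
    labels <- .dbscan(xyz, eps_um, min_samples)
    keep <- labels > 0L
    df <- df[keep, , drop = FALSE]
    labels <- labels[keep]
    cen_x <- tapply(df$x_um, labels, mean)
    cen_y <- tapply(df$y_um, labels, mean)
    cen_z <- tapply(df$z_um, labels, mean)
    inten <- tapply(df$intensity, labels, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    border <- tapply(df$border, labels, any)
    spotTable(x_um = as.numeric(cen_x), y_um = as.numeric(cen_y),
              z_um = as.numeric(cen_z), intensity = as.numeric(inten),
              source = "consolidated", border = as.logical(border))
}
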