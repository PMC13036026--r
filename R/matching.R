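## Radius-constrained one-to-one matching of predicted against ground-truth
## spots. Feasible pairs are those within the matching radius; among all
## one-to-one matchings we take one of maximum cardinality and, among those,
## minimum total distance (optimal assignment). Solved exactly by successive
## shortest augmenting paths (Bellman-Ford on the residual graph) over the
## sparse feasible-pair graph; maximum-cardinality augmentation plus
## shortest-path (cheapest) augmenting steps yields the min-cost
## max-cardinality matching.

.mincostMatching <- function(pairs, cost, n_pred, n_truth) {
    match_p <- rep(0L, n_pred)
    match_t <- rep(0L, n_truth)
    if (nrow(pairs) == 0L)
        return(list(match_p = match_p, n_matched = 0L, total = 0))
    nv <- n_pred + n_truth                  # truth node t is n_pred + t
    repeat {
        ## residual graph: unmatched pair edges run pred -> truth at +cost,
        ## matched pair edges run truth -> pred at -cost
        fwd <- match_p[pairs[, 1]] != pairs[, 2]
        u <- ifelse(fwd, pairs[, 1], n_pred + pairs[, 2])
        v <- ifelse(fwd, n_pred + pairs[, 2], pairs[, 1])
        w <- ifelse(fwd, cost, -cost)
        dist <- rep(Inf, nv)
        dist[which(match_p == 0L)] <- 0
        prevEdge <- rep(0L, nv)
        for (iter in seq_len(nv)) {         # Bellman-Ford, no neg cycles
            nd <- dist[u] + w
            improved <- which(nd + 1e-12 < dist[v])
            if (!length(improved)) break
            for (e in improved) {           # sequential to keep best per node
                if (nd[e] + 1e-12 < dist[v[e]]) {
                    dist[v[e]] <- nd[e]
                    prevEdge[v[e]] <- e
                }
            }
        }
        free_t <- which(match_t == 0L)
        reach <- free_t[is.finite(dist[n_pred + free_t])]
        if (!length(reach)) break
        t_end <- reach[which.min(dist[n_pred + reach])]
        ## collect the alternating path, then flip it
        node <- n_pred + t_end
        path <- integer(0)
        while (prevEdge[node] != 0L) {
            e <- prevEdge[node]
            path <- c(path, e)
            node <- u[e]
            if (node <= n_pred && match_p[node] == 0L) break
        }
        for (e in path) {
            p <- pairs[e, 1]; t <- pairs[e, 2]
            if (fwd[e]) {
                match_p[p] <- t
                match_t[t] <- p
            } else {
                if (match_p[p] == t) match_p[p] <- 0L
                if (match_t[t] == p) match_t[t] <- 0L
            }
        }
    }
    matched <- which(match_p != 0L)
    total <- 0
    for (p in matched) {
        e <- which(pairs[, 1] == p & pairs[, 2] == match_p[p])[1]
        total <- total + cost[e]
    }
    list(match_p = match_p, n_matched = length(matched), total = total)
}

#' Match predicted spots against ground truth within a radius
#'
#' One-to-one optimal matching: all (pred, truth) pairs within
#' \code{radius_um} are feasible; the matching maximizes the number of
#' matched pairs and, among such matchings, minimizes the total distance.
#' Precision = matched / n_pred, recall = matched / n_truth, and
#' F1 = 2PR / (P + R) (0 when P + R = 0). The 5-micrometre default radius is
#' the intersection criterion used when validating detections against
#' expert annotation.
#'
#' @param pred,truth [SpotTable]s (or data.frames with \code{x_um, y_um,
#'   z_um}).
#' @param radius_um matching radius in micrometres (> 0).
#' @return a [MatchResult].
#' @export
matchSpots <- function(pred, truth, radius_um = 5) {
    stopifnot(radius_um > 0)
    P <- if (is(pred, "SpotTable")) .spotXYZ(pred) else
        as.matrix(pred[, c("x_um", "y_um", "z_um")])
    T_ <- if (is(truth, "SpotTable")) .spotXYZ(truth) else
        as.matrix(truth[, c("x_um", "y_um", "z_um")])
    np <- nrow(P); nt <- nrow(T_)
    n_matched <- 0L
    if (np > 0L && nt > 0L) {
        pairs <- .feasiblePairs(P, T_, radius_um)
        if (nrow(pairs)) {
            ## decompose into connected components of the bipartite graph;
            ## each is solved independently (typically 1-3 spots per side)
            g <- igraph::make_graph(
                rbind(pairs[, 1], np + pairs[, 2]), n = np + nt,
                directed = FALSE)
            comp <- igraph::components(g)$membership
            for (cm in unique(comp[pairs[, 1]])) {
                sel <- comp[pairs[, 1]] == cm
                sub <- pairs[sel, , drop = FALSE]
                pmap <- sort(unique(sub[, 1]))
                tmap <- sort(unique(sub[, 2]))
                subi <- cbind(match(sub[, 1], pmap), match(sub[, 2], tmap))
                res <- .mincostMatching(subi, pairs[sel, 3], length(pmap),
                                        length(tmap))
                n_matched <- n_matched + res$n_matched
            }
        }
    }
    precision <- if (np > 0) n_matched / np else 0
    recall <- if (nt > 0) n_matched / nt else 0
    ## 2PR/(P+R) algebraically equals 2m/(np+nt); the latter avoids
    ## rounding at exact boundaries such as F1 = 0.8
    f1 <- if (precision + recall > 0) 2 * n_matched / (np + nt) else 0
    new("MatchResult", n_truth = as.integer(nt), n_pred = as.integer(np),
        n_matched = as.integer(n_matched), precision = precision,
        recall = recall, f1 = f1)
}

## sparse feasible pairs via eps-grid hashing; columns (pred, truth, dist)
.feasiblePairs <- function(P, T_, radius) {
    cellP <- floor(P / radius)
    cellT <- floor(T_ / radius)
    keyT <- paste(cellT[, 1], cellT[, 2], cellT[, 3])
    bucketT <- split(seq_len(nrow(T_)), keyT)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    out <- vector("list", nrow(P))
    for (i in seq_len(nrow(P))) {
        cand <- integer(0)
        for (o in seq_len(nrow(off))) {
            k <- paste(cellP[i, 1] + off[o, 1], cellP[i, 2] + off[o, 2],
                       cellP[i, 3] + off[o, 3])
            b <- bucketT[[k]]
            if (!is.null(b)) cand <- c(cand, b)
        }
        if (!length(cand)) next
        dd <- sqrt((T_[cand, 1] - P[i, 1])^2 + (T_[cand, 2] - P[i, 2])^2 +
                   (T_[cand, 3] - P[i, 3])^2)
        ok <- dd <= radius
        if (any(ok))
            out[[i]] <- cbind(i, cand[ok], dd[ok])
    }
    res <- do.call(rbind, out)
    if (is.null(res)) matrix(numeric(0), 0, 3) else res
}
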