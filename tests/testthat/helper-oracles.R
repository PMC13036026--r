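## independent oracles, deliberately brute force

## all one-to-one matchings within the radius: maximize cardinality, then
## minimize total distance; recursion over predictions
bruteForceMatch <- function(P, T_, radius) {
    np <- nrow(P); nt <- nrow(T_)
    D <- matrix(Inf, max(np, 1), max(nt, 1))
    for (i in seq_len(np)) for (j in seq_len(nt)) {
        d <- sqrt(sum((P[i, ] - T_[j, ])^2))
        if (d <= radius) D[i, j] <- d
    }
    best <- list(card = -1L, cost = Inf)
    recurse <- function(i, used, card, cost) {
        if (i > np) {
            if (card > best$card ||
                (card == best$card && cost < best$cost - 1e-12))
                best <<- list(card = card, cost = cost)
            return(invisible(NULL))
        }
        recurse(i + 1L, used, card, cost)        # skip prediction i
        for (j in seq_len(nt)) {
            if (!used[j] && is.finite(D[i, j])) {
                used[j] <- TRUE
                recurse(i + 1L, used, card + 1L, cost + D[i, j])
                used[j] <- FALSE
            }
        }
    }
    if (np > 0 && nt > 0) recurse(1L, rep(FALSE, nt), 0L, 0)
    else best <- list(card = 0L, cost = 0)
    best
}

## textbook step-up definition
bruteForceBH <- function(p) {
    n <- length(p)
    o <- order(p)
    raw <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(raw)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

## descendant sets by repeated direct-child expansion over the raw table
bruteForceDescendants <- function(tab, id) {
    out <- integer(0)
    frontier <- id
    repeat {
        kids <- tab$id[!is.na(tab$parent_id) & tab$parent_id %in% frontier]
        kids <- setdiff(kids, out)
        if (!length(kids)) break
        out <- c(out, kids)
        frontier <- kids
    }
    sort(out)
}
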