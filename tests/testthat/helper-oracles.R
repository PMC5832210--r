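# Independent brute-force oracles: plain nested-loop enumeration, kept
# deliberately naive and separate from the package implementations.

allDirections26 <- function() {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# naive GLCM: enumerate every in-ROI voxel pair per direction
naiveGLCM <- function(bins, ng) {
    dirs13 <- directionSet()
    dm <- dim(bins)
    acc <- matrix(0, ng, ng)
    used <- 0
    for (k in seq_len(nrow(dirs13))) {
        d <- dirs13[k, ]
        cnt <- matrix(0, ng, ng)
        for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
            a <- bins[x, y, z]
            if (is.na(a)) next
            p <- c(x, y, z) + d
            if (any(p < 1) || any(p > dm)) next
            b <- bins[p[1], p[2], p[3]]
            if (is.na(b)) next
            cnt[a, b] <- cnt[a, b] + 1
        }
        cnt <- cnt + t(cnt)
        if (sum(cnt) == 0) next
        acc <- acc + cnt / sum(cnt)
        used <- used + 1
    }
    if (used == 0) stop("no pairs")
    acc / used
}

# naive GLRLM: walk every line voxel by voxel
naiveGLRLM <- function(bins, ng) {
    dirs13 <- directionSet()
    dm <- dim(bins)
    runs <- list()
    for (k in seq_len(nrow(dirs13))) {
        d <- dirs13[k, ]
        for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
            g <- bins[x, y, z]
            if (is.na(g)) next
            prev <- c(x, y, z) - d
            if (all(prev >= 1) && all(prev <= dm)) {
                pb <- bins[prev[1], prev[2], prev[3]]
                if (!is.na(pb) && pb == g) next  # not a run start
            }
            len <- 1
            cur <- c(x, y, z) + d
            while (all(cur >= 1) && all(cur <= dm)) {
                cb <- bins[cur[1], cur[2], cur[3]]
                if (is.na(cb) || cb != g) break
                len <- len + 1
                cur <- cur + d
            }
            runs[[length(runs) + 1]] <- c(k, g, len)
        }
    }
    rn <- do.call(rbind, runs)
    rmax <- max(rn[, 3])
    acc <- matrix(0, ng, rmax)
    for (i in seq_len(nrow(rn)))
        acc[rn[i, 2], rn[i, 3]] <- acc[rn[i, 2], rn[i, 3]] + 1
    acc / nrow(dirs13)
}

# naive GLSZM: BFS flood fill per grey level, 26-connectivity
naiveGLSZM <- function(bins, ng) {
    dm <- dim(bins)
    dirs26 <- allDirections26()
    seen <- array(FALSE, dm)
    zones <- list()
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
        if (is.na(bins[x, y, z]) || seen[x, y, z]) next
        g <- bins[x, y, z]
        queue <- list(c(x, y, z))
        seen[x, y, z] <- TRUE
        size <- 0
        while (length(queue)) {
            v <- queue[[1]]; queue <- queue[-1]
            size <- size + 1
            for (k in seq_len(nrow(dirs26))) {
                p <- v + dirs26[k, ]
                if (any(p < 1) || any(p > dm)) next
                if (seen[p[1], p[2], p[3]]) next
                b <- bins[p[1], p[2], p[3]]
                if (is.na(b) || b != g) next
                seen[p[1], p[2], p[3]] <- TRUE
                queue[[length(queue) + 1]] <- p
            }
        }
        zones[[length(zones) + 1]] <- c(g, size)
    }
    zn <- do.call(rbind, zones)
    smax <- max(zn[, 2])
    acc <- matrix(0, ng, smax)
    for (i in seq_len(nrow(zn)))
        acc[zn[i, 1], zn[i, 2]] <- acc[zn[i, 1], zn[i, 2]] + 1
    acc
}

# brute-force Harrell's C: all ordered pairs, usable when the earlier
# time is an event (or exactly one of a tied pair is an event)
bruteForceC <- function(risk, time, event) {
    n <- length(risk)
    num <- 0; den <- 0
    for (i in 1:n) for (j in 1:n) {
        if (i == j) next
        usable <- (time[i] < time[j] && event[i] == 1) ||
            (time[i] == time[j] && event[i] == 1 && event[j] == 0)
        if (!usable) next
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
    }
    num / den
}

# small random masked discretized volume for oracle comparisons
randomDiscretizedROI <- function(seed, maxDim = 6, nLevels = 3) {
    set.seed(seed)
    dm <- sample(2:maxDim, 3, replace = TRUE)
    vals <- array(sample(seq_len(nLevels), prod(dm), TRUE) * 0.5 - 0.25,
                  dm)
    ind <- array(stats::runif(prod(dm)) < 0.7, dm)
    if (!any(ind)) ind[1, 1, 1] <- TRUE
    img <- SUVImage(vals, spacing = c(1, 1, 1))
    msk <- ROIMask(ind, spacing = c(1, 1, 1))
    discretize(img, msk, binWidth = 0.5)
}

# tiny deterministic image/mask pair used across tests
smallFixture <- function(vals, ind = NULL, spacing = c(1, 1, 1)) {
    arr <- if (is.array(vals)) vals else array(vals, c(2, 2, 2))
    if (is.null(ind)) ind <- array(TRUE, dim(arr))
    list(image = SUVImage(arr, spacing = spacing),
         mask = ROIMask(ind, spacing = spacing))
}
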