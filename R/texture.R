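# Texture matrix construction on the discretized ROI.
#
# All three matrices work on the 26-neighborhood at a distance of one
# voxel. GLCM and GLRLM are accumulated per direction over the 13
# sign-unique offsets and averaged; GLSZM is directionless.

# overlap of the grid with itself shifted by d; returns the two aligned
# bin sub-arrays (NA outside the ROI)
.shiftedPair <- function(bins, d) {
    dm <- dim(bins)
    x0 <- max(1L, 1L - d[1]); x1 <- min(dm[1], dm[1] - d[1])
    y0 <- max(1L, 1L - d[2]); y1 <- min(dm[2], dm[2] - d[2])
    z0 <- max(1L, 1L - d[3]); z1 <- min(dm[3], dm[3] - d[3])
    if (x0 > x1 || y0 > y1 || z0 > z1)
        return(list(a = integer(0), b = integer(0)))
    a <- bins[x0:x1, y0:y1, z0:z1, drop = FALSE]
    b <- bins[(x0 + d[1]):(x1 + d[1]), (y0 + d[2]):(y1 + d[2]),
              (z0 + d[3]):(z1 + d[3]), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    list(a = a[ok], b = b[ok])
}

#' Grey-level co-occurrence matrix (GLCM)
#'
#' Counts pairs of grey levels at neighboring voxels (distance one voxel,
#' 26-connectivity). For each of the 13 directions, in-ROI voxel pairs are
#' counted, the count matrix is symmetrized and normalized to a
#' probability distribution; the returned matrix is the average over the
#' directions that contribute at least one pair.
#'
#' @param disc a `DiscretizedROI` from [discretize()].
#' @return Ng x Ng symmetric matrix summing to 1.
#' @export
computeGLCM <- function(disc) {
    stopifnot(inherits(disc, "DiscretizedROI"))
    ng <- disc$nLevels
    dirs <- directionSet()
    acc <- matrix(0, ng, ng)
    used <- 0L
    for (k in seq_len(nrow(dirs))) {
        p <- .shiftedPair(disc$bins, dirs[k, ])
        if (length(p$a) == 0L) next
        cnt <- matrix(tabulate((p$a - 1L) * ng + p$b, nbins = ng * ng),
                      ng, ng)
        cnt <- cnt + t(cnt)
        acc <- acc + cnt / sum(cnt)
        used <- used + 1L
    }
    if (used == 0L)
        stop("ROI has no neighboring voxel pair in any direction; ",
             "co-occurrence texture is undefined")
    acc / used
}

#' Grey-level run-length matrix (GLRLM)
#'
#' For each direction, the in-ROI voxels decompose into maximal collinear
#' runs of equal grey level (a run breaks at the ROI boundary or at a
#' grey-level change). Entry (g, r) counts runs of level g and length r;
#' the matrix is averaged over the 13 directions.
#'
#' @param disc a `DiscretizedROI`.
#' @return Ng x Rmax matrix of (averaged) run counts.
#' @export
computeGLRLM <- function(disc) {
    stopifnot(inherits(disc, "DiscretizedROI"))
    bins <- disc$bins
    ng <- disc$nLevels
    dm <- dim(bins)
    dirs <- directionSet()
    perDir <- vector("list", nrow(dirs))
    rmax <- 1L
    roi <- which(!is.na(bins), arr.ind = TRUE)
    roiBin <- bins[!is.na(bins)]
    for (k in seq_len(nrow(dirs))) {
        d <- dirs[k, ]
        # run starts: ROI voxels whose predecessor along d is absent or of
        # a different grey level
        prev <- sweep(roi, 2, d)
        inb <- prev[, 1] >= 1 & prev[, 1] <= dm[1] &
               prev[, 2] >= 1 & prev[, 2] <= dm[2] &
               prev[, 3] >= 1 & prev[, 3] <= dm[3]
        prevBin <- rep(NA_integer_, nrow(roi))
        if (any(inb))
            prevBin[inb] <- bins[prev[inb, , drop = FALSE]]
        isStart <- is.na(prevBin) | prevBin != roiBin
        cur <- roi[isStart, , drop = FALSE]
        g <- roiBin[isStart]
        len <- rep(1L, nrow(cur))
        active <- rep(TRUE, nrow(cur))
        pos <- cur
        while (any(active)) {
            nxt <- sweep(pos[active, , drop = FALSE], 2, -d)
            ok <- nxt[, 1] >= 1 & nxt[, 1] <= dm[1] &
                  nxt[, 2] >= 1 & nxt[, 2] <= dm[2] &
                  nxt[, 3] >= 1 & nxt[, 3] <= dm[3]
            same <- rep(FALSE, nrow(nxt))
            if (any(ok)) {
                nb <- bins[nxt[ok, , drop = FALSE]]
                same[ok] <- !is.na(nb) & nb == g[active][ok]
            }
            idx <- which(active)
            cont <- idx[same]
            len[cont] <- len[cont] + 1L
            active[idx[!same]] <- FALSE
            pos[cont, ] <- nxt[same, , drop = FALSE]
        }
        perDir[[k]] <- cbind(g = g, r = len)
        rmax <- max(rmax, len)
    }
    acc <- matrix(0, ng, rmax)
    for (k in seq_along(perDir)) {
        gr <- perDir[[k]]
        acc <- acc + matrix(tabulate((gr[, 1] - 1L) * rmax + gr[, 2],
                                     nbins = ng * rmax),
                            ng, rmax, byrow = TRUE)
    }
    acc / nrow(dirs)
}

#' Grey-level size-zone matrix (GLSZM)
#'
#' Entry (g, s) counts the 26-connected zones of grey level g containing
#' exactly s voxels. The matrix is directionless by construction.
#'
#' @param disc a `DiscretizedROI`.
#' @return Ng x Smax matrix of zone counts.
#' @export
computeGLSZM <- function(disc) {
    stopifnot(inherits(disc, "DiscretizedROI"))
    bins <- disc$bins
    ng <- disc$nLevels
    lin <- which(!is.na(bins))
    if (length(lin) == 0L) stop("mask is empty")
    id <- integer(length(bins))
    id[lin] <- seq_along(lin)
    dirs <- directionSet()
    eFrom <- integer(0); eTo <- integer(0)
    for (k in seq_len(nrow(dirs))) {
        p <- .shiftedPairLinear(bins, dirs[k, ])
        if (length(p$a) == 0L) next
        same <- bins[p$a] == bins[p$b]
        eFrom <- c(eFrom, id[p$a[same]])
        eTo <- c(eTo, id[p$b[same]])
    }
    if (length(eFrom)) {
        g <- igraph::make_graph(rbind(eFrom, eTo), n = length(lin),
                                directed = FALSE)
        comp <- igraph::components(g)
        member <- comp$membership
        sizes <- comp$csize
    } else {
        member <- seq_along(lin)
        sizes <- rep(1L, length(lin))
    }
    lev <- bins[lin][match(seq_along(sizes), member)]
    smax <- max(sizes)
    matrix(tabulate((lev - 1L) * smax + sizes, nbins = ng * smax),
           ng, smax, byrow = TRUE)
}

# same as .shiftedPair but returns linear indices of the paired voxels
.shiftedPairLinear <- function(bins, d) {
    dm <- dim(bins)
    x0 <- max(1L, 1L - d[1]); x1 <- min(dm[1], dm[1] - d[1])
    y0 <- max(1L, 1L - d[2]); y1 <- min(dm[2], dm[2] - d[2])
    z0 <- max(1L, 1L - d[3]); z1 <- min(dm[3], dm[3] - d[3])
    if (x0 > x1 || y0 > y1 || z0 > z1)
        return(list(a = integer(0), b = integer(0)))
    gx <- x0:x1; gy <- y0:y1; gz <- z0:z1
    linA <- outer(outer(gx, (gy - 1L) * dm[1], `+`),
                  (gz - 1L) * dm[1] * dm[2], `+`)
    linB <- linA + d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
    ok <- !is.na(bins[linA]) & !is.na(bins[linB])
    list(a = linA[ok], b = linB[ok])
}
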