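#' Fixed-bin-width SUV discretization
#'
#' Texture analysis requires the continuous SUV scale to be discretized
#' into grey levels. A fixed bin width W (default 0.5 SUV) is used:
#' for each ROI voxel x,
#' \deqn{I_D(x) = \lceil I(x)/W \rceil - \min_{ROI} \lceil I(x)/W \rceil + 1,}
#' so the lowest occupied bin is always relabeled 1 and the number of grey
#' levels Ng equals the maximum label. A fixed bin width (as opposed to a
#' fixed number of bins) preserves the SUV contrast scale across ROIs.
#'
#' @param image an [SUVImage-class].
#' @param mask a non-empty [ROIMask-class] on the same grid.
#' @param binWidth bin width in SUV units (> 0).
#' @return a `DiscretizedROI`: list with `bins` (integer 3D array, `NA`
#'   outside the ROI), `nLevels` (Ng), `binWidth`, `mask` (logical array)
#'   and `spacing`.
#' @examples
#' img <- SUVImage(array(c(0.2, 0.6, 1.0, 2.3, 0, 0, 0, 0), c(2, 2, 2)))
#' msk <- ROIMask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
#' d <- discretize(img, msk)
#' d$bins[msk@indicator]  # 1 2 2 5
#' @export
discretize <- function(image, mask, binWidth = 0.5) {
    stopifnot(is(image, "SUVImage"), is(mask, "ROIMask"))
    if (!identical(dim(suvValues(image)), dim(maskArray(mask))))
        stop("image and mask grids are not congruent")
    if (binWidth <= 0) stop("binWidth must be > 0")
    ind <- maskArray(mask)
    if (!any(ind)) stop("mask is empty")
    v <- suvValues(image)[ind]
    if (any(v < 0)) stop("masked SUV values must be non-negative")
    cl <- ceiling(v / binWidth)
    lab <- as.integer(cl - min(cl) + 1)
    bins <- array(NA_integer_, dim = dim(ind))
    bins[ind] <- lab
    structure(list(bins = bins, nLevels = max(lab), binWidth = binWidth,
                   mask = ind, spacing = voxelSpacing(mask)),
              class = "DiscretizedROI")
}

#' The 13 unique 3D neighbor directions
#'
#' Two voxels are neighbors when their index offset lies in the
#' 26-neighborhood (Chebyshev distance 1 in 3D). Because an offset and its
#' negation define the same direction, texture matrices are accumulated
#' over the 13 sign-unique offsets; their signed closure is the full
#' 26-neighborhood.
#'
#' @return integer matrix with 13 rows and columns `dx`, `dy`, `dz`.
#' @export
directionSet <- function() {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
    # keep one representative per {d, -d}: first nonzero component positive
    keep <- apply(g, 1, function(d) {
        nz <- d[d != 0]
        nz[1] > 0
    })
    out <- g[keep, , drop = FALSE]
    storage.mode(out) <- "integer"
    rownames(out) <- NULL
    out
}
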