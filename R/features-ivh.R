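#' Intensity-volume histogram features (45 features)
#'
#' The intensity-volume histogram (IVH) gives, for each intensity
#' threshold, the fraction of the ROI volume with SUV at or above the
#' threshold. The feature set comprises:
#' \itemize{
#'   \item `ivh_v10` .. `ivh_v90`: volume fraction at thresholds placed at
#'     10..90\% of the ROI intensity range above the minimum (9 features);
#'   \item `ivh_i10` .. `ivh_i90`: the minimum intensity of the hottest
#'     x\% of the ROI volume, x = 10..90 (9);
#'   \item `ivh_v10_minus_v90` .. `ivh_v40_minus_v60` and
#'     `ivh_i10_minus_i90` .. `ivh_i40_minus_i60`: the four
#'     Vx - V(100-x) and four Ix - I(100-x) differences (8);
#'   \item `ivh_vf_suv1` .. `ivh_vf_suv9`: volume fraction at absolute SUV
#'     thresholds 1.0..9.0 (9);
#'   \item `ivh_av_suv1` .. `ivh_av_suv9`: absolute ROI volume in cc at
#'     or above the same absolute thresholds (9);
#'   \item `ivh_auc`: area under the IVH over the normalized intensity
#'     range (1); for a constant ROI the IVH is identically 1 over the
#'     degenerate range and the AUC is defined as 1.
#' }
#'
#' @param image an [SUVImage-class].
#' @param mask a non-empty [ROIMask-class].
#' @return named numeric of length 45, names prefixed `ivh_`.
#' @export
ivhFeatures <- function(image, mask) {
    stopifnot(is(image, "SUVImage"), is(mask, "ROIMask"))
    ind <- maskArray(mask)
    if (!any(ind)) stop("mask is empty")
    v <- suvValues(image)[ind]
    n <- length(v)
    volCC <- n * prod(voxelSpacing(mask)) / 1000
    lo <- min(v); hi <- max(v); rng <- hi - lo
    fracAtOrAbove <- function(t) sum(v >= t) / n
    xs <- seq(10, 90, by = 10)
    vx <- vapply(xs, function(x) fracAtOrAbove(lo + rng * x / 100),
                 numeric(1))
    names(vx) <- sprintf("ivh_v%d", xs)
    # Ix: minimum intensity of the hottest x% of the volume
    sv <- sort(v, decreasing = TRUE)
    ix <- vapply(xs, function(x) sv[ceiling(x / 100 * n)], numeric(1))
    names(ix) <- sprintf("ivh_i%d", xs)
    dx <- c(10, 20, 30, 40)
    vd <- vx[sprintf("ivh_v%d", dx)] - vx[sprintf("ivh_v%d", 100 - dx)]
    names(vd) <- sprintf("ivh_v%d_minus_v%d", dx, 100 - dx)
    id <- ix[sprintf("ivh_i%d", dx)] - ix[sprintf("ivh_i%d", 100 - dx)]
    names(id) <- sprintf("ivh_i%d_minus_i%d", dx, 100 - dx)
    ts <- 1:9
    vf <- vapply(ts, fracAtOrAbove, numeric(1))
    names(vf) <- sprintf("ivh_vf_suv%d", ts)
    av <- vf * volCC
    names(av) <- sprintf("ivh_av_suv%d", ts)
    auc <- if (rng > 0) mean((v - lo) / rng) else 1
    c(vx, ix, vd, id, vf, av, ivh_auc = auc)
}
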