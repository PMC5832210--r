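#' First-order statistics of the ROI SUV distribution (16 features)
#'
#' Intensity-histogram descriptors computed on the raw masked SUV values.
#' Entropy and uniformity use the same fixed-bin-width discretization
#' (default 0.5 SUV) as the texture families so a single discretization
#' contract governs the whole vector; logarithms are base 2. The SUV peak
#' is the mean over the 3 x 3 x 3 voxel neighborhood of the hottest voxel
#' (about 1.5 cc on the development grid), restricted to the ROI; ties on
#' the hottest voxel resolve to the first voxel in array order. Skewness
#' and (Pearson) kurtosis of a zero-variance ROI are defined as 0 so the
#' feature vector stays finite on degenerate inputs.
#'
#' @param image an [SUVImage-class].
#' @param mask a non-empty [ROIMask-class].
#' @param binWidth bin width (SUV) for the entropy/uniformity histogram.
#' @return named numeric of length 16, names prefixed `stats_`.
#' @export
firstOrderFeatures <- function(image, mask, binWidth = 0.5) {
    stopifnot(is(image, "SUVImage"), is(mask, "ROIMask"))
    ind <- maskArray(mask)
    if (!any(ind)) stop("mask is empty")
    v <- suvValues(image)[ind]
    n <- length(v)
    m <- mean(v)
    va <- sum((v - m)^2) / n        # population variance
    s <- sqrt(va)
    skew <- if (s > 0) sum((v - m)^3) / n / s^3 else 0
    kurt <- if (s > 0) sum((v - m)^4) / n / va^2 else 0
    # histogram on the shared fixed-bin-width discretization
    lab <- ceiling(v / binWidth)
    p <- tabulate(lab - min(lab) + 1L)
    p <- p[p > 0] / n
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
    # SUV peak: ROI-restricted 3x3x3 neighborhood mean at the hottest voxel
    vals <- suvValues(image)
    dm <- dim(vals)
    hot <- which(ind & vals == max(v), arr.ind = TRUE)[1, ]
    xs <- max(1, hot[1] - 1):min(dm[1], hot[1] + 1)
    ys <- max(1, hot[2] - 1):min(dm[2], hot[2] + 1)
    zs <- max(1, hot[3] - 1):min(dm[3], hot[3] + 1)
    nb <- vals[xs, ys, zs][ind[xs, ys, zs]]
    c(stats_minimum = min(v),
      stats_maximum = max(v),
      stats_range = max(v) - min(v),
      stats_mean = m,
      stats_median = stats::median(v),
      stats_sd = s,
      stats_variance = va,
      stats_skewness = skew,
      stats_kurtosis = kurt,
      stats_energy = sum(v^2),
      stats_entropy = entropy,
      stats_uniformity = uniformity,
      stats_mad = mean(abs(v - m)),
      stats_rms = sqrt(mean(v^2)),
      stats_suv_peak = mean(nb),
      stats_cov = if (m != 0) s / m else 0)
}
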