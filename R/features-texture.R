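#' GLCM features (22 features)
#'
#' Standard Haralick-style descriptors of the direction-averaged,
#' normalized co-occurrence matrix. Logarithms are base 2. On a
#' degenerate single-level matrix the correlation-type features take
#' their defined fallback: correlation = 0, IMC1 = 0, IMC2 = 0.
#'
#' @param P Ng x Ng symmetric co-occurrence probability matrix (sums
#'   to 1), as returned by [computeGLCM()].
#' @return named numeric of length 22, names prefixed `glcm_`.
#' @export
glcmFeatures <- function(P) {
    stopifnot(is.matrix(P), nrow(P) == ncol(P))
    P <- P / sum(P)
    ng <- nrow(P)
    i <- matrix(seq_len(ng), ng, ng)
    j <- t(i)
    px <- rowSums(P)                     # == colSums by symmetry
    mu <- sum(seq_len(ng) * px)
    sg <- sqrt(sum((seq_len(ng) - mu)^2 * px))
    log2z <- function(x) ifelse(x > 0, log2(x), 0)
    # diagonal and cross-diagonal marginals
    pxmy <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]),
                   numeric(1))
    pxpy <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]),
                   numeric(1))
    sumAvg <- sum((2:(2 * ng)) * pxpy)
    hxy <- -sum(P * log2z(P))
    hx <- -sum(px * log2z(px))
    pij <- outer(px, px)
    hxy1 <- -sum(P * log2z(pij))
    hxy2 <- -sum(pij * log2z(pij))
    imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
    imc2 <- max(0, 1 - 2^(-2 * (hxy2 - hxy)))
    imc2 <- sqrt(imc2)
    corr <- if (sg > 0) (sum(i * j * P) - mu^2) / sg^2 else 0
    offd <- i != j
    c(glcm_autocorrelation = sum(i * j * P),
      glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
      glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
      glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
      glcm_contrast = sum((i - j)^2 * P),
      glcm_correlation = corr,
      glcm_difference_entropy = -sum(pxmy * log2z(pxmy)),
      glcm_dissimilarity = sum(abs(i - j) * P),
      glcm_energy = sum(P^2),
      glcm_entropy = hxy,
      glcm_homogeneity1 = sum(P / (1 + abs(i - j))),
      glcm_homogeneity2 = sum(P / (1 + (i - j)^2)),
      glcm_imc1 = imc1,
      glcm_imc2 = imc2,
      glcm_idmn = sum(P / (1 + (i - j)^2 / ng^2)),
      glcm_idn = sum(P / (1 + abs(i - j) / ng)),
      glcm_inverse_variance = sum(P[offd] / (i[offd] - j[offd])^2),
      glcm_max_probability = max(P),
      glcm_sum_average = sumAvg,
      glcm_sum_entropy = -sum(pxpy * log2z(pxpy)),
      glcm_sum_variance = sum(((2:(2 * ng)) - sumAvg)^2 * pxpy),
      glcm_variance = sum((i - mu)^2 * P))
}

#' GLRLM features (11 features)
#'
#' Run-emphasis descriptors of the direction-averaged run-length matrix:
#' short/long-run emphasis, grey-level and run-length non-uniformity, run
#' percentage, and the low/high grey-level crosses.
#'
#' @param R Ng x Rmax run-length matrix from [computeGLRLM()].
#' @param nVoxels number of ROI voxels (for run percentage).
#' @return named numeric of length 11, names prefixed `glrlm_`.
#' @export
glrlmFeatures <- function(R, nVoxels) {
    stopifnot(is.matrix(R))
    g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
    r <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
    nr <- sum(R)
    c(glrlm_sre = sum(R / r^2) / nr,
      glrlm_lre = sum(R * r^2) / nr,
      glrlm_gln = sum(rowSums(R)^2) / nr,
      glrlm_rln = sum(colSums(R)^2) / nr,
      glrlm_rp = nr / nVoxels,
      glrlm_lgre = sum(R / g^2) / nr,
      glrlm_hgre = sum(R * g^2) / nr,
      glrlm_srlge = sum(R / (g^2 * r^2)) / nr,
      glrlm_srhge = sum(R * g^2 / r^2) / nr,
      glrlm_lrlge = sum(R * r^2 / g^2) / nr,
      glrlm_lrhge = sum(R * g^2 * r^2) / nr)
}

#' GLSZM features (11 features)
#'
#' Zone-based analogues of the run-length descriptors on the
#' (directionless) size-zone matrix.
#'
#' @param S Ng x Smax size-zone matrix from [computeGLSZM()].
#' @param nVoxels number of ROI voxels (for zone percentage).
#' @return named numeric of length 11, names prefixed `glszm_`.
#' @export
glszmFeatures <- function(S, nVoxels) {
    stopifnot(is.matrix(S))
    g <- matrix(seq_len(nrow(S)), nrow(S), ncol(S))
    s <- matrix(seq_len(ncol(S)), nrow(S), ncol(S), byrow = TRUE)
    nz <- sum(S)
    c(glszm_sze = sum(S / s^2) / nz,
      glszm_lze = sum(S * s^2) / nz,
      glszm_gln = sum(rowSums(S)^2) / nz,
      glszm_zsn = sum(colSums(S)^2) / nz,
      glszm_zp = nz / nVoxels,
      glszm_lgze = sum(S / g^2) / nz,
      glszm_hgze = sum(S * g^2) / nz,
      glszm_szlge = sum(S / (g^2 * s^2)) / nz,
      glszm_szhge = sum(S * g^2 / s^2) / nz,
      glszm_lzlge = sum(S * s^2 / g^2) / nz,
      glszm_lzhge = sum(S * g^2 * s^2) / nz)
}
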