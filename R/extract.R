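#' Extract the full 118-feature radiomics vector
#'
#' Computes all six feature families on one (image, ROI) pair: 16
#' first-order statistics, 13 shape descriptors, 45 intensity-volume
#' histogram features, and 44 texture features (22 GLCM + 11 GLRLM + 11
#' GLSZM) on the fixed-bin-width discretized ROI.
#'
#' @param image an [SUVImage-class].
#' @param mask a non-empty [ROIMask-class] with at least one pair of
#'   neighboring voxels (texture is undefined on isolated voxels).
#' @param binWidth SUV bin width for discretization (default 0.5).
#' @return named numeric of length 118; `featureFamilies()` maps each
#'   name to its family.
#' @examples
#' sim <- simulatePatientImages(phantomSpec(seed = 1))
#' fv <- extractAll(sim$image, sim$tumor)
#' length(fv)        # 118
#' table(featureFamilies(names(fv)))
#' @export
extractAll <- function(image, mask, binWidth = 0.5) {
    disc <- discretize(image, mask, binWidth)
    n <- sum(disc$mask)
    out <- c(firstOrderFeatures(image, mask, binWidth),
             shapeFeatures(mask),
             ivhFeatures(image, mask),
             glcmFeatures(computeGLCM(disc)),
             glrlmFeatures(computeGLRLM(disc), n),
             glszmFeatures(computeGLSZM(disc), n))
    stopifnot(length(out) == 118L, all(is.finite(out)))
    out
}

#' Map feature names to their families
#'
#' @param featureNames character vector of canonical feature names
#'   (family prefix + underscore).
#' @return factor with levels `first_order`, `shape`, `ivh`, `glcm`,
#'   `glrlm`, `glszm`.
#' @export
featureFamilies <- function(featureNames) {
    pre <- sub("_.*$", "", featureNames)
    map <- c(stats = "first_order", shape = "shape", ivh = "ivh",
             glcm = "glcm", glrlm = "glrlm", glszm = "glszm")
    factor(unname(map[pre]), levels = unname(map))
}

#' Extract features for a list of structures across patients
#'
#' Convenience wrapper building a per-patient feature table (one row per
#' patient, 118 columns) for a single structure.
#'
#' @param images list of [SUVImage-class], one per patient.
#' @param masks list of [ROIMask-class], aligned with `images`.
#' @param binWidth SUV bin width.
#' @return data.frame of features with one row per patient.
#' @export
extractCohort <- function(images, masks, binWidth = 0.5) {
    stopifnot(length(images) == length(masks))
    rows <- mapply(function(im, mk) extractAll(im, mk, binWidth),
                   images, masks, SIMPLIFY = TRUE)
    as.data.frame(t(rows))
}
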