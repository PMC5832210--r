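#' @import methods
NULL

VALID_MASK_LABELS <- c("tumor", "node", "LN_merged", "LN_volume", "LN_max")

#' SUVImage: a 3D standardized-uptake-value image
#'
#' Container for a 3D scalar field of standardized uptake values (SUV,
#' dimensionless) on a regular voxel grid with physical spacing in mm.
#'
#' @slot values numeric 3D array of SUV values.
#' @slot spacing numeric length-3, voxel spacing in mm per axis.
#' @slot origin numeric length-3, position in mm of the center of voxel
#'   (1,1,1).
#' @export
setClass("SUVImage",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    prototype(spacing = c(4.0728, 4.0728, 3), origin = c(0, 0, 0))
)

setValidity("SUVImage", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3D array")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "all SUV values must be finite")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (mm)")
    if (length(msg)) msg else TRUE
})

#' ROIMask: a binary region-of-interest mask on an SUV grid
#'
#' A binary 3D mask congruent with its paired [SUVImage], labeled by the
#' structure it delineates: the primary tumor, an individual metastatic
#' lymph node (`"node"`), or one of the derived nodal structures
#' (`"LN_merged"`, `"LN_volume"`, `"LN_max"`).
#'
#' @slot indicator logical 3D array; `TRUE` marks ROI voxels.
#' @slot spacing numeric length-3, voxel spacing in mm (same grid as the
#'   paired image).
#' @slot label character structure label.
#' @export
setClass("ROIMask",
    representation(indicator = "array", spacing = "numeric",
                   label = "character"),
    prototype(spacing = c(4.0728, 4.0728, 3), label = "tumor")
)

setValidity("ROIMask", function(object) {
    msg <- character()
    if (length(dim(object@indicator)) != 3L)
        msg <- c(msg, "indicator must be a 3D array")
    if (!is.logical(object@indicator))
        msg <- c(msg, "indicator must be logical")
    if (anyNA(object@indicator))
        msg <- c(msg, "indicator must not contain NA")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    if (length(object@label) != 1L)
        msg <- c(msg, "label must be a single string")
    else if (!object@label %in% VALID_MASK_LABELS &&
             !grepl("^node_[0-9]+$", object@label))
        msg <- c(msg, sprintf("label '%s' not one of %s or 'node_<i>'",
                              object@label,
                              paste(VALID_MASK_LABELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ModelFit: a fitted prognostic Cox model
#'
#' Result of LASSO selection plus unpenalized refit for one of the three
#' model pools (tumor features, lymph-node features, or their union).
#'
#' @slot modelId one of `"tumor"`, `"LN"`, `"combined"`.
#' @slot features character vector of selected feature names (possibly
#'   empty).
#' @slot coefficients named numeric, refit (unpenalized) log hazard ratios.
#' @slot hrTable data.frame with columns feature, coef, HR, HR_lo, HR_hi,
#'   p_value.
#' @slot cIndex named numeric: internal Harrell's C with its 95% CI
#'   (`c`, `lower`, `upper`).
#' @slot cExternal numeric, external-validation C (NA until validated).
#' @slot aic numeric, Akaike information criterion of the refit.
#' @slot lambda numeric, the penalty chosen by cross-validation.
#' @slot seed integer seed used for fold assignment.
#' @slot fit the underlying `survival::coxph` fit (or NULL for an empty
#'   selection).
#' @slot diagnostics list of proportional-hazards and log-linearity
#'   diagnostics, filled by [checkPHSchoenfeld()] / [checkLogLinearity()].
#' @export
setClass("ModelFit",
    representation(modelId = "character", features = "character",
                   coefficients = "numeric", hrTable = "data.frame",
                   cIndex = "numeric", cExternal = "numeric",
                   aic = "numeric", lambda = "numeric", seed = "integer",
                   fit = "ANY", diagnostics = "list"),
    prototype(cExternal = NA_real_, diagnostics = list())
)

setValidity("ModelFit", function(object) {
    msg <- character()
    if (!object@modelId %in% c("tumor", "LN", "combined"))
        msg <- c(msg, "modelId must be 'tumor', 'LN' or 'combined'")
    if (length(object@features) &&
        !setequal(object@features, names(object@coefficients)))
        msg <- c(msg, "coefficients must be named by the selected features")
    if (length(object@aic) == 1L && !is.na(object@aic) &&
        !is.finite(object@aic))
        msg <- c(msg, "AIC must be finite")
    if (length(msg)) msg else TRUE
})
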