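#' Construct an SUVImage
#'
#' @param values numeric 3D array of SUV values.
#' @param spacing voxel spacing in mm per axis; the default is the
#'   development-cohort PET grid (4.0728 x 4.0728 x 3 mm).
#' @param origin mm position of the first voxel center.
#' @return an [SUVImage-class] object.
#' @examples
#' img <- SUVImage(array(1, c(4, 4, 4)))
#' voxelSpacing(img)
#' @export
SUVImage <- function(values, spacing = c(4.0728, 4.0728, 3),
                     origin = c(0, 0, 0)) {
    new("SUVImage", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct an ROIMask
#'
#' @param indicator logical (or coercible 0/1) 3D array.
#' @param spacing voxel spacing in mm per axis.
#' @param label structure label: `"tumor"`, `"node"`, `"node_<i>"`,
#'   `"LN_merged"`, `"LN_volume"` or `"LN_max"`.
#' @return an [ROIMask-class] object.
#' @export
ROIMask <- function(indicator, spacing = c(4.0728, 4.0728, 3),
                    label = "tumor") {
    if (!is.logical(indicator)) {
        ind <- array(indicator != 0, dim = dim(indicator))
    } else ind <- indicator
    new("ROIMask", indicator = ind, spacing = as.numeric(spacing),
        label = label)
}

#' Accessors for SUVImage
#'
#' `suvValues` returns the raw 3D SUV array, `voxelSpacing` the mm spacing,
#' `imageOrigin` the mm origin.
#'
#' @param x an [SUVImage-class] or [ROIMask-class].
#' @name SUVImage-accessors
NULL

#' @rdname SUVImage-accessors
#' @export
setMethod("suvValues", "SUVImage", function(x) x@values)

#' @rdname SUVImage-accessors
#' @export
setMethod("voxelSpacing", "SUVImage", function(x) x@spacing)

#' @rdname SUVImage-accessors
#' @export
setMethod("voxelSpacing", "ROIMask", function(x) x@spacing)

#' @rdname SUVImage-accessors
#' @export
setMethod("imageOrigin", "SUVImage", function(x) x@origin)

#' Accessors for ROIMask
#'
#' `maskArray` returns the logical indicator array, `maskLabel` the
#' structure label, `voxelCount` the number of ROI voxels, and
#' `maskVolume` the physical volume in cc (mm^3 / 1000).
#'
#' @param x an [ROIMask-class].
#' @param value replacement label.
#' @name ROIMask-accessors
NULL

#' @rdname ROIMask-accessors
#' @export
setMethod("maskArray", "ROIMask", function(x) x@indicator)

#' @rdname ROIMask-accessors
#' @export
setMethod("maskLabel", "ROIMask", function(x) x@label)

#' @rdname ROIMask-accessors
#' @export
setMethod("maskLabel<-", "ROIMask", function(x, value) {
    x@label <- value
    validObject(x)
    x
})

#' @rdname ROIMask-accessors
#' @export
setMethod("voxelCount", "ROIMask", function(x) sum(x@indicator))

#' @rdname ROIMask-accessors
#' @export
setMethod("maskVolume", "ROIMask", function(x)
    sum(x@indicator) * prod(x@spacing) / 1000)

setMethod("show", "SUVImage", function(object) {
    d <- dim(object@values)
    v <- object@values
    cat(sprintf("SUVImage: %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  SUV range: [%.3g, %.3g], mean %.3g\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "ROIMask", function(object) {
    d <- dim(object@indicator)
    cat(sprintf("ROIMask '%s': %d of %d voxels set (%.2f cc)\n",
                object@label, sum(object@indicator), prod(d),
                maskVolume(object)))
})

# shared grid check used by the ROI construction operations
stopIfIncongruent <- function(a, b) {
    if (!identical(dim(maskArray(a)), dim(maskArray(b))) ||
        !isTRUE(all.equal(voxelSpacing(a), voxelSpacing(b))))
        stop("masks are not on congruent grids")
    invisible(TRUE)
}

#' Read / write SUV images and masks as NIfTI
#'
#' Images and masks are stored as standard NIfTI volumes; the voxel spacing
#' is carried in the NIfTI pixdim fields. Masks are written as 0/1 integer
#' volumes and the structure label follows the
#' `<patient>_<label>.nii.gz` filename convention.
#'
#' @param x object to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param label structure label to attach to a mask read from disk; by
#'   default parsed from the filename.
#' @return `readSUVImage` returns an [SUVImage-class]; `readROIMask` an
#'   [ROIMask-class]; the writers return `path` invisibly.
#' @export
writeSUVImage <- function(x, path) {
    stopifnot(is(x, "SUVImage"))
    nii <- RNifti::asNifti(x@values)
    RNifti::pixdim(nii) <- x@spacing
    RNifti::writeNifti(nii, path)
    invisible(path)
}

#' @rdname writeSUVImage
#' @export
readSUVImage <- function(path) {
    nii <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(nii)[1:3]
    SUVImage(array(as.numeric(nii), dim = dim(nii)[1:3]), spacing = sp)
}

#' @rdname writeSUVImage
#' @export
writeROIMask <- function(x, path) {
    stopifnot(is(x, "ROIMask"))
    nii <- RNifti::asNifti(array(as.integer(x@indicator),
                                 dim = dim(x@indicator)))
    RNifti::pixdim(nii) <- x@spacing
    RNifti::writeNifti(nii, path)
    invisible(path)
}

#' @rdname writeSUVImage
#' @export
readROIMask <- function(path, label = NULL) {
    nii <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(nii)[1:3]
    if (is.null(label)) {
        base <- sub("\\.nii(\\.gz)?$", "", basename(path))
        label <- sub("^[^_]*_", "", base)
        if (!nzchar(label) || identical(label, base)) label <- "tumor"
    }
    ROIMask(array(as.numeric(nii), dim = dim(nii)[1:3]) != 0,
            spacing = sp, label = label)
}
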