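#' @rdname SUVImage-accessors
#' @export
setGeneric("suvValues", function(x) standardGeneric("suvValues"))

#' @rdname SUVImage-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname SUVImage-accessors
#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))

#' @rdname ROIMask-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname ROIMask-accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname ROIMask-accessors
#' @export
setGeneric("maskLabel<-", function(x, value) standardGeneric("maskLabel<-"))

#' @rdname ROIMask-accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname ROIMask-accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
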