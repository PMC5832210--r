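#' Nodal structure construction
#'
#' Patients in a node-positive cohort carry one to many metastatic lymph
#' nodes. Three derived nodal structures are used for analysis: the union
#' of all nodes (`LN_merged`, the primary analysis structure), the node of
#' largest physical volume (`LN_volume`), and the node with the highest
#' maximum SUV (`LN_max`). Ties in the two selections are broken by input
#' order (first wins), which keeps the operations deterministic.
#'
#' @param nodes list of [ROIMask-class] objects on congruent grids.
#' @param image the paired [SUVImage-class] (for `selectMostActiveNode`).
#' @return an [ROIMask-class] labeled `LN_merged`, `LN_volume` or
#'   `LN_max`.
#' @examples
#' a <- ROIMask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), label = "node_1")
#' b <- ROIMask(array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2)),
#'              label = "node_2")
#' voxelCount(mergeNodes(list(a, b)))
#' @export
mergeNodes <- function(nodes) {
    if (!is.list(nodes) || length(nodes) == 0L)
        stop("at least one node mask is required")
    for (nd in nodes) stopifnot(is(nd, "ROIMask"))
    if (length(nodes) > 1L)
        for (i in 2:length(nodes)) stopIfIncongruent(nodes[[1L]], nodes[[i]])
    ind <- Reduce(`|`, lapply(nodes, maskArray))
    ROIMask(ind, spacing = voxelSpacing(nodes[[1L]]), label = "LN_merged")
}

#' @rdname mergeNodes
#' @export
selectLargestNode <- function(nodes) {
    if (!is.list(nodes) || length(nodes) == 0L)
        stop("at least one node mask is required")
    vols <- vapply(nodes, maskVolume, numeric(1))
    out <- nodes[[which.max(vols)]]  # which.max: first maximum wins
    maskLabel(out) <- "LN_volume"
    out
}

#' @rdname mergeNodes
#' @export
selectMostActiveNode <- function(nodes, image) {
    if (!is.list(nodes) || length(nodes) == 0L)
        stop("at least one node mask is required")
    stopifnot(is(image, "SUVImage"))
    vals <- suvValues(image)
    peak <- vapply(nodes, function(nd) max(vals[maskArray(nd)]), numeric(1))
    out <- nodes[[which.max(peak)]]
    maskLabel(out) <- "LN_max"
    out
}

#' Tumor load
#'
#' The tumor load is the sum of the primary-tumor volume and the (merged)
#' lymph-node volume, both in cc.
#'
#' @param volumeTumor,volumeLN volumes in cc; both must be non-negative.
#' @return tumor load in cc.
#' @examples
#' tumorLoad(79.5, 35.3)  # 114.8
#' @export
tumorLoad <- function(volumeTumor, volumeLN) {
    if (any(!is.finite(volumeTumor)) || any(!is.finite(volumeLN)) ||
        any(volumeTumor < 0) || any(volumeLN < 0))
        stop("volumes must be finite and non-negative")
    volumeTumor + volumeLN
}
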