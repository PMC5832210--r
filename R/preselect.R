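#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' from the standard two-way ANOVA decomposition. With n subjects and
#' k = 2 measurements,
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}.}
#' Absolute agreement is the stricter of the standard ICC variants and is
#' the usual choice for radiomics feature-robustness studies.
#'
#' @param a,b paired measurements (measurement A and B across subjects).
#' @return ICC value in [-1, 1].
#' @export
icc <- function(a, b) {
    stopifnot(length(a) == length(b))
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 3L) stop("at least 3 complete pairs are required")
    k <- 2
    y <- c(a, b)
    if (stats::var(y) == 0)
        stop("zero total variance; ICC undefined")
    rowMean <- (a + b) / 2
    colMean <- c(mean(a), mean(b))
    grand <- mean(y)
    ssr <- k * sum((rowMean - grand)^2)
    ssc <- n * sum((colMean - grand)^2)
    sst <- sum((y - grand)^2)
    sse <- sst - ssr - ssc
    msr <- ssr / (n - 1)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Bland-Altman limits of agreement on the percent scale
#'
#' Differences are expressed as a percentage of the pair mean,
#' d = 100 (A - B) / ((A + B)/2); the limits are mean(d) +/- 1.96 sd(d).
#'
#' @param a,b paired measurements; no pair mean may be zero.
#' @return numeric `c(lower, upper)` in percent.
#' @export
limitsOfAgreement <- function(a, b) {
    stopifnot(length(a) == length(b), length(a) >= 3L)
    pm <- (a + b) / 2
    if (any(pm == 0)) stop("zero pair mean; percent difference undefined")
    d <- 100 * (a - b) / pm
    m <- mean(d)
    s <- stats::sd(d)
    c(lower = m - 1.96 * s, upper = m + 1.96 * s)
}

#' Robustness filter by ICC across measurement contexts
#'
#' A feature is retained only when its ICC exceeds the cutoff in every
#' provided context (e.g. test-retest AND inter-observer), mirroring the
#' pre-selection that reduced the candidate pool before modeling.
#' Features with zero variance across subjects (ICC undefined) are
#' excluded.
#'
#' @param candidates character vector of feature names.
#' @param contexts named list of contexts; each context is a list of two
#'   aligned data.frames `A` and `B` holding the paired measurements,
#'   with the candidate features as columns.
#' @param iccCutoff retention threshold (default 0.85).
#' @return list with `retained` (character) and `report` (data.frame of
#'   per-feature, per-context ICCs and flags).
#' @export
robustnessFilter <- function(candidates, contexts, iccCutoff = 0.85) {
    stopifnot(is.list(contexts), length(contexts) >= 1L)
    rows <- list()
    keep <- setNames(rep(TRUE, length(candidates)), candidates)
    for (cx in names(contexts)) {
        A <- contexts[[cx]]$A; B <- contexts[[cx]]$B
        if (!all(candidates %in% names(A)) ||
            !all(candidates %in% names(B)))
            stop("candidate feature without measurement pairs in ",
                 "context ", cx)
        for (f in candidates) {
            val <- tryCatch(icc(A[[f]], B[[f]]), error = function(e) NA)
            pass <- !is.na(val) && val > iccCutoff
            keep[f] <- keep[f] && pass
            rows[[length(rows) + 1L]] <-
                data.frame(feature = f, context = cx, icc = val,
                           pass = pass)
        }
    }
    list(retained = names(keep)[keep], report = do.call(rbind, rows))
}

#' Surrogacy filter for merged-node features
#'
#' Features of the merged nodal structure are retained only when they are
#' interchangeable with the same feature measured on a single
#' representative node. Agreement is assessed against the largest node
#' and the most active node by ICC and percent limits of agreement; a
#' feature passes a comparison when ICC > `iccCutoff` AND the whole LoA
#' interval lies within +/-`loaBound` percent.
#'
#' @param featuresMerged,featuresLargest,featuresMostActive aligned
#'   per-patient feature data.frames for the LN_merged, LN_volume and
#'   LN_max structures.
#' @param iccCutoff ICC threshold (default 0.85).
#' @param loaBound LoA containment bound in percent (default 10).
#' @param rule `"both"` (default) requires passing against both
#'   comparators; `"either"` accepts one.
#' @return list with `retained` and `report` as in [robustnessFilter()].
#' @export
surrogateFilter <- function(featuresMerged, featuresLargest,
                            featuresMostActive, iccCutoff = 0.85,
                            loaBound = 10, rule = c("both", "either")) {
    rule <- match.arg(rule)
    if (nrow(featuresMerged) != nrow(featuresLargest) ||
        nrow(featuresMerged) != nrow(featuresMostActive))
        stop("misaligned patients across structures")
    candidates <- intersect(names(featuresMerged),
                            intersect(names(featuresLargest),
                                      names(featuresMostActive)))
    comparators <- list(LN_volume = featuresLargest,
                        LN_max = featuresMostActive)
    rows <- list()
    verdict <- matrix(NA, length(candidates), length(comparators),
                      dimnames = list(candidates, names(comparators)))
    for (cmp in names(comparators)) {
        for (f in candidates) {
            a <- featuresMerged[[f]]; b <- comparators[[cmp]][[f]]
            iv <- tryCatch(icc(a, b), error = function(e) NA)
            loa <- tryCatch(limitsOfAgreement(a, b),
                            error = function(e) c(NA, NA))
            pass <- !is.na(iv) && iv > iccCutoff &&
                all(is.finite(loa)) &&
                loa[1] >= -loaBound && loa[2] <= loaBound
            verdict[f, cmp] <- pass
            rows[[length(rows) + 1L]] <-
                data.frame(feature = f, context = cmp, icc = iv,
                           loa_low = loa[1], loa_high = loa[2],
                           pass = pass)
        }
    }
    keep <- if (rule == "both") apply(verdict, 1, all)
            else apply(verdict, 1, any)
    list(retained = candidates[keep], report = do.call(rbind, rows))
}
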