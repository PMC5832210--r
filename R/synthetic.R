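# Synthetic PET phantoms, replicate segmentations and survival outcomes.
#
# The generator emulates the study conditions the downstream stages need:
# heterogeneous tumor and 1-5 lymph-node SUV blobs on the development
# PET grid (4.0728 x 4.0728 x 3 mm voxels), replicate segmentations for
# the robustness (ICC) stage, and right-censored Weibull survival whose
# log-hazard is linear in chosen ground-truth features.

# deterministic per-patient seed derived from (master seed, index), kept
# below 2^31 so generation order never matters
.deriveSeed <- function(seed, index) {
    m <- 2147483629
    as.integer((as.double(seed %% m) * 48271 + as.double(index) * 16807 +
                1) %% m)
}

#' Specification of one synthetic PET phantom
#'
#' @param gridShape voxels per axis.
#' @param spacing mm per axis; default is the development-cohort PET grid.
#' @param nNodes number of metastatic lymph-node blobs (1-5; the cohort
#'   is node-positive, so at least one).
#' @param tumorSUVMean,nodeSUVMean mean SUV of the blobs (cohort-scale
#'   defaults: tumor mean SUV 4.4, node mean SUV 3.5).
#' @param backgroundSUV background tissue SUV.
#' @param textureScale correlation length (voxels) of the multiplicative
#'   lognormal noise field.
#' @param noiseSigma log-scale standard deviation of the noise field; 0
#'   gives noiseless blobs.
#' @param tumorRadius,nodeRadius mean blob radii in mm (volumes on the
#'   scale of the cohort's 79.5 cc tumors and ~10 cc nodes).
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @return a `PhantomSpec` (validated list).
#' @export
phantomSpec <- function(gridShape = c(48, 48, 36),
                        spacing = c(4.0728, 4.0728, 3),
                        nNodes = 3,
                        tumorSUVMean = 4.4, nodeSUVMean = 3.5,
                        backgroundSUV = 0.7,
                        textureScale = 1.5, noiseSigma = 0.35,
                        tumorRadius = 24, nodeRadius = 12,
                        seed = 1L) {
    spec <- list(gridShape = as.integer(gridShape),
                 spacing = as.numeric(spacing), nNodes = as.integer(nNodes),
                 tumorSUVMean = tumorSUVMean, nodeSUVMean = nodeSUVMean,
                 backgroundSUV = backgroundSUV, textureScale = textureScale,
                 noiseSigma = noiseSigma, tumorRadius = tumorRadius,
                 nodeRadius = nodeRadius, seed = as.integer(seed))
    stopifnot(length(spec$gridShape) == 3L, all(spec$gridShape >= 8L),
              all(spec$spacing > 0), spec$nNodes >= 1L, spec$nNodes <= 5L,
              spec$tumorSUVMean > 0, spec$nodeSUVMean > 0,
              spec$backgroundSUV > 0, spec$noiseSigma >= 0,
              spec$textureScale >= 0)
    class(spec) <- "PhantomSpec"
    spec
}

# correlated standard-normal field via FFT convolution of white noise
# with a (periodic) Gaussian kernel, re-standardized to unit variance
.correlatedField <- function(dims, scale) {
    z <- array(stats::rnorm(prod(dims)), dims)
    if (scale <= 0) return(z)
    ax <- lapply(dims, function(n) {
        d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
        exp(-d^2 / (2 * scale^2))
    })
    k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
    sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
        prod(dims)
    (sm - mean(sm)) / stats::sd(sm)
}

# voxel-center membership of an axis-aligned ellipsoid (center and
# semi-axes in voxel units of each axis)
.ellipsoidMask <- function(dims, center, semi) {
    x <- ((1:dims[1]) - center[1]) / semi[1]
    y <- ((1:dims[2]) - center[2]) / semi[2]
    z <- ((1:dims[3]) - center[3]) / semi[3]
    outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Simulate one patient's PET image and structures
#'
#' Places one tumor and `nNodes` lymph-node blobs as randomized ellipsoids
#' (semi-axis ratio at most 2) that neither touch the grid boundary nor
#' each other, and modulates every blob's mean SUV by a correlated
#' multiplicative lognormal texture field (mean 1), so SUV stays strictly
#' positive and heterogeneity is tunable.
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` ([SUVImage-class]), `tumor` ([ROIMask-class])
#'   and `nodes` (list of [ROIMask-class], labels `node_1` ...), pairwise
#'   disjoint.
#' @export
simulatePatientImages <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    set.seed(spec$seed)
    dims <- spec$gridShape
    sp <- spec$spacing
    radiiMM <- c(spec$tumorRadius,
                 rep(spec$nodeRadius, spec$nNodes)) *
        exp(stats::rnorm(spec$nNodes + 1, 0, 0.25))
    placed <- list()
    for (b in seq_along(radiiMM)) {
        ok <- FALSE
        for (try in 1:200) {
            ax <- stats::runif(3, 0.7, 1.4)       # axis ratio <= 2
            semiMM <- radiiMM[b] * ax
            semiVox <- pmax(semiMM / sp, 1.1)
            lo <- semiVox + 2; hi <- dims - semiVox - 1
            if (any(hi <= lo)) next
            ctr <- stats::runif(3, lo, hi)
            clash <- FALSE
            for (p in placed) {
                gap <- sqrt(sum(((ctr - p$ctr) * sp)^2))
                if (gap < (max(semiMM) + max(p$semiMM) + 2 * max(sp))) {
                    clash <- TRUE; break
                }
            }
            if (clash) next
            m <- .ellipsoidMask(dims, ctr, semiVox)
            if (!any(m)) next
            placed[[b]] <- list(ctr = ctr, semiMM = semiMM, mask = m)
            ok <- TRUE
            break
        }
        if (!ok)
            stop("blob placement failed after bounded retries; ",
                 "enlarge the grid or shrink the blobs")
    }
    field <- exp(-spec$noiseSigma^2 / 2 + spec$noiseSigma *
                 .correlatedField(dims, spec$textureScale))
    vals <- array(spec$backgroundSUV, dims)
    means <- c(spec$tumorSUVMean, rep(spec$nodeSUVMean, spec$nNodes))
    for (b in seq_along(placed)) vals[placed[[b]]$mask] <- means[b]
    vals <- vals * field
    img <- SUVImage(vals, spacing = sp)
    tumor <- ROIMask(placed[[1]]$mask, spacing = sp, label = "tumor")
    nodes <- lapply(seq_len(spec$nNodes), function(i)
        ROIMask(placed[[i + 1]]$mask, spacing = sp,
                label = sprintf("node_%d", i)))
    list(image = img, tumor = tumor, nodes = nodes)
}

# one full-depth 6-connectivity erosion of a logical array
.erode6 <- function(ind) {
    dm <- dim(ind)
    out <- ind
    for (ax in 1:3) for (s in c(-1L, 1L)) {
        shifted <- array(FALSE, dm)
        src <- lapply(dm, seq_len); dst <- src
        n <- dm[ax]
        if (s == 1L) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
        else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
        shifted[dst[[1]], dst[[2]], dst[[3]]] <-
            ind[src[[1]], src[[2]], src[[3]]]
        out <- out & shifted
    }
    out
}

#' Randomly perturb a segmentation
#'
#' Emulates test-retest / inter-observer delineation variability by
#' `magnitude` rounds of random boundary editing: each round adds every
#' outside face-neighbor voxel with probability 0.2 and removes every
#' inner boundary voxel with probability 0.2. `magnitude = 0` returns the
#' mask unchanged. A perturbation whose erosion depth could empty the
#' mask (i.e. `magnitude` full erosions leave nothing) is refused.
#'
#' @param mask a non-empty [ROIMask-class].
#' @param magnitude non-negative integer number of boundary-editing
#'   rounds.
#' @param seed RNG seed.
#' @return a perturbed [ROIMask-class] with the same label.
#' @export
perturbSegmentation <- function(mask, magnitude, seed = 1L) {
    stopifnot(is(mask, "ROIMask"), magnitude >= 0)
    ind <- maskArray(mask)
    if (!any(ind)) stop("mask is empty")
    if (magnitude == 0) return(mask)
    probe <- ind
    for (i in seq_len(magnitude)) probe <- .erode6(probe)
    if (!any(probe))
        stop("perturbation of this magnitude would empty the mask")
    set.seed(seed)
    dm <- dim(ind)
    for (i in seq_len(magnitude)) {
        dil <- ind
        for (ax in 1:3) for (s in c(-1L, 1L)) {
            shifted <- array(FALSE, dm)
            src <- lapply(dm, seq_len); dst <- src
            n <- dm[ax]
            if (s == 1L) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
            else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
            shifted[dst[[1]], dst[[2]], dst[[3]]] <-
                ind[src[[1]], src[[2]], src[[3]]]
            dil <- dil | shifted
        }
        outer_b <- which(dil & !ind)
        inner_b <- which(ind & !.erode6(ind))
        add <- outer_b[stats::runif(length(outer_b)) < 0.2]
        rem <- inner_b[stats::runif(length(inner_b)) < 0.2]
        ind[add] <- TRUE
        ind[rem] <- FALSE
        if (!any(ind)) stop("perturbation emptied the mask")
    }
    ROIMask(ind, spacing = voxelSpacing(mask), label = maskLabel(mask))
}

#' Specification of the synthetic survival model
#'
#' @param betas named numeric: log-hazard coefficient per standard
#'   deviation of each ground-truth feature.
#' @param baselineShape,baselineScale Weibull baseline parameters
#'   (months; defaults give a median survival on the scale of a
#'   locally-advanced NSCLC cohort, about 20 months).
#' @param censoringRate target fraction right-censored, in [0, 1).
#' @param seed RNG seed.
#' @return a `SurvivalSpec` (validated list).
#' @export
survivalSpec <- function(betas = numeric(0), baselineShape = 1.2,
                         baselineScale = 24, censoringRate = 0.3,
                         seed = 1L) {
    stopifnot(censoringRate >= 0, censoringRate < 1, baselineShape > 0,
              baselineScale > 0)
    structure(list(betas = betas, baselineShape = baselineShape,
                   baselineScale = baselineScale,
                   censoringRate = censoringRate, seed = as.integer(seed)),
              class = "SurvivalSpec")
}

#' Simulate right-censored survival outcomes
#'
#' Draws Weibull proportional-hazards event times whose linear predictor
#' is the sum of z-scored ground-truth features weighted by `betas`, and
#' applies independent administrative censoring: a uniform cutoff whose
#' upper limit is calibrated so the expected censored fraction matches
#' the target.
#'
#' @param features data.frame of per-patient ground-truth feature values;
#'   must contain every name in `spec$betas` and be finite.
#' @param spec a [survivalSpec()].
#' @return data.frame with columns `time` (months) and `event` (1 =
#'   death observed, 0 = right-censored), plus attribute `lp` holding the
#'   true linear predictor.
#' @export
simulateSurvival <- function(features, spec) {
    stopifnot(inherits(spec, "SurvivalSpec"), is.data.frame(features),
              nrow(features) >= 2L)
    bn <- names(spec$betas)
    if (!all(bn %in% names(features)))
        stop("betas name features absent from the feature table: ",
             paste(setdiff(bn, names(features)), collapse = ", "))
    n <- nrow(features)
    lp <- rep(0, n)
    for (nm in bn) {
        x <- features[[nm]]
        if (any(!is.finite(x))) stop("non-finite feature values in ", nm)
        s <- stats::sd(x)
        z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
        lp <- lp + spec$betas[[nm]] * z
    }
    set.seed(spec$seed)
    u <- stats::runif(n)
    tt <- spec$baselineScale * (-log(u) / exp(lp))^(1 / spec$baselineShape)
    if (spec$censoringRate == 0) {
        out <- data.frame(time = tt, event = 1L)
    } else {
        f <- function(cmax) mean(pmin(tt / cmax, 1)) - spec$censoringRate
        cmax <- stats::uniroot(f, lower = min(tt) * 1e-6,
                               upper = max(tt) * 1e6, tol = 1e-10)$root
        cens <- stats::runif(n, 0, cmax)
        out <- data.frame(time = pmin(tt, cens),
                          event = as.integer(tt <= cens))
    }
    attr(out, "lp") <- lp
    out
}

#' Simulate a whole imaging cohort
#'
#' Generates `nPatients` phantoms with 1-5 nodes each (node count drawn
#' uniformly), using an independent per-patient RNG stream derived from
#' the master seed so results do not depend on generation order.
#' Between-patient heterogeneity is essential for agreement statistics
#' downstream, so each patient draws individual mean SUVs from lognormal
#' distributions on the cohort scale of a locally-advanced NSCLC
#' population (tumor mean SUV about 4.4 +/- 2.3, nodal mean SUV about
#' 3.5 +/- 1.9); all nodes of one patient share that patient's nodal
#' uptake level.
#'
#' @param nPatients number of patients.
#' @param seed master seed.
#' @param baseSpec a [phantomSpec()] used as a template (its `nNodes`,
#'   SUV means and `seed` are overridden per patient).
#' @param suvSpread lognormal log-scale SD of the per-patient tumor and
#'   node mean SUVs (length 2); `c(0, 0)` disables the cohort spread.
#' @return list of per-patient lists as from [simulatePatientImages()].
#' @export
simulateCohortImages <- function(nPatients, seed = 1L,
                                 baseSpec = phantomSpec(),
                                 suvSpread = c(0.50, 0.51)) {
    lapply(seq_len(nPatients), function(i) {
        ps <- .deriveSeed(seed, i)
        set.seed(ps)
        nn <- sample(1:5, 1)
        spec <- baseSpec
        spec$nNodes <- nn
        spec$tumorSUVMean <- stats::rlnorm(1,
            log(baseSpec$tumorSUVMean) - suvSpread[1]^2 / 2, suvSpread[1])
        spec$nodeSUVMean <- stats::rlnorm(1,
            log(baseSpec$nodeSUVMean) - suvSpread[2]^2 / 2, suvSpread[2])
        spec$seed <- .deriveSeed(ps, 1L)
        simulatePatientImages(spec)
    })
}
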