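test_that("first-order features match hand arithmetic and degenerate limits", {
    fx <- smallFixture(c(1, 2, 3, 4, 9, 9, 9, 9),
                       ind = array(c(rep(TRUE, 4), rep(FALSE, 4)),
                                   c(2, 2, 2)))
    f <- firstOrderFeatures(fx$image, fx$mask)
    expect_equal(unname(f["stats_mean"]), 2.5)
    expect_equal(unname(f["stats_range"]), 3)
    expect_equal(unname(f["stats_rms"]), sqrt(7.5))
    expect_equal(unname(f["stats_median"]), 2.5)
    expect_equal(unname(f["stats_skewness"]), 0)  # symmetric values
    # constant ROI limits
    fc <- smallFixture(rep(4.2, 8))
    g <- firstOrderFeatures(fc$image, fc$mask)
    expect_equal(unname(g[c("stats_variance", "stats_entropy",
                            "stats_cov")]), c(0, 0, 0))
    expect_equal(unname(g["stats_uniformity"]), 1)
    expect_equal(unname(g["stats_suv_peak"]), 4.2)
    # mean/max equal direct reductions on a phantom ROI
    sim <- simulatePatientImages(phantomSpec(seed = 2, nNodes = 1,
                                             gridShape = c(24, 24, 18),
                                             tumorRadius = 12, nodeRadius = 7))
    v <- suvValues(sim$image)[maskArray(sim$tumor)]
    ph <- firstOrderFeatures(sim$image, sim$tumor)
    expect_equal(unname(ph["stats_mean"]), mean(v))
    expect_equal(unname(ph["stats_maximum"]), max(v))
    expect_lte(ph["stats_suv_peak"], ph["stats_maximum"])
})

test_that("shape features: voxel volume, ball sphericity, cube diameter", {
    single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
    s1 <- shapeFeatures(ROIMask(single, spacing = c(4.0728, 4.0728, 3)))
    expect_equal(unname(s1["shape_volume_cc"]) * 1000,
                 4.0728 * 4.0728 * 3, tolerance = 1e-12)
    # digital ball approaches unit sphericity
    r <- 10; n <- 2 * r + 5; x <- (1:n) - (n + 1) / 2
    ball <- outer(outer(x^2, x^2, `+`), x^2, `+`) <= r^2
    sb <- shapeFeatures(ROIMask(ball, spacing = c(1, 1, 1)))
    expect_lt(abs(sb["shape_sphericity"] - 1), 0.05)
    expect_lt(abs(sb["shape_surface_mm2"] / (4 * pi * r^2) - 1), 0.05)
    expect_equal(unname(sb["shape_max_diameter_3d"]), 2 * r,
                 tolerance = 0.1)
    expect_equal(unname(sb["shape_elongation"]), 1, tolerance = 0.05)
    # cube of side a: space diagonal a*sqrt(3) between voxel centers
    cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
    sc <- shapeFeatures(ROIMask(cube, spacing = c(2, 2, 2)))
    expect_equal(unname(sc["shape_max_diameter_3d"]), 8 * sqrt(3),
                 tolerance = 1e-10)
    expect_equal(unname(sc["shape_max_diameter_axial"]), 8 * sqrt(2),
                 tolerance = 1e-10)
    # translation invariance on the grid
    cube2 <- array(FALSE, c(9, 9, 9)); cube2[2:6, 2:6, 3:7] <- TRUE
    s2 <- shapeFeatures(ROIMask(cube2, spacing = c(2, 2, 2)))
    expect_equal(sc, s2)
})

test_that("IVH features honor boundary, monotonicity and AUC conventions", {
    fx <- smallFixture(c(1, 2, 3, 4, 5, 6, 7, 8))
    f <- ivhFeatures(fx$image, fx$mask)
    # the threshold at the ROI minimum keeps the whole volume
    expect_equal(unname(f["ivh_vf_suv1"]), 1)
    # Vx and Ix are non-increasing in x
    vx <- f[sprintf("ivh_v%d", seq(10, 90, 10))]
    ix <- f[sprintf("ivh_i%d", seq(10, 90, 10))]
    expect_true(all(diff(vx) <= 0))
    expect_true(all(diff(ix) <= 0))
    expect_gte(f["ivh_i10"], f["ivh_i90"])
    # hand check: V50 = fraction of voxels >= 1 + 0.5*7 = 4.5 -> 4/8
    expect_equal(unname(f["ivh_v50"]), 0.5)
    # absolute volumes scale with the voxel volume
    expect_equal(unname(f["ivh_av_suv1"]),
                 8 * 1 / 1000)
    # constant ROI: AUC = 1 by the step-function convention
    fc <- smallFixture(rep(2.5, 8))
    expect_equal(unname(ivhFeatures(fc$image, fc$mask)["ivh_auc"]), 1)
})

test_that("texture features match hand evaluations and definitional bounds", {
    # SRE of runs {(g1,len2):1, (g2,len1):1} = (1/4 + 1)/2
    R <- matrix(0, 2, 2); R[1, 2] <- 1; R[2, 1] <- 1
    expect_equal(unname(glrlmFeatures(R, nVoxels = 3)["glrlm_sre"]),
                 0.625)
    # all runs of length 1: SRE attains its upper bound 1
    R1 <- matrix(c(2, 3), 2, 1)
    expect_equal(unname(glrlmFeatures(R1, nVoxels = 5)["glrlm_sre"]), 1)
    expect_equal(unname(glrlmFeatures(R1, nVoxels = 5)["glrlm_rp"]), 1)
    # single grey level GLCM: entropy 0, max probability 1, fallbacks
    P1 <- matrix(1, 1, 1)
    g1 <- glcmFeatures(P1)
    expect_equal(unname(g1["glcm_entropy"]), 0)
    expect_equal(unname(g1["glcm_max_probability"]), 1)
    expect_equal(unname(g1["glcm_correlation"]), 0)
    expect_equal(unname(g1["glcm_imc1"]), 0)
    # all features finite on a phantom-derived matrix
    sim <- simulatePatientImages(phantomSpec(seed = 23, nNodes = 1,
                                             gridShape = c(24, 24, 18),
                                             tumorRadius = 12, nodeRadius = 7))
    d <- discretize(sim$image, sim$tumor)
    expect_true(all(is.finite(glcmFeatures(computeGLCM(d)))))
    expect_true(all(is.finite(glrlmFeatures(computeGLRLM(d),
                                            sum(d$mask)))))
    expect_true(all(is.finite(glszmFeatures(computeGLSZM(d),
                                            sum(d$mask)))))
})

test_that("extractAll returns the deterministic 118-feature vector", {
    sim <- simulatePatientImages(phantomSpec(seed = 4, nNodes = 2,
                                             gridShape = c(32, 32, 24),
                                             tumorRadius = 16, nodeRadius = 9))
    fv <- extractAll(sim$image, sim$tumor)
    expect_length(fv, 118L)
    expect_true(all(is.finite(fv)))
    fam <- table(featureFamilies(names(fv)))
    expect_equal(unname(fam[c("first_order", "shape", "ivh", "glcm",
                              "glrlm", "glszm")]),
                 c(16L, 13L, 45L, 22L, 11L, 11L), ignore_attr = TRUE)
    # determinism
    expect_identical(fv, extractAll(sim$image, sim$tumor))
    # merged nodes work the same way
    fv2 <- extractAll(sim$image, mergeNodes(sim$nodes))
    expect_length(fv2, 118L)
})
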