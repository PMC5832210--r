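test_that("concordance index equals the all-pairs oracle and handles ties", {
    set.seed(31)
    for (rep in 1:5) {
        n <- sample(10:30, 1)
        time <- round(rexp(n, 0.1), 1)       # induces some tied times
        event <- rbinom(n, 1, 0.7)
        risk <- sample(round(rnorm(n), 1))   # some tied risks
        if (sum(event) == 0) event[1] <- 1
        got <- concordanceIndex(risk, time, event)
        expect_equal(unname(got["c"]), bruteForceC(risk, time, event),
                     tolerance = 1e-12)
    }
    # perfect ranking: highest risk fails first
    tm <- c(1, 2, 3, 4, 5)
    expect_equal(unname(concordanceIndex(5:1, tm, rep(1, 5))["c"]), 1)
    # all risks tied: exactly 0.5
    expect_equal(unname(concordanceIndex(rep(2, 5), tm, rep(1, 5))["c"]),
                 0.5)
    expect_error(concordanceIndex(1:3, c(1, 1, 1), c(0, 0, 0)),
                 "comparable")
})

test_that("concordance CI is consistent with the survival package estimate", {
    set.seed(41)
    f <- data.frame(x = rnorm(300))
    sv <- simulateSurvival(f, survivalSpec(betas = c(x = 0.5),
                                           censoringRate = 0.3, seed = 42))
    got <- concordanceIndex(f$x, sv$time, sv$event)
    ref <- survival::concordance(survival::Surv(time, event) ~ x,
                                 data = cbind(f, sv), reverse = TRUE)
    expect_equal(unname(got["c"]), unname(ref$concordance),
                 tolerance = 1e-8)
    # same order of magnitude for the standard error
    seGot <- (got["upper"] - got["lower"]) / (2 * 1.96)
    expect_lt(abs(seGot - sqrt(ref$var)) / sqrt(ref$var), 0.25)
})

test_that("univariable Cox recovers a planted hazard ratio", {
    set.seed(51)
    x <- rnorm(2000)
    sv <- simulateSurvival(data.frame(x = x),
                           survivalSpec(betas = c(x = log(1.5)),
                                        censoringRate = 0.3, seed = 52))
    u <- univariableCox(x, sv$time, sv$event)
    expect_gt(u$HR, 1.35); expect_lt(u$HR, 1.65)
    expect_lt(u$p, 0.001)
    expect_gt(u$c, 0.55)
    # null feature: HR near 1, C near 0.5
    z <- rnorm(1000)
    sv0 <- simulateSurvival(data.frame(x = rnorm(1000)),
                            survivalSpec(betas = c(x = 0),
                                         censoringRate = 0.3, seed = 53))
    u0 <- univariableCox(z, sv0$time, sv0$event)
    expect_lt(abs(u0$HR - 1), 0.15)
    expect_lt(abs(u0$c - 0.5), 0.03)
    expect_error(univariableCox(rep(1, 100), sv0$time[1:100],
                                sv0$event[1:100]), "constant")
})

test_that("per-unit HR transforms as HR^(1/c) under feature rescaling", {
    set.seed(61)
    x <- rnorm(400)
    sv <- simulateSurvival(data.frame(x = x),
                           survivalSpec(betas = c(x = 0.4),
                                        censoringRate = 0.2, seed = 62))
    h1 <- univariableCox(x, sv$time, sv$event)$HR
    h3 <- univariableCox(3 * x, sv$time, sv$event)$HR
    expect_equal(h3, h1^(1 / 3), tolerance = 1e-6)
})

test_that("Pearson correlation matrix honors its contracts", {
    set.seed(71)
    x <- rnorm(2000)
    M <- pearsonCorrelationMatrix(data.frame(a = x, b = 2 * x,
                                             c = rnorm(2000)))
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, 3))
    expect_equal(M["a", "b"], 1)
    expect_lt(abs(M["a", "c"]), 0.1)
    expect_error(pearsonCorrelationMatrix(data.frame(a = x,
                                                     z = rep(1, 2000))),
                 "zero-variance")
})

test_that("LASSO-Cox selects a planted signal and shrinks pure noise", {
    set.seed(81)
    n <- 260
    X <- as.data.frame(matrix(rnorm(n * 11), n,
                              dimnames = list(NULL, paste0("f", 1:11))))
    sv <- simulateSurvival(X, survivalSpec(betas = c(f1 = log(2)),
                                           censoringRate = 0.4, seed = 82))
    sel <- lassoCoxCV(X, sv$time, sv$event, seed = 83)
    expect_true("f1" %in% sel$selected)
    # the full-shrinkage end of the path has no nonzero coefficients
    path0 <- as.numeric(stats::coef(sel$cvFit$glmnet.fit,
                                    s = max(sel$cvFit$lambda)))
    expect_true(all(path0 == 0))
    # reproducibility under the same seed
    sel2 <- lassoCoxCV(X, sv$time, sv$event, seed = 83)
    expect_identical(sel$selected, sel2$selected)
    expect_equal(sel$lambda, sel2$lambda)
    # duplicated columns never enter with opposite signs
    X2 <- X; X2$dup <- X2$f1
    sel3 <- lassoCoxCV(X2, sv$time, sv$event, seed = 84)
    both <- intersect(c("f1", "dup"), sel3$selected)
    if (length(both) == 2)
        expect_gte(prod(sel3$coefficients[both]), 0)
})

test_that("refit on a single feature equals the univariable fit", {
    set.seed(91)
    x <- rnorm(300)
    sv <- simulateSurvival(data.frame(x = x),
                           survivalSpec(betas = c(x = 0.5),
                                        censoringRate = 0.3, seed = 92))
    mf <- refitCox(data.frame(x = x), sv$time, sv$event, "x",
                   modelId = "tumor")
    u <- univariableCox(x, sv$time, sv$event)
    expect_equal(mf@hrTable$HR, u$HR, tolerance = 1e-8)
    expect_equal(unname(mf@cIndex["c"]), u$c, tolerance = 1e-8)
    expect_error(refitCox(data.frame(x = x), sv$time, sv$event,
                          character(0)), "empty")
    # stored AIC matches the definition
    expect_equal(mf@aic, 2 * 1 - 2 * mf@fit$loglik[2])
})

test_that("AIC formula and ordering utilities behave", {
    expect_equal(aic(0, 2), 4)
    expect_lt(aic(-10, 1), aic(-10, 3))  # fewer parameters preferred
    f1 <- new("ModelFit", modelId = "tumor", features = "a",
              coefficients = c(a = 1), aic = 100)
    f2 <- new("ModelFit", modelId = "LN", features = "a",
              coefficients = c(a = 1), aic = 90)
    ord <- aicOrder(list(tumor = f1, LN = f2))
    expect_identical(ord$model, c("LN", "tumor"))
})

test_that("penalized-spline diagnostic flags curvature and recommends log", {
    set.seed(101)
    hits <- c(linear = 0, nonlinear = 0, reclog = 0)
    for (r in 1:8) {
        n <- 500
        xl <- rnorm(n)
        svl <- simulateSurvival(data.frame(x = xl),
                                survivalSpec(betas = c(x = 0.5),
                                             censoringRate = 0.2,
                                             seed = 200 + r))
        if (checkLogLinearity(xl, svl$time, svl$event)$verdict ==
            "log-linear") hits["linear"] <- hits["linear"] + 1
        # effect linear in log(volume), tested on the raw scale
        vol <- exp(rnorm(n, 2, 1))
        dfv <- data.frame(lv = log(vol))
        svv <- simulateSurvival(dfv,
                                survivalSpec(betas = c(lv = 0.8),
                                             censoringRate = 0.2,
                                             seed = 300 + r))
        res <- checkLogLinearity(vol, svv$time, svv$event)
        if (res$verdict == "non-linear") {
            hits["nonlinear"] <- hits["nonlinear"] + 1
            if (res$recommendLog) hits["reclog"] <- hits["reclog"] + 1
        }
    }
    expect_gte(hits[["linear"]], 6)
    expect_gte(hits[["nonlinear"]], 6)
    expect_gte(hits[["reclog"]], 5)
})

test_that("Schoenfeld test passes proportional hazards and flags reversal", {
    set.seed(111)
    flags <- c(ph = 0, tv = 0)
    for (r in 1:8) {
        n <- 400
        x <- rnorm(n)
        sv <- simulateSurvival(data.frame(x = x),
                               survivalSpec(betas = c(x = 0.5),
                                            censoringRate = 0.2,
                                            seed = 400 + r))
        mf <- refitCox(data.frame(x = x), sv$time, sv$event, "x")
        ph <- checkPHSchoenfeld(mf)
        if (ph$table$p[ph$table$feature == "x"] > 0.05)
            flags["ph"] <- flags["ph"] + 1
        expect_true(all(c("logTime", "x") %in% names(ph$residuals)))
        # time-varying effect: hazard direction reverses at median time
        u <- runif(n)
        t1 <- -log(u) / (0.05 * exp(1.2 * x))
        tmed <- median(t1)
        t2 <- ifelse(t1 <= tmed, t1,
                     tmed - log(runif(n)) / (0.05 * exp(-1.2 * x)))
        mf2 <- refitCox(data.frame(x = x), t2, rep(1, n), "x")
        ph2 <- checkPHSchoenfeld(mf2)
        if (ph2$table$p[ph2$table$feature == "x"] < 0.05)
            flags["tv"] <- flags["tv"] + 1
    }
    expect_gte(flags[["ph"]], 6)
    expect_gte(flags[["tv"]], 6)
})

test_that("external validation freezes coefficients and detects null transfer", {
    set.seed(121)
    n <- 300
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    sv <- simulateSurvival(X, survivalSpec(betas = c(a = 0.6, b = -0.4),
                                           censoringRate = 0.3,
                                           seed = 122))
    mf <- refitCox(X, sv$time, sv$event, c("a", "b"))
    # validating on the development cohort reproduces the internal C
    ext <- externalValidate(mf, X, sv$time, sv$event)
    expect_equal(unname(ext["c"]), unname(mf@cIndex["c"]),
                 tolerance = 1e-8)
    # permuted outcome: no transferable discrimination
    perm <- sample(n)
    ext0 <- externalValidate(mf, X, sv$time[perm], sv$event[perm])
    expect_lt(abs(ext0["c"] - 0.5), 0.05)
    expect_error(externalValidate(mf, X["a"], sv$time, sv$event),
                 "lacks")
})
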