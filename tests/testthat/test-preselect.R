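test_that("ICC(2,1) matches the explicit ANOVA mean-squares oracle", {
    # duplicated data with between-subject variance: perfect agreement
    a <- c(1, 2, 3, 4.5)
    expect_equal(icc(a, a), 1, tolerance = 1e-12)
    # hand ANOVA oracle for pairs (1,1),(2,2),(3,3),(4,5)
    x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
    n <- 4; k <- 2
    yy <- c(x, y); grand <- mean(yy)
    msr <- k * sum(((x + y) / 2 - grand)^2) / (n - 1)
    msc <- n * sum((c(mean(x), mean(y)) - grand)^2) / (k - 1)
    mse <- (sum((yy - grand)^2) - k * sum(((x + y) / 2 - grand)^2) -
            n * sum((c(mean(x), mean(y)) - grand)^2)) / ((n - 1) * (k - 1))
    oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    got <- icc(x, y)
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_gt(got, 0.9); expect_lt(got, 1)
    # independent noise: ICC near zero
    set.seed(101)
    expect_lt(abs(icc(rnorm(200), rnorm(200))), 0.15)
    # error contracts
    expect_error(icc(c(1, 2), c(1, 2)), "3")
    expect_error(icc(rep(1, 5), rep(1, 5)), "variance")
})

test_that("limits of agreement reproduce hand-computed intervals", {
    a <- c(10, 20, 30)
    expect_equal(unname(limitsOfAgreement(a, a)), c(0, 0))
    # constant 5% relative difference: zero spread
    b <- a * (1 - 0.05 / 1.025)   # makes d exactly ~5% of pair mean
    d <- 100 * (a - b) / ((a + b) / 2)
    loa <- limitsOfAgreement(a, b)
    expect_equal(unname(loa), c(mean(d), mean(d)), tolerance = 1e-9)
    # d = {-2, 0, 2}%: 0 +/- 1.96*sd
    a2 <- c(100 * (1 - 0.01) / (1 + 0.01), 100, 100 * (1 + 0.01) / (1 - 0.01))
    b2 <- c(100, 100, 100)
    d2 <- 100 * (a2 - b2) / ((a2 + b2) / 2)
    expect_equal(d2, c(-2, 0, 2), tolerance = 1e-12)
    expect_equal(unname(limitsOfAgreement(a2, b2)),
                 c(-1.96 * sd(d2), 1.96 * sd(d2)), tolerance = 1e-9)
    # swapping sides mirrors the interval
    set.seed(7); p <- runif(10, 50, 60); q <- p + rnorm(10)
    l1 <- limitsOfAgreement(p, q); l2 <- limitsOfAgreement(q, p)
    expect_equal(unname(l1["upper"] - l1["lower"]),
                 unname(l2["upper"] - l2["lower"]), tolerance = 1e-9)
    expect_error(limitsOfAgreement(c(1, -1, 2), c(-1, 1, 2)), "zero")
})

test_that("robustness filter applies the conjunctive ICC rule", {
    set.seed(5)
    base <- data.frame(good = rnorm(30, 10, 3), bad = rnorm(30, 10, 3))
    ctx <- list(
        test_retest = list(A = base,
                           B = base + data.frame(good = rnorm(30, 0, 0.1),
                                                 bad = rnorm(30, 0, 0.1))),
        inter_observer = list(A = base,
                              B = data.frame(good = base$good +
                                                 rnorm(30, 0, 0.1),
                                             bad = rnorm(30, 10, 3))))
    out <- robustnessFilter(c("good", "bad"), ctx, iccCutoff = 0.85)
    expect_identical(out$retained, "good")
    rep_bad <- out$report[out$report$feature == "bad", ]
    expect_true(any(!rep_bad$pass))
    # vacuous candidate list
    expect_length(robustnessFilter(character(0), ctx)$retained, 0)
    # missing pairs is an error
    expect_error(robustnessFilter("missing", ctx), "without measurement")
})

test_that("raising the ICC cutoff never enlarges the retained set", {
    set.seed(11)
    nm <- paste0("f", 1:8)
    base <- as.data.frame(setNames(lapply(nm, function(i)
        rnorm(25, 10, 2)), nm))
    noise <- as.data.frame(setNames(lapply(seq_along(nm), function(i)
        rnorm(25, 0, 0.05 * i^2)), nm))
    ctx <- list(retest = list(A = base, B = base + noise))
    prev <- nm
    for (cut in c(0.5, 0.7, 0.85, 0.95, 0.99)) {
        cur <- robustnessFilter(nm, ctx, iccCutoff = cut)$retained
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("surrogate filter demands ICC and LoA against both comparators", {
    set.seed(3)
    n <- 40
    core <- rnorm(n, 20, 5)
    merged <- data.frame(perfect = core,
                         biased = core,
                         noisy = core)
    largest <- data.frame(perfect = core,
                          biased = core * 1.25,   # ICC ok-ish, LoA far out
                          noisy = rnorm(n, 20, 5))
    mostact <- data.frame(perfect = core,
                          biased = core * 1.25,
                          noisy = core)
    out <- surrogateFilter(merged, largest, mostact)
    expect_identical(out$retained, "perfect")
    # 'noisy' passes against LN_max but fails LN_volume: conjunction drops it
    expect_true("noisy" %in%
        out$report$feature[out$report$context == "LN_volume" &
                           !out$report$pass])
    # the disjunctive variant accepts it
    out2 <- surrogateFilter(merged, largest, mostact, rule = "either")
    expect_true(all(c("perfect", "noisy") %in% out2$retained))
    expect_false("biased" %in% out2$retained)
    expect_error(surrogateFilter(merged, largest[1:10, ], mostact),
                 "misaligned")
})
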