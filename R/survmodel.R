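#' Harrell's concordance index with 95% CI
#'
#' Fraction of usable patient pairs whose predicted risk ordering matches
#' the observed outcome ordering: 0.5 is random, 1 perfect. A pair is
#' usable when the earlier time is an observed event (or, at a tied time,
#' exactly one of the two is an event); ties in the risk score count 0.5.
#' The CI is an asymptotic normal (Noether-type) interval whose variance
#' comes from the degree-2 U-statistic influence-function estimator.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time survival times.
#' @param event 1 = event observed, 0 = right-censored.
#' @return named numeric `c(c, lower, upper, pairs)`.
#' @export
concordanceIndex <- function(risk, time, event) {
    n <- length(risk)
    stopifnot(length(time) == n, length(event) == n, n >= 2L)
    ti <- matrix(time, n, n)
    tj <- t(ti)
    ei <- matrix(event == 1, n, n)
    ej <- t(ei)
    comp <- (ti < tj & ei) | (ti == tj & ei & !ej)   # i fails first
    diag(comp) <- FALSE
    ri <- matrix(risk, n, n)
    rj <- t(ri)
    s <- (ri > rj) + 0.5 * (ri == rj)
    np <- sum(comp)
    if (np == 0L) stop("no comparable pairs")
    cidx <- sum(s[comp]) / np
    # influence of subject k: all usable pairs it takes part in
    contrib <- matrix(0, n, n)
    contrib[comp] <- s[comp] - cidx
    phi <- rowSums(contrib) + colSums(contrib)
    v <- sum(phi^2) / np^2
    se <- sqrt(v)
    c(c = cidx, lower = max(0, cidx - 1.96 * se),
      upper = min(1, cidx + 1.96 * se), pairs = np)
}

#' Univariable Cox regression of one continuous feature
#'
#' Single-covariate Cox proportional-hazards fit by partial-likelihood
#' maximization, with the Wald p-value and CI on the per-unit hazard
#' ratio, and Harrell's C of the fitted linear predictor.
#'
#' @param x feature values (continuous).
#' @param time,event survival outcome.
#' @return one-row data.frame: HR, p, HR_lo, HR_hi, c, c_lo, c_hi.
#' @export
univariableCox <- function(x, time, event) {
    if (sum(event == 1) < 2L) stop("at least 2 events are required")
    if (any(!is.finite(x))) stop("non-finite feature values")
    if (stats::sd(x) == 0) stop("constant feature carries no information")
    fit <- survival::coxph(survival::Surv(time, event) ~ x)
    if (!is.finite(fit$coefficients))
        stop("univariable Cox fit did not converge")
    sm <- summary(fit)
    ci <- concordanceIndex(unname(stats::predict(fit, type = "lp")),
                           time, event)
    data.frame(HR = unname(sm$conf.int[1, "exp(coef)"]),
               p = unname(sm$coefficients[1, "Pr(>|z|)"]),
               HR_lo = unname(sm$conf.int[1, "lower .95"]),
               HR_hi = unname(sm$conf.int[1, "upper .95"]),
               c = unname(ci["c"]), c_lo = unname(ci["lower"]),
               c_hi = unname(ci["upper"]))
}

#' Pearson correlation matrix of common PET descriptors
#'
#' @param features data.frame of continuous columns (at least 3 rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonCorrelationMatrix <- function(features) {
    stopifnot(is.data.frame(features) || is.matrix(features))
    X <- as.matrix(features)
    if (nrow(X) < 3L) stop("at least 3 patients are required")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance column(s): ",
             paste(colnames(X)[sds == 0], collapse = ", "))
    stats::cor(X)
}

# event-stratified fold assignment: every fold gets events
.stratifiedFolds <- function(event, nFolds, seed) {
    for (try in 0:4) {
        set.seed(.deriveSeed(seed, try))
        foldid <- integer(length(event))
        for (g in c(1, 0)) {
            idx <- sample(which(event == g))
            foldid[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
        ev <- tabulate(foldid[event == 1], nFolds)
        if (all(ev >= 1L)) return(foldid)
    }
    stop("could not build event-balanced folds after bounded retries")
}

#' Cross-validated LASSO-Cox feature selection
#'
#' Fits the L1-penalized Cox path on internally standardized features,
#' chooses the penalty minimizing the 10-fold cross-validated partial
#' likelihood deviance (folds stratified by event status), and returns
#' the features with nonzero coefficients at that penalty. An empty
#' selection is a legitimate outcome, not an error.
#'
#' @param X data.frame or matrix of candidate features.
#' @param time,event survival outcome.
#' @param nFolds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return list: `selected` (character), `coefficients` (penalized, per
#'   SD of each feature), `lambda`, `foldid`, `seed`, `cvFit`.
#' @export
lassoCoxCV <- function(X, time, event, nFolds = 10, seed = 1L) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(time))
    if (sum(event == 1) < nFolds)
        stop("need at least as many events as folds")
    mu <- colMeans(X)
    sg <- apply(X, 2, stats::sd)
    if (any(sg == 0)) stop("zero-variance candidate feature(s)")
    Z <- scale(X, center = mu, scale = sg)
    foldid <- .stratifiedFolds(event, nFolds, seed)
    y <- survival::Surv(time, event)
    cv <- glmnet::cv.glmnet(Z, y, family = "cox", foldid = foldid,
                            type.measure = "deviance",
                            standardize = FALSE)
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    names(cf) <- colnames(X)
    sel <- names(cf)[cf != 0]
    list(selected = sel, coefficients = cf[cf != 0],
         lambda = cv$lambda.min, foldid = foldid,
         seed = as.integer(seed), cvFit = cv)
}

#' Unpenalized Cox refit of the selected features
#'
#' Refits the selected features by ordinary multivariable Cox regression
#' on the whole cohort so that coefficients, HRs and CIs are reported on
#' the unpenalized scale. Features listed in `logFeatures` enter as their
#' natural logarithm (the transformation applied to LN volume).
#'
#' @param X data.frame of features (original scale).
#' @param time,event survival outcome.
#' @param selected non-empty character vector of feature names.
#' @param modelId `"tumor"`, `"LN"` or `"combined"`.
#' @param logFeatures features to log-transform before entry.
#' @param lambda,seed metadata from the selection step (stored).
#' @return a [ModelFit-class].
#' @export
refitCox <- function(X, time, event, selected, modelId = "combined",
                     logFeatures = character(0), lambda = NA_real_,
                     seed = NA_integer_) {
    if (length(selected) == 0L) stop("empty selection; nothing to refit")
    stopifnot(all(selected %in% names(X)))
    D <- X[, selected, drop = FALSE]
    for (f in intersect(logFeatures, selected)) {
        if (any(D[[f]] <= 0))
            stop("log transform requested for non-positive feature ", f)
        D[[f]] <- log(D[[f]])
    }
    D$..time <- time
    D$..event <- event
    fml <- stats::as.formula(paste(
        "survival::Surv(..time, ..event) ~",
        paste(sprintf("`%s`", selected), collapse = " + ")))
    fit <- survival::coxph(fml, data = D)
    if (any(!is.finite(fit$coefficients)))
        stop("Cox refit did not converge")
    sm <- summary(fit)
    hrTab <- data.frame(feature = selected,
                        coef = unname(fit$coefficients),
                        HR = unname(sm$conf.int[, "exp(coef)"]),
                        HR_lo = unname(sm$conf.int[, "lower .95"]),
                        HR_hi = unname(sm$conf.int[, "upper .95"]),
                        p_value = unname(sm$coefficients[, "Pr(>|z|)"]))
    lp <- unname(stats::predict(fit, type = "lp"))
    ci <- concordanceIndex(lp, time, event)
    cf <- fit$coefficients
    names(cf) <- selected
    new("ModelFit", modelId = modelId, features = selected,
        coefficients = cf, hrTable = hrTab,
        cIndex = ci[c("c", "lower", "upper")],
        aic = aic(fit$loglik[2], length(cf)),
        lambda = lambda, seed = as.integer(seed), fit = fit,
        diagnostics = list(logFeatures = intersect(logFeatures, selected)))
}

#' Akaike information criterion for a partial likelihood
#'
#' @param logPL maximized log partial likelihood.
#' @param k number of estimated coefficients.
#' @return AIC = 2k - 2 logPL.
#' @export
aic <- function(logPL, k) {
    stopifnot(is.finite(logPL), k >= 0)
    2 * k - 2 * logPL
}

#' Order models by ascending AIC (preferred first)
#'
#' @param fits named list of [ModelFit-class] objects.
#' @return data.frame with columns model and AIC, ascending.
#' @export
aicOrder <- function(fits) {
    a <- vapply(fits, function(f) f@aic, numeric(1))
    out <- data.frame(model = names(fits), AIC = unname(a))
    out[order(out$AIC), , drop = FALSE]
}

#' Log-linearity check by penalized smoothing spline
#'
#' Compares the linear univariable Cox fit against a penalized-spline
#' fit by likelihood ratio: a significant nonlinear component (p < 0.05)
#' yields a "non-linear" verdict. When the raw feature is non-linear,
#' strictly positive, and its logarithm passes the same check, a log
#' transformation is recommended (the LN-volume case).
#'
#' @param x feature values.
#' @param time,event survival outcome.
#' @param alpha significance level for the nonlinear component.
#' @return list: `verdict` ("log-linear"/"non-linear"), `pNonlinear`,
#'   `recommendLog`, and `curve` (data.frame of x vs the spline effect).
#' @export
checkLogLinearity <- function(x, time, event, alpha = 0.05) {
    if (sum(event == 1) < 10L)
        stop("too few events for a spline diagnostic")
    .pNonlin <- function(z) {
        d <- data.frame(z = z, time = time, event = event)
        f1 <- survival::coxph(survival::Surv(time, event) ~ z, data = d)
        f2 <- survival::coxph(
            survival::Surv(time, event) ~ survival::pspline(z), data = d)
        lrt <- 2 * (f2$loglik[2] - f1$loglik[2])
        df <- sum(f2$df) - 1
        list(p = stats::pchisq(max(lrt, 0), df = max(df, 1e-8),
                               lower.tail = FALSE),
             fit = f2)
    }
    raw <- .pNonlin(x)
    verdict <- if (raw$p < alpha) "non-linear" else "log-linear"
    recommendLog <- FALSE
    if (verdict == "non-linear" && all(x > 0)) {
        lg <- .pNonlin(log(x))
        if (lg$p >= alpha) recommendLog <- TRUE
    }
    term <- stats::predict(raw$fit, type = "terms")[, 1]
    ord <- order(x)
    list(verdict = verdict, pNonlinear = raw$p,
         recommendLog = recommendLog,
         curve = data.frame(x = x[ord], effect = term[ord]))
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Runs the standard scaled-Schoenfeld correlation-with-log(time) test
#' per feature and returns the residual series for plotting (residual
#' versus log time).
#'
#' @param fit a [ModelFit-class] or a `coxph` fit.
#' @param time,event the outcome used to fit (for the contract check).
#' @return list: `table` (feature, chisq, df, p; last row GLOBAL) and
#'   `residuals` (data.frame: logTime plus one column per feature).
#' @export
checkPHSchoenfeld <- function(fit, time = NULL, event = NULL) {
    cox <- if (is(fit, "ModelFit")) fit@fit else fit
    if (is.null(cox)) stop("no underlying Cox fit (empty selection?)")
    if (cox$nevent < 2L) stop("at least 2 events are required")
    zph <- survival::cox.zph(cox, transform = "log")
    tab <- data.frame(feature = rownames(zph$table),
                      chisq = zph$table[, "chisq"],
                      df = zph$table[, "df"],
                      p = zph$table[, "p"], row.names = NULL)
    res <- data.frame(logTime = zph$x, zph$y)
    list(table = tab, residuals = res)
}

#' External validation of a fitted model
#'
#' Computes the linear predictor on a new cohort with the frozen
#' development coefficients and evaluates Harrell's C.
#'
#' @param fit a [ModelFit-class].
#' @param features data.frame containing every selected feature.
#' @param time,event outcome of the validation cohort.
#' @return named numeric `c(c, lower, upper, pairs)`.
#' @export
externalValidate <- function(fit, features, time, event) {
    stopifnot(is(fit, "ModelFit"))
    miss <- setdiff(fit@features, names(features))
    if (length(miss))
        stop("validation cohort lacks feature(s): ",
             paste(miss, collapse = ", "))
    D <- features[, fit@features, drop = FALSE]
    for (f in fit@diagnostics$logFeatures) D[[f]] <- log(D[[f]])
    lp <- as.numeric(as.matrix(D) %*% fit@coefficients[fit@features])
    concordanceIndex(lp, time, event)
}

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit '%s': %d feature(s) selected\n",
                object@modelId, length(object@features)))
    if (length(object@features)) {
        print(object@hrTable, row.names = FALSE, digits = 3)
        cat(sprintf("C-index %.3f (95%% CI %.3f-%.3f); AIC %.1f\n",
                    object@cIndex["c"], object@cIndex["lower"],
                    object@cIndex["upper"], object@aic))
    }
    if (!is.na(object@cExternal))
        cat(sprintf("external C-index %.3f\n", object@cExternal))
})

#' Build one prognostic model (LASSO selection + refit)
#'
#' Convenience wrapper running [lassoCoxCV()] then [refitCox()] for one
#' of the three model pools.
#'
#' @inheritParams lassoCoxCV
#' @inheritParams refitCox
#' @return a [ModelFit-class]; when the selection is empty, an empty
#'   `ModelFit` with `aic = NA` and no underlying fit.
#' @export
buildModel <- function(X, time, event, modelId = "combined",
                       nFolds = 10, seed = 1L,
                       logFeatures = character(0)) {
    sel <- lassoCoxCV(X, time, event, nFolds = nFolds, seed = seed)
    if (length(sel$selected) == 0L)
        return(new("ModelFit", modelId = modelId, features = character(0),
                   coefficients = numeric(0), hrTable = data.frame(),
                   cIndex = c(c = NA_real_, lower = NA_real_,
                              upper = NA_real_),
                   aic = NA_real_, lambda = sel$lambda,
                   seed = as.integer(seed), fit = NULL))
    refitCox(X, time, event, sel$selected, modelId = modelId,
             logFeatures = logFeatures, lambda = sel$lambda, seed = seed)
}
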