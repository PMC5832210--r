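# Pipeline orchestration: simulate -> extract -> preselect -> model ->
# validate -> report, driven by a single validated config.

#' Build a pipeline run configuration
#'
#' One structured config drives the whole run; every stochastic stage has
#' an explicit seed derived from the master seed unless overridden. The
#' config round-trips losslessly through YAML via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param outDir output directory of the run.
#' @param nPatients development-cohort size (the study scale is 262).
#' @param nValidation validation-cohort size (study scale: 50).
#' @param seed master seed; stage seeds default to values derived from
#'   it.
#' @param binWidth SUV discretization bin width.
#' @param iccCutoff,loaBound pre-selection thresholds.
#' @param surrogacyRule `"either"` (default) accepts a merged-node
#'   feature that is interchangeable with the largest or the most active
#'   node; `"both"` demands agreement with both comparators.
#' @param nFolds LASSO cross-validation folds.
#' @param nRobustness number of patients given replicate segmentations
#'   for the ICC stage.
#' @param perturbMagnitude boundary-editing rounds for replicate masks.
#' @param betas named list: ground-truth per-SD log-hazard coefficients
#'   on extracted feature columns (prefixed `tumor_` / `ln_`).
#' @param censoringRate,baselineShape,baselineScale survival generator
#'   parameters.
#' @param writeImages write NIfTI volumes per patient (off by default;
#'   the in-memory pipeline does not need them).
#' @param stages character vector of stages to run, in order.
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(outDir = tempfile("petradrun"),
                           nPatients = 262, nValidation = 50,
                           seed = 1L,
                           binWidth = 0.5, iccCutoff = 0.85,
                           loaBound = 10, nFolds = 10,
                           surrogacyRule = c("either", "both"),
                           nRobustness = 40, perturbMagnitude = 1,
                           betas = list(tumor_glrlm_sre = -0.3,
                                        ln_shape_volume_cc = 0.4,
                                        ln_glrlm_gln = 0.3,
                                        ln_stats_uniformity = -0.3),
                           censoringRate = 0.3, baselineShape = 1.2,
                           baselineScale = 24,
                           writeImages = FALSE,
                           stages = c("simulate", "extract", "preselect",
                                      "model", "validate", "report")) {
    cfg <- list(outDir = outDir, nPatients = as.integer(nPatients),
                nValidation = as.integer(nValidation),
                seed = if (is.null(seed)) NULL else as.integer(seed),
                binWidth = binWidth, iccCutoff = iccCutoff,
                loaBound = loaBound, nFolds = as.integer(nFolds),
                nRobustness = as.integer(nRobustness),
                surrogacyRule = match.arg(surrogacyRule),
                perturbMagnitude = as.integer(perturbMagnitude),
                betas = betas, censoringRate = censoringRate,
                baselineShape = baselineShape,
                baselineScale = baselineScale,
                writeImages = isTRUE(writeImages), stages = stages)
    class(cfg) <- "PipelineConfig"
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
validatePipelineConfig <- function(config) {
    if (is.null(config$seed) || length(config$seed) != 1L ||
        !is.finite(config$seed))
        stop("config is missing a seed; every stochastic stage needs one")
    stopifnot(config$nPatients >= 2L, config$nValidation >= 0L,
              config$binWidth > 0, config$iccCutoff > 0,
              config$loaBound > 0, config$nFolds >= 2L,
              config$censoringRate >= 0, config$censoringRate < 1)
    bad <- setdiff(config$stages,
                   c("simulate", "extract", "preselect", "model",
                     "validate", "report"))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(pipelineConfig, raw)
}

# clinical covariates on the demographic scale of a locally-advanced
# node-positive NSCLC cohort; ln_stations is tied to the phantom's node
# count
.simulateClinical <- function(n, nNodes, seed) {
    set.seed(seed)
    data.frame(
        patient_id = sprintf("P%04d", seq_len(n)),
        age = round(stats::rnorm(n, 66, 10)),
        gender = sample(c("Male", "Female"), n, TRUE, c(0.66, 0.34)),
        stage = sample(c("II", "IIIa", "IIIb"), n, TRUE,
                       c(0.04, 0.41, 0.55)),
        n_stage = sample(c("1", "2", "3"), n, TRUE, c(0.11, 0.58, 0.31)),
        ln_stations = nNodes,
        histology = sample(c("Squamous", "Adeno", "NOS"), n, TRUE,
                           c(0.28, 0.23, 0.49)),
        rt_dose = round(stats::rnorm(n, 64.4, 7.5), 1),
        chemotherapy = sample(c("Yes", "No"), n, TRUE, c(0.9, 0.1)))
}

# univariable Cox screen of the clinical table (continuous variables as
# such, categorical with first-level reference coding)
.clinicalUnivariable <- function(clin, time, event) {
    vars <- setdiff(names(clin), "patient_id")
    rows <- list()
    for (v in vars) {
        x <- clin[[v]]
        d <- data.frame(time = time, event = event,
                        x = if (is.character(x)) factor(x) else x)
        fit <- try(survival::coxph(survival::Surv(time, event) ~ x,
                                   data = d), silent = TRUE)
        if (inherits(fit, "try-error")) next
        sm <- summary(fit)
        cf <- sm$conf.int
        lv <- rownames(cf)
        rows[[v]] <- data.frame(
            variable = v,
            level = sub("^x", "", lv),
            HR = unname(cf[, "exp(coef)"]),
            HR_lo = unname(cf[, "lower .95"]),
            HR_hi = unname(cf[, "upper .95"]),
            p = unname(sm$coefficients[, "Pr(>|z|)"]))
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
}

.writeCSV <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE)
    path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on an in-memory synthetic cohort,
#' writing per-stage artifacts under `config$outDir` (`images/`,
#' `features/`, `selection/`, `models/`, `report/`) and a manifest of
#' checksums. A stage failure aborts with the failing stage named;
#' partial outputs are retained.
#'
#' @param config a [pipelineConfig()] or path to a YAML config.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    validatePipelineConfig(config)
    out <- config$outDir
    for (d in c("", "images", "features", "selection", "models", "report"))
        dir.create(file.path(out, d), recursive = TRUE,
                   showWarnings = FALSE)
    state <- new.env(parent = emptyenv())
    state$files <- character(0)
    state$stageLog <- list()
    runStage <- function(name, fun) {
        if (!name %in% config$stages) return(invisible(NULL))
        t0 <- Sys.time()
        res <- tryCatch(fun(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        state$stageLog[[name]] <-
            list(seconds = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
        res
    }
    addFile <- function(path) state$files <- c(state$files, path)

    ## -- simulate ------------------------------------------------------
    runStage("simulate", function() {
        state$dev <- simulateCohortImages(config$nPatients,
                                          seed = .deriveSeed(config$seed, 11))
        nn <- vapply(state$dev, function(p) length(p$nodes), integer(1))
        state$clin <- .simulateClinical(config$nPatients, nn,
                                        seed = .deriveSeed(config$seed, 12))
        addFile(.writeCSV(state$clin,
                          file.path(out, "images", "cohort_clinical.csv")))
        if (config$writeImages) {
            for (i in seq_along(state$dev)) {
                p <- state$dev[[i]]
                id <- state$clin$patient_id[i]
                writeSUVImage(p$image,
                              file.path(out, "images",
                                        sprintf("%s_suv.nii.gz", id)))
                writeROIMask(p$tumor,
                             file.path(out, "images",
                                       sprintf("%s_tumor.nii.gz", id)))
                for (nd in p$nodes)
                    writeROIMask(nd, file.path(
                        out, "images",
                        sprintf("%s_%s.nii.gz", id, maskLabel(nd))))
            }
        }
        state$stageLog$simulate_records <- config$nPatients
    })

    ## -- extract -------------------------------------------------------
    runStage("extract", function() {
        ext <- function(p, structure) {
            mask <- switch(structure,
                tumor = p$tumor,
                LN_merged = mergeNodes(p$nodes),
                LN_volume = selectLargestNode(p$nodes),
                LN_max = selectMostActiveNode(p$nodes, p$image))
            extractAll(p$image, mask, config$binWidth)
        }
        for (s in c("tumor", "LN_merged", "LN_volume", "LN_max")) {
            tab <- as.data.frame(t(vapply(state$dev, ext, numeric(118),
                                          structure = s)))
            state[[paste0("feat_", s)]] <- tab
            addFile(.writeCSV(
                cbind(patient_id = state$clin$patient_id, tab),
                file.path(out, "features",
                          sprintf("features_%s.csv", s))))
        }
        # survival outcomes: log-hazard linear in extracted ground-truth
        # features
        gt <- cbind(setNames(state$feat_tumor,
                             paste0("tumor_", names(state$feat_tumor))),
                    setNames(state$feat_LN_merged,
                             paste0("ln_", names(state$feat_LN_merged))))
        sv <- simulateSurvival(gt, survivalSpec(
            betas = unlist(config$betas),
            baselineShape = config$baselineShape,
            baselineScale = config$baselineScale,
            censoringRate = config$censoringRate,
            seed = .deriveSeed(config$seed, 13)))
        state$surv <- sv
        addFile(.writeCSV(cbind(patient_id = state$clin$patient_id, sv,
                                state$clin[-1]),
                          file.path(out, "features", "cohort.csv")))
    })

    ## -- preselect -----------------------------------------------------
    runStage("preselect", function() {
        nR <- min(config$nRobustness, config$nPatients)
        sub <- state$dev[seq_len(nR)]
        reExtract <- function(structure, seedOff) {
            tab <- t(vapply(seq_along(sub), function(i) {
                p <- sub[[i]]
                mask <- switch(structure, tumor = p$tumor,
                               LN_merged = mergeNodes(p$nodes))
                pm <- perturbSegmentation(
                    mask, config$perturbMagnitude,
                    seed = .deriveSeed(config$seed, seedOff * 1000 + i))
                extractAll(p$image, pm, config$binWidth)
            }, numeric(118)))
            as.data.frame(tab)
        }
        feats <- colnames(state$feat_tumor)
        for (s in c("tumor", "LN_merged")) {
            base <- state[[paste0("feat_", s)]][seq_len(nR), ]
            ctx <- list(
                test_retest = list(A = base, B = reExtract(s, 21)),
                inter_observer = list(A = reExtract(s, 22),
                                      B = reExtract(s, 23)))
            keepVar <- feats[vapply(feats, function(f)
                stats::sd(base[[f]]) > 0, logical(1))]
            rf <- robustnessFilter(keepVar, ctx,
                                   iccCutoff = config$iccCutoff)
            state[[paste0("robust_", s)]] <- rf
            addFile(.writeCSV(rf$report,
                              file.path(out, "selection",
                                        sprintf("robustness_%s.csv", s))))
        }
        sf <- surrogateFilter(state$feat_LN_merged, state$feat_LN_volume,
                              state$feat_LN_max,
                              iccCutoff = config$iccCutoff,
                              loaBound = config$loaBound,
                              rule = config$surrogacyRule)
        state$surrogate <- sf
        addFile(.writeCSV(sf$report,
                          file.path(out, "selection", "surrogacy_LN.csv")))
        state$retainedTumor <- state$robust_tumor$retained
        state$retainedLN <- intersect(state$robust_LN_merged$retained,
                                      sf$retained)
        for (nm in c("retainedTumor", "retainedLN")) {
            p <- file.path(out, "selection", paste0(nm, ".txt"))
            writeLines(state[[nm]], p)
            addFile(p)
        }
    })

    ## -- model ---------------------------------------------------------
    prefixCols <- function(df, cols, prefix) {
        out <- df[, cols, drop = FALSE]
        if (length(cols)) names(out) <- paste0(prefix, cols)
        out
    }
    runStage("model", function() {
        poolT <- prefixCols(state$feat_tumor, state$retainedTumor,
                            "tumor_")
        poolL <- prefixCols(state$feat_LN_merged, state$retainedLN,
                            "ln_")
        pools <- list(tumor = poolT, LN = poolL,
                      combined = cbind(poolT, poolL))
        state$fits <- list()
        for (m in names(pools)) {
            X <- pools[[m]]
            fit <- if (ncol(X) == 0L)
                new("ModelFit", modelId = m, features = character(0),
                    coefficients = numeric(0), hrTable = data.frame(),
                    cIndex = c(c = NA_real_, lower = NA_real_,
                               upper = NA_real_),
                    aic = NA_real_, lambda = NA_real_,
                    seed = .deriveSeed(config$seed, 31), fit = NULL)
            else
                buildModel(X, state$surv$time, state$surv$event,
                           modelId = m, nFolds = config$nFolds,
                           seed = .deriveSeed(config$seed, 31),
                           logFeatures = "ln_shape_volume_cc")
            state$fits[[m]] <- fit
            js <- file.path(out, "models", sprintf("model_%s.json", m))
            jsonlite::write_json(list(
                model = m, features = fit@features,
                coefficients = as.list(fit@coefficients),
                hr_table = fit@hrTable,
                c_index = as.list(fit@cIndex),
                aic = fit@aic, lambda = fit@lambda, seed = fit@seed),
                js, auto_unbox = TRUE, digits = NA, null = "null")
            addFile(js)
        }
    })

    ## -- validate ------------------------------------------------------
    runStage("validate", function() {
        if (config$nValidation < 2L) return(invisible(NULL))
        val <- simulateCohortImages(config$nValidation,
                                    seed = .deriveSeed(config$seed, 41))
        ext <- function(p, structure) {
            mask <- switch(structure, tumor = p$tumor,
                           LN_merged = mergeNodes(p$nodes))
            extractAll(p$image, mask, config$binWidth)
        }
        ft <- as.data.frame(t(vapply(val, ext, numeric(118), "tumor")))
        fl <- as.data.frame(t(vapply(val, ext, numeric(118), "LN_merged")))
        gt <- cbind(setNames(ft, paste0("tumor_", names(ft))),
                    setNames(fl, paste0("ln_", names(fl))))
        sv <- simulateSurvival(gt, survivalSpec(
            betas = unlist(config$betas),
            baselineShape = config$baselineShape,
            baselineScale = config$baselineScale,
            censoringRate = config$censoringRate,
            seed = .deriveSeed(config$seed, 42)))
        state$external <- lapply(state$fits, function(f) {
            if (length(f@features) == 0L) return(NA_real_)
            unname(externalValidate(f, gt, sv$time, sv$event)["c"])
        })
        for (m in names(state$fits))
            state$fits[[m]]@cExternal <- state$external[[m]]
        addFile(.writeCSV(data.frame(model = names(state$external),
                                     c_external =
                                         unlist(state$external)),
                          file.path(out, "models",
                                    "external_validation.csv")))
    })

    ## -- report --------------------------------------------------------
    runStage("report", function() {
        t2 <- .clinicalUnivariable(state$clin, state$surv$time,
                                   state$surv$event)
        addFile(.writeCSV(t2, file.path(out, "report",
                                        "table2_clinical.csv")))
        # common descriptors (Table-3 shape): ranges + univariable Cox
        common <- data.frame(
            tumor_max_suv = state$feat_tumor$stats_maximum,
            tumor_peak_suv = state$feat_tumor$stats_suv_peak,
            tumor_mean_suv = state$feat_tumor$stats_mean,
            tumor_volume = state$feat_tumor$shape_volume_cc,
            ln_max_suv = state$feat_LN_merged$stats_maximum,
            ln_peak_suv = state$feat_LN_merged$stats_suv_peak,
            ln_mean_suv = state$feat_LN_merged$stats_mean,
            ln_volume = state$feat_LN_merged$shape_volume_cc)
        common$tumor_load <- tumorLoad(common$tumor_volume,
                                       common$ln_volume)
        t3 <- do.call(rbind, lapply(names(common), function(f) {
            u <- univariableCox(common[[f]], state$surv$time,
                                state$surv$event)
            cbind(data.frame(
                feature = f,
                range = sprintf("%.1f-%.1f", min(common[[f]]),
                                max(common[[f]])),
                mean_sd = sprintf("%.1f±%.1f", mean(common[[f]]),
                                  stats::sd(common[[f]]))), u)
        }))
        addFile(.writeCSV(t3, file.path(out, "report",
                                        "table3_common_descriptors.csv")))
        addFile(.writeCSV(
            as.data.frame(pearsonCorrelationMatrix(common)),
            file.path(out, "report", "pearson_common_descriptors.csv")))
        # model comparison (Table-4 shape), ascending AIC
        rows <- lapply(state$fits, function(f) {
            if (length(f@features) == 0L)
                return(data.frame(model = f@modelId, feature = NA,
                                  coef = NA, HR = NA, HR_lo = NA,
                                  HR_hi = NA, p_value = NA,
                                  c_index = NA, c_lo = NA, c_hi = NA,
                                  c_external = f@cExternal, AIC = NA))
            cbind(model = f@modelId, f@hrTable,
                  c_index = unname(f@cIndex["c"]),
                  c_lo = unname(f@cIndex["lower"]),
                  c_hi = unname(f@cIndex["upper"]),
                  c_external = f@cExternal, AIC = f@aic)
        })
        ord <- aicOrder(state$fits)
        rows <- rows[match(ord$model, names(rows))]
        t4 <- do.call(rbind, c(rows, make.row.names = FALSE))
        addFile(.writeCSV(t4, file.path(out, "report",
                                        "table4_models.csv")))
        addFile(.writeCSV(ord, file.path(out, "report",
                                         "model_aic_order.csv")))
    })

    ## -- manifest ------------------------------------------------------
    files <- state$files[file.exists(state$files)]
    manifest <- list(
        package_version =
            as.character(utils::packageVersion("nodalPETrad")),
        config = unclass(config)[setdiff(names(unclass(config)),
                                         "outDir")],
        config_hash = digestConfig(config),
        stages_run = intersect(config$stages, names(state$stageLog)),
        timestamp = format(Sys.time(), tz = "UTC"),
        stage_seconds = lapply(state$stageLog, function(x)
            if (is.list(x)) x$seconds else x),
        outputs = lapply(files, function(f) list(
            path = sub(paste0("^", out, "/?"), "", f),
            md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}

#' Hash of a pipeline config (content-addressed run identity)
#'
#' @param config a `PipelineConfig`.
#' @return md5 hex string of the canonical serialized config (outDir
#'   excluded so runs are relocatable).
#' @export
digestConfig <- function(config) {
    x <- unclass(config)
    x$outDir <- NULL
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
}
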