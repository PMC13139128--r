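#' Pipeline configuration
#'
#' One object driving the full chain: simulate both phenological stages,
#' preprocess, screen outliers, split, select wavelengths, train the four
#' models, evaluate, cross-stage validate, and attribute. A single global
#' `seed` fans out to per-stage seeds via [stage_seed()].
#'
#' @param seed global integer seed.
#' @param n_nss,n_ass simulated sample counts per stage (defaults 125 / 118).
#' @param preprocess_method chain passed to [preprocess()] (default `"sg-sd"`).
#' @param window,poly_order Savitzky-Golay settings.
#' @param outlier_alpha Mahalanobis flagging tail (default 0.025).
#' @param train_fraction SPXY training fraction (default 0.6).
#' @param max_vars maximal SPA subset size (default 15).
#' @param cars_runs CARS Monte-Carlo runs (default 50).
#' @param models which regressors to train, a subset of
#'   `c("rf", "svm", "cnn", "pso_cnn")`.
#' @param published_protocol if `TRUE`, reproduce the published evaluation protocol:
#'   wavelength selection on all samples with holdout scoring on the test set,
#'   and PSO fitness on the test set. Default `FALSE` keeps every choice
#'   inside the training partition.
#' @param explain whether to run Shapley attribution on the best model.
#' @param n_explain maximal number of test samples to explain (default 25).
#' @param cnn a [cnn_config()] used for the CNN and as the PSO-CNN baseline.
#' @param pso a [pso_config()].
#' @param out_dir optional directory; when set, stage artifacts (datasets,
#'   selection, metrics, attributions) are written there and hashed into the
#'   manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, n_nss = 125, n_ass = 118,
                            preprocess_method = "sg-sd", window = 15,
                            poly_order = 2, outlier_alpha = 0.025,
                            train_fraction = 0.6, max_vars = 15,
                            cars_runs = 50,
                            models = c("rf", "svm", "cnn", "pso_cnn"),
                            published_protocol = FALSE, explain = TRUE,
                            n_explain = 25, cnn = cnn_config(),
                            pso = pso_config(), out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(manifest, name, seed, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest$stages[[name]] <- list(name = name, seed = seed,
                                  elapsed = proc.time()[["elapsed"]] - t0,
                                  completed = TRUE)
  list(manifest = manifest, value = value)
}

#' Run the full inversion pipeline
#'
#' Executes simulate -> preprocess -> outlier screening -> SPXY split ->
#' CARS-SPA selection -> model training -> evaluation (plus cross-stage
#' validation of the best model on the other phenological stage) -> Shapley
#' attribution, and returns a manifest alongside all stage outputs.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result` with `manifest`, `comparison`
#'   (per-model train/test metric table), `models`, `selection`, `split`,
#'   `outliers`, `best_model`, `cross_stage`, `shap`, `shap_ranking`, and the
#'   simulated datasets.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  man <- list(stages = list(), seed = seed,
              package_version = as.character(utils::packageVersion("nitrospec")))

  st <- run_stage(man, "simulate", seed, {
    list(nss = simulate_dataset("NSS", n = config$n_nss, seed = seed),
         ass = simulate_dataset("ASS", n = config$n_ass, seed = seed))
  })
  man <- st$manifest; data_raw <- st$value

  st <- run_stage(man, "preprocess", NA, {
    lapply(data_raw, function(ds)
      preprocess(ds$spectra, config$preprocess_method,
                 window = config$window, poly_order = config$poly_order))
  })
  man <- st$manifest; prep <- st$value

  st <- run_stage(man, "outliers", NA, {
    lapply(data_raw, function(ds)
      mahalanobis_outliers(ds$spectra, alpha = config$outlier_alpha))
  })
  man <- st$manifest; outliers <- st$value
  keep <- lapply(outliers, function(o)
    setdiff(seq_along(o$distance2), o$flagged_idx))
  x_nss <- prep$nss[keep$nss, ]
  y_nss <- data_raw$nss$nitrogen[keep$nss]
  x_ass <- prep$ass[keep$ass, ]
  y_ass <- data_raw$ass$nitrogen[keep$ass]

  st <- run_stage(man, "split", NA, spxy_split(x_nss, y_nss, config$train_fraction))
  man <- st$manifest; split <- st$value

  st <- run_stage(man, "select", stage_seed(seed, "select"), {
    if (config$published_protocol) {
      cars_spa(x_nss, y_nss, max_vars = config$max_vars,
               n_runs = config$cars_runs, validation = "holdout",
               X_val = x_nss$reflectance[split$test, , drop = FALSE],
               y_val = y_nss[split$test],
               seed = stage_seed(seed, "select"))
    } else {
      cars_spa(x_nss[split$train, ], y_nss[split$train],
               max_vars = config$max_vars, n_runs = config$cars_runs,
               validation = "cv", seed = stage_seed(seed, "select"))
    }
  })
  man <- st$manifest; selection <- st$value
  # models see features in spectral order so convolution windows are local
  sel_idx <- sort(selection$indices)
  sel_nm <- x_nss$wavelengths[sel_idx]

  X_train <- x_nss$reflectance[split$train, sel_idx, drop = FALSE]
  X_test <- x_nss$reflectance[split$test, sel_idx, drop = FALSE]
  y_train <- y_nss[split$train]
  y_test <- y_nss[split$test]

  st <- run_stage(man, "train", stage_seed(seed, "train"), {
    fits <- list()
    if ("rf" %in% config$models)
      fits$rf <- rf_fit(X_train, y_train, seed = stage_seed(seed, "rf"),
                        wavelengths = sel_nm)
    if ("svm" %in% config$models)
      fits$svm <- svm_fit(X_train, y_train, seed = stage_seed(seed, "svm"),
                          wavelengths = sel_nm)
    if ("cnn" %in% config$models) {
      cfg <- config$cnn; cfg$seed <- stage_seed(seed, "cnn")
      fits$cnn <- cnn_fit(X_train, y_train, cfg, wavelengths = sel_nm)
    }
    if ("pso_cnn" %in% config$models)
      fits$pso_cnn <- pso_cnn_fit(
        X_train, y_train, pso = config$pso, cnn = config$cnn,
        fitness_on = if (config$published_protocol) "test" else "inner_validation",
        X_test = X_test, y_test = y_test,
        seed = stage_seed(seed, "pso_cnn"), wavelengths = sel_nm)
    fits
  })
  man <- st$manifest; fits <- st$value

  st <- run_stage(man, "evaluate", NA, {
    rows <- list()
    for (nm in names(fits)) {
      for (part in c("train", "test")) {
        Xp <- if (part == "train") X_train else X_test
        yp <- if (part == "train") y_train else y_test
        m <- compute_metrics(yp, predict(fits[[nm]], Xp))
        rows[[paste(nm, part)]] <- data.frame(
          model = nm, split = part, r2 = m$r2, rmse = m$rmse,
          rpd_printed = m$rpd_printed, rpd_conventional = m$rpd_conventional)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  man <- st$manifest; comparison <- st$value

  test_rows <- comparison[comparison$split == "test", ]
  best_name <- test_rows$model[which.max(test_rows$r2)]
  best <- fits[[best_name]]

  cross <- NULL
  if (length(y_ass) >= 10) {
    st <- run_stage(man, "cross_stage", NA, {
      idx_ass <- wavelength_index(x_ass, sel_nm)
      cross_stage_validate(best, x_ass$reflectance[, idx_ass, drop = FALSE],
                           y_ass)
    })
    man <- st$manifest; cross <- st$value
  }

  shap <- NULL; ranking <- NULL
  if (isTRUE(config$explain)) {
    st <- run_stage(man, "explain", stage_seed(seed, "explain"), {
      n_ex <- min(config$n_explain, nrow(X_test))
      baseline <- colMeans(X_train)
      if (ncol(X_test) <= 16)
        shapley_exact(best, X_test[seq_len(n_ex), , drop = FALSE], baseline)
      else
        shapley_sampled(best, X_test[seq_len(n_ex), , drop = FALSE], baseline,
                        seed = stage_seed(seed, "explain"))
    })
    man <- st$manifest; shap <- st$value
    ranking <- shap_ranking(shap, wavelengths = sel_nm)
  }

  result <- structure(
    list(manifest = man, comparison = comparison, models = fits,
         selection = selection, selected_nm = sel_nm, split = split,
         outliers = outliers, best_model = best_name, cross_stage = cross,
         shap = shap, shap_ranking = ranking,
         data = list(nss = data_raw$nss, ass = data_raw$ass),
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) result <- write_pipeline_artifacts(result)
  result
}

write_pipeline_artifacts <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$out_dir
  paths <- c(
    nss_csv = file.path(od, "nss.csv"),
    ass_csv = file.path(od, "ass.csv"),
    selection = file.path(od, "selection.json"),
    comparison = file.path(od, "comparison.csv"),
    shap = file.path(od, "shap_beeswarm.csv")
  )
  write_dataset(result$data$nss, paths[["nss_csv"]])
  write_dataset(result$data$ass, paths[["ass_csv"]])
  jsonlite::write_json(
    list(wavelengths = result$selected_nm,
         indices = result$selection$indices,
         rmse = result$selection$rmse,
         validation = result$selection$validation,
         n_cars = length(result$selection$cars$selected)),
    paths[["selection"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$comparison, paths[["comparison"]], row.names = FALSE)
  if (!is.null(result$shap))
    utils::write.csv(shap_long(result$shap, wavelengths = result$selected_nm),
                     paths[["shap"]], row.names = FALSE)
  result$manifest$artifacts <- lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$manifest$seed, "- stages:",
      paste(names(x$manifest$stages), collapse = ", "), "\n")
  cat("selected wavelengths (nm):", paste(round(x$selected_nm), collapse = ", "), "\n\n")
  tab <- x$comparison
  tab[, 3:6] <- round(tab[, 3:6], 3)
  print(tab, row.names = FALSE)
  cat("\nbest model by test R2:", x$best_model, "\n")
  if (!is.null(x$cross_stage))
    cat(sprintf("cross-stage: R2 = %.3f, RMSE = %.3f, RPD = %.3f, slope = %.3f, within +/-1 SD = %.1f%%\n",
                x$cross_stage$metrics$r2, x$cross_stage$metrics$rmse,
                x$cross_stage$metrics$rpd_conventional, x$cross_stage$slope,
                100 * x$cross_stage$diagnostics$fraction_within_1sd))
  invisible(x)
}
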