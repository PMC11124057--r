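feature_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(X, scaler) {
  scale(X, center = scaler$mean, scale = scaler$sd)
}

feature_matrix <- function(feature_table) {
  as.matrix(feature_table[, setdiff(names(feature_table), "record_id"),
                          drop = FALSE])
}

#' Pipeline configuration
#'
#' Desk-scale defaults for the end-to-end solubility modelling pipeline.
#'
#' @param seed Master seed for splitting, tuning and stochastic fits.
#' @param fractions Train/test/validation fractions for [split_dataset()].
#' @param threshold Sigma-point selection threshold ([select_sigma_points()]).
#' @param activity_model `"ideal"` or `"cosmors"` for the SLE descriptor
#'   ([build_feature_table()]).
#' @param n_trials Tuning trials ([tune_models()]; full-scale protocol: 5000).
#' @param tune_max_iter MLP iteration cap during tuning.
#' @param final_max_iter MLP iteration cap for final refits.
#' @param lambda Learning-curve penalty weight ([custom_score()]).
#' @param k_lca_final Learning-curve points for the final model audit.
#' @param mixture_method Solvent-potential mixing rule
#'   ([mixture_potential()]).
#' @return A named list.
#' @export
pipeline_config <- function(seed = 1, fractions = c(0.70, 0.15, 0.15),
                            threshold = 0.4, activity_model = "ideal",
                            n_trials = 100, tune_max_iter = 150L,
                            final_max_iter = 2000L, lambda = 1,
                            k_lca_final = 20, mixture_method = "potential") {
  list(seed = as.integer(seed), fractions = fractions, threshold = threshold,
       activity_model = activity_model, n_trials = n_trials,
       tune_max_iter = as.integer(tune_max_iter),
       final_max_iter = as.integer(final_max_iter), lambda = lambda,
       k_lca_final = k_lca_final, mixture_method = mixture_method)
}

refit_candidate <- function(cand, X, y, config) {
  if (cand$family == "mlp") {
    hidden <- c(cand$params$hidden1,
                if (cand$params$hidden2 > 0) cand$params$hidden2)
    train_network(network_spec(hidden, alpha = cand$params$alpha,
                               max_iter = config$final_max_iter),
                  X, y, seed = 7L)
  } else if (cand$family == "ridge") {
    fit_ridge(X, y, cand$params$lambda)
  } else if (cand$family == "rf") {
    fit_rf(X, y, cand$params$mtry_frac, cand$params$min_node, seed = 7L)
  } else {
    stop("unknown model family: ", cand$family, call. = FALSE)
  }
}

#' Fit the full solubility model
#'
#' Runs the modelling stages end to end on a set of solubility records:
#' train/test/validation split, per-sigma R-squared descriptor selection on
#' the training subset, descriptor assembly (SLE-computed solubility,
#' selected relative sigma-potentials, temperature), z-score standardisation
#' fitted on the training split, learning-curve-penalised TPE tuning across
#' model families, final refits, validation-RMSD-optimal ensemble weighting
#' with 1% pruning, and test-set evaluation.
#'
#' @param records Record tibble (`record_id`, `solute`, `system_id`,
#'   `is_DES`, `T_K`, `x_exp`).
#' @param systems Solvent-system component tibble.
#' @param profiles Long sigma-profile tibble.
#' @param fusion Fusion tibble.
#' @param config A [pipeline_config()].
#' @param relpots Optional precomputed [compute_relative_potentials()] store.
#' @return A `des_model_fit`: selection, scaler, tuning history, refitted
#'   candidates, ensemble, per-split metrics, the final learning curve of the
#'   best family, and the configuration.
#' @export
fit_solubility_model <- function(records, systems, profiles, fusion,
                                 config = pipeline_config(), relpots = NULL) {
  splits <- split_dataset(records, config$fractions, seed = config$seed)
  if (is.null(relpots)) {
    relpots <- compute_relative_potentials(records, systems, profiles,
                                           mixture_method = config$mixture_method)
  }

  sel <- select_sigma_points(
    r2_profile(splits$train, relpots, "nonDES"),
    r2_profile(splits$train, relpots, "DES"),
    threshold = config$threshold)

  feats <- lapply(splits, function(s) {
    ft <- build_feature_table(s, systems, profiles, fusion, sel,
                              activity_model = config$activity_model,
                              relpots = relpots,
                              mixture_method = config$mixture_method)
    list(X = feature_matrix(ft),
         y = log10(s$x_exp),
         record_id = ft$record_id)
  })
  scaler <- feature_scaler(feats$train$X)
  Xtr <- apply_scaler(feats$train$X, scaler)

  families <- model_library(tune_max_iter = config$tune_max_iter)
  tuned <- tune_models(Xtr, feats$train$y, families,
                       n_trials = config$n_trials, seed = config$seed,
                       lambda = config$lambda)

  models <- purrr::map(tuned$candidates,
                       function(cand) refit_candidate(cand, Xtr,
                                                      feats$train$y, config))
  Xval <- apply_scaler(feats$validation$X, scaler)
  ensemble <- build_ensemble(models, Xval, feats$validation$y)

  metrics <- purrr::imap_dfr(feats, function(f, split) {
    pred <- predict(ensemble, apply_scaler(f$X, scaler))
    tibble::tibble(split = split, n = length(f$y),
                   rmsd = rmsd(f$y, pred),
                   r2 = stats::cor(f$y, pred)^2)
  })

  best <- tuned$candidates[[1]]
  final_lca <- learning_curve(
    function(X, y) refit_candidate(best, X, y, config),
    Xtr, feats$train$y, k = config$k_lca_final, seed = config$seed)

  structure(
    list(selection = sel, scaler = scaler, tuning = tuned,
         candidates = models, ensemble = ensemble, metrics = metrics,
         final_lca = final_lca, config = config,
         split_sizes = vapply(splits, nrow, 0L)),
    class = "des_model_fit")
}

#' @export
print.des_model_fit <- function(x, ...) {
  cat("<des_model_fit>\n")
  cat("  splits:", paste(names(x$split_sizes), x$split_sizes,
                         sep = "=", collapse = ", "), "\n")
  cat("  sigma points selected:", length(x$selection$selected_indices), "\n")
  cat("  ensemble members:", paste(names(x$ensemble$weights), collapse = ", "),
      "\n")
  print(x$metrics)
  invisible(x)
}

#' @export
glance.des_model_fit <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_selected = length(x$selection$selected_indices),
    n_members = length(x$ensemble$members),
    rmsd_train = m$rmsd[m$split == "train"],
    rmsd_test = m$rmsd[m$split == "test"],
    rmsd_validation = m$rmsd[m$split == "validation"],
    r2_test = m$r2[m$split == "test"])
}

#' Predict solubility for new compounds across solvent systems
#'
#' Computes descriptors for every requested (solute, system, temperature)
#' combination and applies a fitted model. Solutes without fusion data are
#' skipped with a warning, mirroring the method's inherent requirement for
#' melting data.
#'
#' @param fit A `des_model_fit`.
#' @param targets Tibble with columns `solute`, `system_id`, `T_K`.
#' @param systems,profiles,fusion As in [fit_solubility_model()].
#' @return A tibble: `solute`, `system_id`, `x_star_des`, `T_K`,
#'   `log10_x_pred`.
#' @export
predict_solubility <- function(fit, targets, systems, profiles, fusion) {
  have_fusion <- targets$solute %in% fusion$compound_id
  if (any(!have_fusion)) {
    warning("skipping solute(s) without fusion data: ",
            paste(unique(targets$solute[!have_fusion]), collapse = ", "),
            call. = FALSE)
    targets <- targets[have_fusion, , drop = FALSE]
  }
  if (nrow(targets) == 0L) {
    return(tibble::tibble(solute = character(), system_id = character(),
                          x_star_des = numeric(), T_K = numeric(),
                          log10_x_pred = numeric()))
  }
  targets$record_id <- sprintf("p%04d", seq_len(nrow(targets)))
  ft <- build_feature_table(targets, systems, profiles, fusion, fit$selection,
                            activity_model = fit$config$activity_model,
                            mixture_method = fit$config$mixture_method)
  X <- apply_scaler(feature_matrix(ft), fit$scaler)
  xstar <- dplyr::distinct(systems[, c("system_id", "x_star_des")])
  out <- dplyr::left_join(targets, xstar, by = "system_id")
  tibble::tibble(solute = out$solute, system_id = out$system_id,
                 x_star_des = out$x_star_des, T_K = out$T_K,
                 log10_x_pred = predict(fit$ensemble, X))
}

#' Write a model card
#'
#' JSON summary of a fitted pipeline: selection, candidate hyperparameters,
#' ensemble weights, per-split accuracy and the seed.
#'
#' @param fit A `des_model_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_card <- function(fit, path) {
  card <- list(
    seed = fit$config$seed,
    sigma_points_selected = fit$selection$selected_indices,
    threshold = fit$selection$threshold,
    candidates = lapply(fit$tuning$candidates, function(cand) {
      list(family = cand$family, params = cand$params, score = cand$score)
    }),
    ensemble_weights = as.list(fit$ensemble$weights),
    metrics = as.list(tidyr::pivot_wider(
      fit$metrics[, c("split", "rmsd")],
      names_from = "split", values_from = "rmsd", names_prefix = "rmsd_"))
  )
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the pipeline end to end from a configuration
#'
#' Orchestrates simulate (optional) -> featurize/select -> tune -> ensemble ->
#' predict, writing all artifacts (records, selection report, model card,
#' predictions, run manifest with input digests and stage timings) to an
#' output directory. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A configuration list (see [pipeline_config()] for the
#'   modelling keys), a path to a YAML file with the same keys, or keys
#'   `simulate` (logical), `generator` (list passed to [generator_config()]),
#'   `records`/`profiles_dir`/`fusion` (input paths when not simulating) and
#'   `output_dir`.
#' @return A `run_manifest` list (invisibly): config hash, seed, input
#'   digests, stage timings in seconds, output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  model_cfg <- utils::modifyList(defaults,
                                 config[intersect(names(config),
                                                  names(defaults))])
  out_dir <- config$output_dir %||% "desolv_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  input_digests <- list()
  if (isTRUE(config$simulate)) {
    gen_cfg <- do.call(generator_config,
                       utils::modifyList(list(seed = model_cfg$seed),
                                         config$generator %||% list()))
    ds <- stage("simulate", gen_solubility_dataset(gen_cfg))
    records <- ds$records; systems <- ds$systems
    profiles <- ds$profiles; fusion <- ds$fusion; relpots <- ds$relpots
    readr::write_csv(records, file.path(out_dir, "records.csv"))
    readr::write_csv(ds$truth, file.path(out_dir, "truth.csv"))
  } else {
    for (key in c("records", "fusion")) {
      if (is.null(config[[key]]) || !file.exists(config[[key]])) {
        stop("pipeline stage 'featurize' failed: missing input '", key,
             "' (", config[[key]] %||% "unset", ")", call. = FALSE)
      }
    }
    records <- readr::read_csv(config$records, show_col_types = FALSE)
    fusion <- read_fusion(config$fusion)
    profiles <- read_sigma_profiles(config$profiles_dir)
    systems <- readr::read_csv(config$systems, show_col_types = FALSE)
    relpots <- NULL
    input_digests <- as.list(tools::md5sum(
      unlist(config[c("records", "fusion", "systems")])))
  }

  fit <- stage("model", fit_solubility_model(records, systems, profiles,
                                             fusion, model_cfg, relpots))
  write_selection(fit$selection, file.path(out_dir, "selection.csv"))
  write_model_card(fit, file.path(out_dir, "model_card.json"))

  pred_targets <- dplyr::distinct(records[, c("solute", "system_id", "T_K")])
  preds <- stage("predict",
                 predict_solubility(fit, pred_targets, systems, profiles,
                                    fusion))
  readr::write_csv(preds, file.path(out_dir, "predictions.csv"))

  outputs <- file.path(out_dir, c("selection.csv", "model_card.json",
                                  "predictions.csv"))
  manifest <- list(
    config_hash = digest_object(model_cfg),
    seed = model_cfg$seed,
    input_digests = input_digests,
    output_digests = as.list(tools::md5sum(outputs)),
    stage_timings_s = as.list(timings),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
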