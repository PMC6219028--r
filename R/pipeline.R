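# End-to-end pipeline: simulate -> extract -> select -> train -> predict ->
# evaluate, with every artifact written under one output directory and a
# manifest (config hash, seed, package version) making each report
# reproducible.

#' Pipeline run configuration
#'
#' Collects every tunable of a full run, with defaults reproducing the
#' package's reference settings (5x5 windows with a 3x3 LBP neighborhood,
#' GLCM at distance 1 / 135 degrees, 100 trees of depth at most 10,
#' FT-maximum intensity threshold).
#'
#' @param out Output directory for artifacts (`NULL` = no files written).
#' @param phantom A [phantom_spec()] describing the simulated data, or a
#'   list of overrides for it. `regime = "hard"` switches to
#'   [hard_phantom_spec()].
#' @param regime `"separable"` or `"hard"`.
#' @param n_train,n_test Frames simulated for training and testing.
#' @param features A [feature_config()] or a list of overrides.
#' @param variance_target,k,score_quantile Selection parameters (see
#'   [fit_pca_selector()]).
#' @param n_trees,max_depth,threshold_percentile Classifier parameters
#'   (see [train_multilevel()]).
#' @param seed Master seed for the whole run.
#' @param write_features Also write per-frame feature CSVs (large; off by
#'   default).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out = NULL, phantom = list(),
                       regime = c("separable", "hard"),
                       n_train = 5L, n_test = 2L, features = list(),
                       variance_target = 0.95, k = NULL, score_quantile = 0.6,
                       n_trees = 100L, max_depth = 10L,
                       threshold_percentile = 100, seed = 1L,
                       write_features = FALSE) {
  regime <- match.arg(regime)
  if (n_train < 1 || n_test < 1)
    ivustex_abort("need at least one training and one test frame", "parameter")
  if (!inherits(phantom, "phantom_spec")) {
    maker <- if (regime == "hard") hard_phantom_spec else phantom_spec
    phantom <- do.call(maker, phantom)
  }
  if (!inherits(features, "feature_config"))
    features <- do.call(feature_config, features)
  structure(list(out = out, phantom = phantom, regime = regime,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 variance_target = variance_target, k = k,
                 score_quantile = score_quantile,
                 features = features,
                 n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 threshold_percentile = threshold_percentile,
                 seed = as.integer(seed),
                 write_features = isTRUE(write_features)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file holds any subset of the [run_config()] arguments;
#' `phantom:` and `features:` map onto [phantom_spec()] and
#' [feature_config()] arguments.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file (e.g. `seed`, `out`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path))
    ivustex_abort(paste0("config file not found: ", path), "io")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) cfg <- list()  # empty config file
  if (!is.null(cfg$phantom)) {
    if (!is.null(cfg$phantom$mu)) cfg$phantom$mu <- unlist(cfg$phantom$mu)
    if (!is.null(cfg$phantom$sigma_class))
      cfg$phantom$sigma_class <- unlist(cfg$phantom$sigma_class)
    if (!is.null(cfg$phantom$proportions))
      cfg$phantom$proportions <- unlist(cfg$phantom$proportions)
  }
  do.call(run_config, modifyList(cfg, list(...)))
}

# extract features for a list of phantom triples and bind them,
# tagging each row with its frame index
extract_dataset <- function(phantoms, config) {
  purrr::imap_dfr(phantoms, function(ph, i) {
    f <- extract_features(ph$frame, ph$mask, ph$labels, config)
    dplyr::mutate(f, frame = i, .before = 1)
  })
}

#' Run the full pipeline
#'
#' Simulates `n_train + n_test` phantom frames, extracts the 54 features
#' for every plaque pixel, fits the per-net PCA selections and the
#' three-net model on the training frames, predicts and evaluates on the
#' held-out test frames, and (when `config$out` is set) writes frames,
#' masks, label maps, the model directory, the evaluation report, and a
#' manifest. Rerunning with an identical configuration reproduces the
#' report bit-for-bit.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @param baseline Also fit the FT-vs-FFT [intensity_baseline()] on the
#'   same split and attach it as `attr(, "baseline")`.
#' @return The test-set `eval_report`, invisibly carrying the fitted model
#'   (`attr(, "model")`) and predictions (`attr(, "predictions")`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE,
                         baseline = FALSE) {
  if (!inherits(config, "run_config"))
    ivustex_abort("config must be a run_config", "parameter")
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) say("[%s] %+.1fs", what,
                              as.numeric(Sys.time() - t0, units = "secs"))

  n_frames <- config$n_train + config$n_test
  spec <- config$phantom
  phantoms <- generate_dataset(spec, n_frames, seed = config$seed)
  stage("simulate")

  train_ph <- phantoms[seq_len(config$n_train)]
  test_ph <- phantoms[config$n_train + seq_len(config$n_test)]
  train <- extract_dataset(train_ph, config$features)
  test <- extract_dataset(test_ph, config$features)
  stage("extract")

  model <- train_multilevel(train,
                            variance_target = config$variance_target,
                            k = config$k,
                            score_quantile = config$score_quantile,
                            n_trees = config$n_trees,
                            max_depth = config$max_depth,
                            threshold_percentile = config$threshold_percentile,
                            seed = config$seed)
  stage("select+train")

  preds <- predict(model, test)
  report <- evaluate_model(model, test)
  stage("predict+evaluate")

  bl <- NULL
  if (baseline) {
    bl <- intensity_baseline(train, test,
                             n_trees = config$n_trees,
                             max_depth = config$max_depth,
                             seed = config$seed)
    stage("intensity baseline")
  }

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(phantoms)) {
      tag <- sprintf("frame_%02d", i)
      write_frame(phantoms[[i]]$frame, file.path(config$out, paste0(tag, ".png")))
      write_mask(phantoms[[i]]$mask, file.path(config$out, paste0(tag, "_mask.png")))
      write_label_map(phantoms[[i]]$labels,
                      file.path(config$out, paste0(tag, "_labels.png")))
    }
    if (config$write_features) {
      save_feature_table(train, file.path(config$out, "features_train.csv"))
      save_feature_table(test, file.path(config$out, "features_test.csv"))
    }
    save_model(model, file.path(config$out, "model"))
    write_report(report, file.path(config$out, "report.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("ivustex")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      config_hash = rlang::hash(config),
      regime = config$regime,
      n_train = config$n_train, n_test = config$n_test,
      created = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE)
    say("artifacts written to %s", config$out)
  }
  attr(report, "model") <- model
  attr(report, "predictions") <- preds
  if (!is.null(bl)) attr(report, "baseline") <- bl
  invisible(report)
}
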