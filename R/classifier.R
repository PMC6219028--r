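# Intensity-routed multi-level classification. Four steps:
#   1. an intensity threshold (the maximum gray value over training FT
#      pixels) splits pixels into low and high intensity;
#   2. net 1 splits low-intensity pixels into the FT/FFT and NC/DC groups;
#   3. net 2 resolves the FT/FFT group into FT or FFT;
#   4. net 3 resolves the NC/DC group — and every high-intensity pixel,
#      which bypasses nets 1-2 — into NC or DC.
# Each net is a seeded random forest (100 trees, depth <= 10) on its own
# PCA-selected, standardized feature subset.

NET_POSITIVE <- c(net1 = "NC/DC", net2 = "FFT", net3 = "DC")
NET_NEGATIVE <- c(net1 = "FT/FFT", net2 = "FT", net3 = "NC")

#' Intensity threshold from FT pixels
#'
#' The gray value separating low- from high-intensity plaque: the
#' `percentile`-th percentile of raw intensity over FT-labeled pixels. The
#' default (100) is the FT maximum — every pixel brighter than any training
#' FT pixel is routed straight to the NC-vs-DC net. Lower percentiles guard
#' against single outlier FT pixels.
#'
#' @param data Feature tibble with `intensity` and `label` columns.
#' @param percentile Percentile in \[0, 100\] (default 100 = maximum).
#' @return A single gray value.
#' @export
intensity_threshold <- function(data, percentile = 100) {
  if (!all(c("intensity", "label") %in% names(data)))
    ivustex_abort("data must have intensity and label columns", "schema")
  if (percentile < 0 || percentile > 100)
    ivustex_abort("percentile must be in [0, 100]", "parameter")
  ft <- data$intensity[!is.na(data$label) & data$label == "FT"]
  if (length(ft) == 0)
    ivustex_abort("no FT-labeled pixels to derive the intensity threshold",
                  "degeneracy")
  unname(quantile(ft, probs = percentile / 100, names = FALSE))
}

#' Route a pixel by intensity
#'
#' `"high"` iff `intensity > threshold`, strictly: the threshold is the FT
#' maximum, so FT's own brightest pixel must stay on the low side.
#'
#' @param intensity Numeric vector of gray values.
#' @param threshold Gray value from [intensity_threshold()].
#' @return Character vector over `c("low", "high")`.
#' @export
route_intensity <- function(intensity, threshold) {
  ifelse(intensity > threshold, "high", "low")
}

# tissue label -> net-1 group
tissue_group <- function(label) {
  factor(ifelse(label %in% c("FT", "FFT"), "FT/FFT", "NC/DC"),
         levels = c("FT/FFT", "NC/DC"))
}

fit_net <- function(x, y, rf_params, net) {
  if (nlevels(droplevels(y)) < 2)
    ivustex_abort(
      paste0(net, " training pool lacks one of its two classes (",
             paste(levels(y), collapse = " vs "), ")"),
      "class_coverage")
  ranger::ranger(x = x, y = y,
                 num.trees = rf_params$n_trees,
                 max.depth = rf_params$max_depth,
                 seed = rf_params$seed,
                 num.threads = 1,
                 probability = FALSE,
                 verbose = FALSE)
}

# fraction of trees voting for the net's positive class; 0-row input allowed
vote_fraction <- function(net, x, positive) {
  if (nrow(x) == 0) return(numeric(0))
  pr <- predict(net, data = x, predict.all = TRUE, num.threads = 1,
                verbose = FALSE)$predictions
  pos_code <- which(net$forest$levels == positive)
  rowMeans(pr == pos_code)
}

#' Train the intensity-based multi-level model
#'
#' Derives the intensity threshold from FT pixels, fits one PCA feature
#' selection per net on that net's own training pool, and trains the three
#' binary random forests: net 1 on low-intensity pixels labeled by tissue
#' group (FT/FFT vs NC/DC), net 2 on all FT- and FFT-labeled pixels, and
#' net 3 on all NC- and DC-labeled pixels. Nets 2 and 3 train on the full
#' labeled pool for their tissue pair (by tissue identity, not by where
#' net 1 would route a pixel).
#'
#' @param data Feature tibble with a `label` factor column covering all
#'   four tissue classes.
#' @param selections Optional list of three `pca_selection` objects (named
#'   `net1`, `net2`, `net3`); fitted internally when `NULL`.
#' @param variance_target,k,score_quantile Selection parameters passed to
#'   [fit_pca_selector()] when `selections` is `NULL`; `k` may be a single
#'   count or a vector of three per-net counts.
#' @param n_trees,max_depth Random-forest size (defaults 100 trees of depth
#'   at most 10).
#' @param threshold_percentile Percentile for [intensity_threshold()].
#' @param seed Integer seed fixing both selection and forest training.
#' @return An object of class `multilevel_model`.
#' @export
train_multilevel <- function(data, selections = NULL, variance_target = 0.95,
                             k = NULL, score_quantile = 0.6, n_trees = 100L,
                             max_depth = 10L, threshold_percentile = 100,
                             seed = 1L) {
  check_feature_frame(data)
  if (!"label" %in% names(data))
    ivustex_abort("training data must have a label column", "schema")
  lab <- data$label
  if (any(is.na(lab)))
    ivustex_abort("training data contains unlabeled pixels", "schema")
  missing_cls <- setdiff(tissue_classes(), as.character(unique(lab)))
  if (length(missing_cls) > 0)
    ivustex_abort(paste0("training labels lack class(es): ",
                         paste(missing_cls, collapse = ", ")),
                  "class_coverage")
  threshold <- intensity_threshold(data, threshold_percentile)
  low <- data$intensity <= threshold

  pools <- list(
    net1 = list(rows = which(low),
                y = tissue_group(as.character(lab[low]))),
    net2 = list(rows = which(lab %in% c("FT", "FFT")),
                y = factor(as.character(lab[lab %in% c("FT", "FFT")]),
                           levels = c("FT", "FFT"))),
    net3 = list(rows = which(lab %in% c("NC", "DC")),
                y = factor(as.character(lab[lab %in% c("NC", "DC")]),
                           levels = c("NC", "DC")))
  )

  if (is.null(selections)) {
    ks <- if (is.null(k)) rep(list(NULL), 3) else as.list(rep_len(k, 3))
    selections <- purrr::imap(pools, function(pool, nm) {
      fit_pca_selector(data[pool$rows, , drop = FALSE],
                       variance_target = variance_target,
                       k = ks[[match(nm, names(pools))]],
                       score_quantile = score_quantile,
                       net_id = match(nm, names(pools)))
    })
  }
  if (!identical(sort(names(selections)), c("net1", "net2", "net3")))
    ivustex_abort("selections must be a named list: net1, net2, net3",
                  "parameter")

  rf_params <- list(n_trees = as.integer(n_trees),
                    max_depth = as.integer(max_depth),
                    seed = as.integer(seed))
  nets <- purrr::imap(pools, function(pool, nm) {
    x <- apply_selection(data[pool$rows, , drop = FALSE], selections[[nm]])
    x <- x[selections[[nm]]$selected]
    params <- rf_params
    params$seed <- rf_params$seed + match(nm, names(pools)) - 1L
    fit_net(as.data.frame(x), pool$y, params, nm)
  })

  structure(list(threshold = threshold,
                 threshold_percentile = threshold_percentile,
                 nets = nets,
                 selections = selections,
                 net_positive = NET_POSITIVE,
                 net_negative = NET_NEGATIVE,
                 rf_params = rf_params,
                 classes = tissue_classes(),
                 n_train = nrow(data)),
            class = "multilevel_model")
}

#' @export
print.multilevel_model <- function(x, ...) {
  cat("<multilevel_model>\n")
  cat(sprintf("  intensity threshold: %g (percentile %g of FT pixels)\n",
              x$threshold, x$threshold_percentile))
  cat(sprintf("  forests: %d trees, depth <= %d, seed %d\n",
              x$rf_params$n_trees, x$rf_params$max_depth, x$rf_params$seed))
  for (nm in names(x$nets))
    cat(sprintf("  %s (%s vs %s): %d features\n", nm,
                x$net_negative[[nm]], x$net_positive[[nm]],
                length(x$selections[[nm]]$selected)))
  invisible(x)
}

#' Predict tissue labels with a multi-level model
#'
#' Routes each pixel by the intensity threshold, scores low pixels with
#' net 1, sends net-1 FT/FFT-group pixels to net 2 and the rest — plus all
#' high-intensity pixels — to net 3. Scores are positive-class tree-vote
#' fractions (granularity 1 / n_trees); a pixel is assigned the positive
#' class when its score exceeds 0.5. Route tags partition the pixels: every
#' pixel carries exactly one of `low_net1_net2`, `low_net1_net3`,
#' `high_net3`, and FT/FFT labels arise only via net 2, NC/DC only via
#' net 3.
#'
#' @param object A `multilevel_model`.
#' @param data Feature tibble containing every feature any net needs.
#' @param ... Unused.
#' @return A tibble with identifier columns, `intensity`, `route`,
#'   `net1_score`, `net2_score`, `net3_score` (NA where a net was not
#'   consulted), and the final `label` factor.
#' @export
predict.multilevel_model <- function(object, data, ...) {
  needed <- unique(unlist(lapply(object$selections, `[[`, "selected")))
  check_feature_frame(data, required = c("intensity", needed))
  n <- nrow(data)
  route <- route_intensity(data$intensity, object$threshold)
  s1 <- s2 <- s3 <- rep(NA_real_, n)
  pred <- rep(NA_character_, n)

  low <- which(route == "low")
  x1 <- apply_selection(data[low, , drop = FALSE], object$selections$net1)
  s1[low] <- vote_fraction(object$nets$net1,
                           as.data.frame(x1[object$selections$net1$selected]),
                           object$net_positive[["net1"]])
  to_net2 <- low[s1[low] <= 0.5]
  to_net3_low <- low[s1[low] > 0.5]

  x2 <- apply_selection(data[to_net2, , drop = FALSE], object$selections$net2)
  s2[to_net2] <- vote_fraction(object$nets$net2,
                               as.data.frame(x2[object$selections$net2$selected]),
                               object$net_positive[["net2"]])
  pred[to_net2] <- ifelse(s2[to_net2] > 0.5, "FFT", "FT")

  to_net3 <- c(to_net3_low, which(route == "high"))
  x3 <- apply_selection(data[to_net3, , drop = FALSE], object$selections$net3)
  s3[to_net3] <- vote_fraction(object$nets$net3,
                               as.data.frame(x3[object$selections$net3$selected]),
                               object$net_positive[["net3"]])
  pred[to_net3] <- ifelse(s3[to_net3] > 0.5, "DC", "NC")

  tag <- character(n)
  tag[to_net2] <- "low_net1_net2"
  tag[to_net3_low] <- "low_net1_net3"
  tag[route == "high"] <- "high_net3"

  meta <- intersect(c("row", "col", "label"), names(data))
  out <- data[meta]
  if ("label" %in% meta) names(out)[names(out) == "label"] <- "truth"
  dplyr::bind_cols(out, tibble(
    intensity = data$intensity,
    route = tag,
    net1_score = s1, net2_score = s2, net3_score = s3,
    label = factor(pred, levels = tissue_classes())
  ))
}

#' Score one net on arbitrary pixels
#'
#' Applies a single net of the cascade directly (ignoring routing), giving
#' the positive-class vote fraction for each row. Used for truth-pool
#' evaluation.
#'
#' @param model A `multilevel_model`.
#' @param data Feature tibble.
#' @param net `"net1"`, `"net2"`, or `"net3"`.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
score_net <- function(model, data, net = c("net1", "net2", "net3")) {
  net <- match.arg(net)
  sel <- model$selections[[net]]
  check_feature_frame(data, required = sel$selected)
  x <- apply_selection(data, sel)
  vote_fraction(model$nets[[net]], as.data.frame(x[sel$selected]),
                model$net_positive[[net]])
}

#' Intensity-only baseline for a binary tissue task
#'
#' Trains a random forest with the same size parameters as the cascade's
#' nets, but on the raw `intensity` column alone, for one binary tissue
#' task (FT vs FFT by default), and evaluates it on held-out pixels.
#' Comparing a net's accuracy against this baseline shows whether the
#' windowed texture features carry information beyond the pixel's own gray
#' value.
#'
#' @param train,test Labeled feature tibbles.
#' @param classes The two tissue classes of the task.
#' @param positive The positive class of the pair.
#' @param n_trees,max_depth,seed Forest parameters (defaults match
#'   [train_multilevel()]).
#' @return A tibble with `accuracy` (percent), `auc`, `n_train`, `n_test`.
#' @export
intensity_baseline <- function(train, test, classes = c("FT", "FFT"),
                               positive = "FFT", n_trees = 100L,
                               max_depth = 10L, seed = 1L) {
  pick <- function(d) d[!is.na(d$label) & d$label %in% classes, , drop = FALSE]
  tr <- pick(train); te <- pick(test)
  y <- factor(as.character(tr$label), levels = classes)
  net <- fit_net(data.frame(intensity = tr$intensity), y,
                 list(n_trees = n_trees, max_depth = max_depth, seed = seed),
                 "intensity baseline")
  scores <- vote_fraction(net, data.frame(intensity = te$intensity), positive)
  truth <- as.character(te$label) == positive
  counts <- confusion_counts(truth, scores > 0.5)
  tibble(accuracy = 100 * mean((scores > 0.5) == truth),
         auc = roc_auc(scores, truth)$auc,
         sensitivity = 100 * counts$TP / (counts$TP + counts$FN),
         n_train = nrow(tr), n_test = nrow(te))
}

#' Tidy a multi-level model
#'
#' @param x A `multilevel_model`.
#' @param ... Unused.
#' @return One row per net: task polarity, feature count, out-of-bag error.
#' @export
tidy.multilevel_model <- function(x, ...) {
  tibble(net = names(x$nets),
         negative = unname(x$net_negative[names(x$nets)]),
         positive = unname(x$net_positive[names(x$nets)]),
         n_features = vapply(x$selections, function(s) length(s$selected),
                             integer(1)),
         n_train = vapply(x$nets, function(n) n$num.samples, numeric(1)),
         oob_error = vapply(x$nets, function(n) n$prediction.error,
                            numeric(1)))
}

#' @rdname tidy.multilevel_model
#' @export
glance.multilevel_model <- function(x, ...) {
  tibble(threshold = x$threshold,
         threshold_percentile = x$threshold_percentile,
         n_trees = x$rf_params$n_trees,
         max_depth = x$rf_params$max_depth,
         seed = x$rf_params$seed,
         n_train = x$n_train)
}

#' Save / load a multi-level model
#'
#' Writes a model directory holding `model.json` (threshold, forest
#' parameters, per-net selections, label palette) plus one serialized
#' forest per net.
#'
#' @param model A `multilevel_model`.
#' @param dir Directory path (created if needed).
#' @return `dir` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(threshold = model$threshold,
               threshold_percentile = model$threshold_percentile,
               rf_params = model$rf_params,
               net_positive = as.list(model$net_positive),
               net_negative = as.list(model$net_negative),
               classes = model$classes,
               palette = as.list(label_palette()),
               n_train = model$n_train)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(model$selections))
    write_selection(model$selections[[nm]],
                    file.path(dir, paste0("selection_", nm, ".json")))
  for (nm in names(model$nets))
    saveRDS(model$nets[[nm]], file.path(dir, paste0("forest_", nm, ".rds")))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  nets_nm <- c("net1", "net2", "net3")
  structure(list(threshold = meta$threshold,
                 threshold_percentile = meta$threshold_percentile,
                 nets = setNames(lapply(nets_nm, function(nm)
                   readRDS(file.path(dir, paste0("forest_", nm, ".rds")))),
                   nets_nm),
                 selections = setNames(lapply(nets_nm, function(nm)
                   read_selection(file.path(dir, paste0("selection_", nm, ".json")))),
                   nets_nm),
                 net_positive = unlist(meta$net_positive),
                 net_negative = unlist(meta$net_negative),
                 rf_params = meta$rf_params,
                 classes = meta$classes,
                 n_train = meta$n_train),
            class = "multilevel_model")
}
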