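# Per-net evaluation: confusion counts, sensitivity/specificity/accuracy
# (as percentages), ROC curves and trapezoid AUC, plus an overall 4-class
# confusion table from the routed predictions.

#' Confusion counts
#'
#' @param truth Logical vector (or factor coerced by `positive`) of true
#'   positives.
#' @param pred Logical vector of predicted positives.
#' @param positive When `truth`/`pred` are factors or characters, the level
#'   counted as positive.
#' @return A named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  as_bool <- function(v) {
    if (is.logical(v)) return(v)
    if (is.null(positive))
      ivustex_abort("positive class must be given for non-logical labels",
                    "parameter")
    as.character(v) == positive
  }
  t <- as_bool(truth); p <- as_bool(pred)
  if (length(t) != length(p))
    ivustex_abort("truth and pred lengths differ", "parameter")
  list(TP = sum(t & p), TN = sum(!t & !p), FP = sum(!t & p), FN = sum(t & !p))
}

#' Sensitivity, specificity and accuracy
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, each as a percentage.
#'
#' @param counts A list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return A tibble with columns `sensitivity`, `specificity`, `accuracy`
#'   (percent).
#' @export
#' @examples
#' classification_metrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0))
    ivustex_abort("confusion counts must be nonnegative", "parameter")
  if (tp + fn == 0)
    ivustex_abort("no positive cases: sensitivity undefined", "undefined_rate")
  if (tn + fp == 0)
    ivustex_abort("no negative cases: specificity undefined", "undefined_rate")
  tibble(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and returns the operating points
#' `(1 - specificity, sensitivity)` from (0, 0) to (1, 1), plus the
#' trapezoid area under the curve. The trapezoid AUC equals the
#' tie-adjusted pairwise concordance probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Logical (or factor with `positive`) true labels.
#' @param positive Positive level for non-logical `truth`.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  if (!is.logical(truth)) {
    if (is.null(positive))
      ivustex_abort("positive class must be given for non-logical labels",
                    "parameter")
    truth <- as.character(truth) == positive
  }
  if (length(scores) != length(truth))
    ivustex_abort("scores and truth lengths differ", "parameter")
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0)
    ivustex_abort("ROC undefined: both classes must be present",
                  "undefined_roc")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  # collapse tied scores into one operating point
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(t)[last] / np
  fpr <- cumsum(!t)[last] / nn
  roc <- tibble(threshold = c(Inf, s[last]),
                fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate a multi-level model
#'
#' Computes per-net confusion counts, sensitivity/specificity/accuracy,
#' ROC curve and AUC, plus the overall 4-class confusion table from routed
#' predictions. By default each net is evaluated on its ground-truth pool:
#' net 1 on all low-intensity pixels against the true tissue group, net 2
#' on all FT/FFT-truth pixels, net 3 on all NC/DC-truth pixels — each net
#' scored directly on its pool. With `pool = "routed"`, nets 2 and 3 are
#' instead evaluated only on the pixels the cascade actually routed to
#' them (restricted to pixels whose truth lies in the net's class pair).
#'
#' @param model A `multilevel_model`.
#' @param data Labeled feature tibble.
#' @param pool `"truth"` (default) or `"routed"`.
#' @return An object of class `eval_report`.
#' @export
evaluate_model <- function(model, data, pool = c("truth", "routed")) {
  pool <- match.arg(pool)
  check_feature_frame(data)
  if (!"label" %in% names(data) || any(is.na(data$label)))
    ivustex_abort("evaluation data must be fully labeled", "schema")
  lab <- factor(as.character(data$label), levels = tissue_classes())
  preds <- predict(model, data)
  low <- preds$route != "high_net3"

  net_eval <- function(net, rows, truth_bin, scores) {
    pos <- model$net_positive[[net]]
    if (length(unique(truth_bin)) < 2)
      ivustex_abort(paste0(net, " evaluation pool lacks one of its classes"),
                    "undefined_rate")
    counts <- confusion_counts(truth_bin, scores > 0.5)
    ra <- roc_auc(scores, truth_bin)
    c(list(net = net, positive = pos, n = length(rows), counts = counts),
      as.list(classification_metrics(counts)),
      list(roc = ra$roc, auc = ra$auc))
  }

  if (pool == "truth") {
    r1 <- which(low)
    r2 <- which(lab %in% c("FT", "FFT"))
    r3 <- which(lab %in% c("NC", "DC"))
    s1 <- preds$net1_score[r1]  # net 1 already scored every low pixel
    s2 <- score_net(model, data[r2, , drop = FALSE], "net2")
    s3 <- score_net(model, data[r3, , drop = FALSE], "net3")
  } else {
    r1 <- which(low)
    r2 <- which(preds$route == "low_net1_net2" & lab %in% c("FT", "FFT"))
    r3 <- which(preds$route %in% c("low_net1_net3", "high_net3") &
                  lab %in% c("NC", "DC"))
    s1 <- preds$net1_score[r1]
    s2 <- preds$net2_score[r2]
    s3 <- preds$net3_score[r3]
  }
  nets <- list(
    net1 = net_eval("net1", r1, tissue_group(as.character(lab[r1])) == "NC/DC", s1),
    net2 = net_eval("net2", r2, as.character(lab[r2]) == "FFT", s2),
    net3 = net_eval("net3", r3, as.character(lab[r3]) == "DC", s3)
  )
  confusion <- table(truth = lab, predicted = preds$label)
  structure(list(nets = nets,
                 confusion = confusion,
                 overall_accuracy = 100 * mean(preds$label == lab),
                 threshold = model$threshold,
                 pool = pool,
                 n_pixels = nrow(data)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d pixels, %s pools, threshold %g\n",
              x$n_pixels, x$pool, x$threshold))
  print(tidy(x))
  cat(sprintf("overall 4-class accuracy: %.1f%%\n", x$overall_accuracy))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One row per net with confusion counts, rates (percent) and AUC.
#' @export
tidy.eval_report <- function(x, ...) {
  purrr::map_dfr(x$nets, function(e)
    tibble(net = e$net, positive = e$positive, n = e$n,
           TP = e$counts$TP, TN = e$counts$TN,
           FP = e$counts$FP, FN = e$counts$FN,
           sensitivity = e$sensitivity, specificity = e$specificity,
           accuracy = e$accuracy, auc = e$auc))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy,
         n_pixels = x$n_pixels,
         threshold = x$threshold,
         pool = x$pool)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  rocs <- purrr::map_dfr(object$nets, function(n) {
    d <- n$roc
    d$net <- sprintf("%s (AUC %.3f)", n$net, n$auc)
    d
  })
  ggplot2::ggplot(rocs, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                     color = .data$net)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", color = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_report()` returns the report.
#' @export
write_report <- function(report, path) {
  obj <- list(
    nets = lapply(report$nets, function(n) {
      n$roc <- as.list(n$roc)
      n
    }),
    confusion = list(truth = rownames(report$confusion),
                     predicted = colnames(report$confusion),
                     counts = unclass(unname(report$confusion))),
    overall_accuracy = report$overall_accuracy,
    threshold = report$threshold,
    pool = report$pool,
    n_pixels = report$n_pixels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- lapply(obj$nets, function(n) {
    n$roc <- as_tibble(n$roc)
    n$counts <- as.list(n$counts)
    n
  })
  conf <- obj$confusion$counts
  dimnames(conf) <- list(truth = obj$confusion$truth,
                         predicted = obj$confusion$predicted)
  structure(list(nets = nets,
                 confusion = as.table(conf),
                 overall_accuracy = obj$overall_accuracy,
                 threshold = obj$threshold,
                 pool = obj$pool,
                 n_pixels = obj$n_pixels),
            class = "eval_report")
}
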