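# PCA-based feature subsetting. Plain PCA produces linear combinations, not
# subsets; to obtain a subset of the original named features (the form the
# per-net classifiers consume) each original feature is scored by its
# maximum absolute loading over the retained components and the top-scoring
# features are kept.

#' Fit a PCA feature selector
#'
#' Standardizes (z-scores) the 54 canonical feature columns, runs principal
#' component analysis, retains the fewest components whose cumulative
#' explained variance reaches `variance_target`, scores each original
#' feature by its maximum absolute loading over the retained components,
#' and selects either the top `k` features or (if `k` is `NULL`) all
#' features whose score exceeds the `score_quantile` quantile of the
#' scores. Zero-variance columns are excluded from standardization (never
#' divided by zero) and can never be selected.
#'
#' Determinism: eigenvector signs are fixed by making the largest-magnitude
#' loading of each component positive; score ties (within 1e-12) are broken
#' in favor of the earlier canonical column.
#'
#' @param data A feature tibble containing the 54 canonical columns (see
#'   [extract_features()]).
#' @param variance_target Fraction of variance the retained components must
#'   explain (default 0.95).
#' @param k Number of features to select; `NULL` for the quantile rule.
#' @param score_quantile Quantile of the loading scores above which
#'   features are selected when `k` is `NULL` (default 0.6).
#' @param net_id Optional identifier (1, 2, or 3) recorded in the result.
#' @return An object of class `pca_selection` with fields `selected`
#'   (feature names in decreasing score order), `scores`, `loadings`,
#'   `explained_variance`, `retained` (component count), `center`, `scale`,
#'   and `dropped` (zero-variance columns).
#' @export
fit_pca_selector <- function(data, variance_target = 0.95, k = NULL,
                             score_quantile = 0.6, net_id = NULL) {
  check_feature_frame(data)
  feats <- feature_names()
  x <- as.matrix(data[feats])
  if (nrow(x) < 2)
    ivustex_abort("PCA selection needs at least 2 rows", "degeneracy")
  if (!is.null(k) && (k < 1 || k > length(feats)))
    ivustex_abort(paste0("k must be between 1 and ", length(feats)),
                  "parameter")
  if (variance_target <= 0 || variance_target > 1)
    ivustex_abort("variance_target must be in (0, 1]", "parameter")
  sds <- apply(x, 2, stats::sd)
  constant <- !is.finite(sds) | sds < 1e-12
  if (sum(!constant) < 2)
    ivustex_abort("PCA selection needs at least 2 non-constant feature columns",
                  "degeneracy")
  xs <- x[, !constant, drop = FALSE]
  pca <- prcomp(xs, center = TRUE, scale. = TRUE)
  rot <- pca$rotation
  # sign convention: largest-|loading| entry of each PC positive (first on tie)
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  retained <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  if (is.na(retained)) retained <- length(ev)
  scores <- setNames(numeric(length(feats)), feats)
  scores[colnames(xs)] <-
    apply(abs(rot[, seq_len(retained), drop = FALSE]), 1, max)
  if (is.null(k)) {
    cutoff <- quantile(scores[!constant], probs = score_quantile, names = FALSE)
    chosen <- names(scores)[scores > cutoff & !constant]
  } else {
    ord <- order(-scores, seq_along(scores))  # ties -> earlier canonical column
    chosen <- feats[ord][seq_len(min(k, sum(!constant)))]
  }
  # report in decreasing score order, canonical order on ties
  chosen <- chosen[order(-scores[chosen], match(chosen, feats))]
  structure(list(
    net_id = net_id,
    selected = chosen,
    scores = scores,
    loadings = rot[, seq_len(retained), drop = FALSE],
    explained_variance = ev,
    retained = retained,
    variance_target = variance_target,
    k = k,
    score_quantile = if (is.null(k)) score_quantile else NULL,
    center = setNames(pca$center, colnames(xs)),
    scale = setNames(pca$scale, colnames(xs)),
    dropped = feats[constant]
  ), class = "pca_selection")
}

#' Apply a fitted selection to a feature table
#'
#' Subsets the selected feature columns (in the selection's order) and, by
#' default, standardizes them with the center/scale stored at fit time —
#' never recomputed — so train and predict see the same transformation.
#' Identifier columns (`row`, `col`, `label`) are carried through.
#'
#' @param data A feature tibble containing all selected columns.
#' @param selection A `pca_selection`.
#' @param standardize Apply the stored z-scoring (default `TRUE`).
#' @return Tibble of identifier columns plus the selected features.
#' @export
apply_selection <- function(data, selection, standardize = TRUE) {
  if (!inherits(selection, "pca_selection"))
    ivustex_abort("selection must be a pca_selection object", "parameter")
  unknown <- setdiff(selection$selected, feature_names())
  if (length(unknown) > 0)
    ivustex_abort(paste0("selection names unknown features: ",
                         paste(unknown, collapse = ", ")), "schema")
  check_feature_frame(data, required = selection$selected)
  meta <- intersect(c("row", "col", "label"), names(data))
  x <- as.matrix(data[selection$selected])
  if (standardize && length(selection$selected) > 0) {
    x <- sweep(x, 2, selection$center[selection$selected], "-")
    x <- sweep(x, 2, selection$scale[selection$selected], "/")
  }
  dplyr::bind_cols(data[meta], as_tibble(x))
}

#' @export
print.pca_selection <- function(x, ...) {
  cat("<pca_selection>",
      if (!is.null(x$net_id)) paste0(" net ", x$net_id), "\n", sep = "")
  cat(sprintf("  %d features selected from %d non-constant (of %d); %d PCs retained (%.1f%% variance)\n",
              length(x$selected), sum(x$scores > 0), length(x$scores),
              x$retained, 100 * sum(x$explained_variance[seq_len(x$retained)])))
  cat("  top features:", paste(head(x$selected, 8), collapse = ", "),
      if (length(x$selected) > 8) "...", "\n")
  invisible(x)
}

#' Tidy a PCA selection
#'
#' @param x A `pca_selection`.
#' @param ... Unused.
#' @return One row per canonical feature: `feature`, `family`, `score`
#'   (maximum absolute loading over retained components), and `selected`.
#' @export
tidy.pca_selection <- function(x, ...) {
  fam <- feature_families()
  tibble(feature = names(x$scores),
         family = fam$family[match(names(x$scores), fam$name)],
         score = unname(x$scores),
         selected = names(x$scores) %in% x$selected) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' @rdname tidy.pca_selection
#' @export
glance.pca_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_retained_pcs = x$retained,
         variance_target = x$variance_target,
         cum_variance = sum(x$explained_variance[seq_len(x$retained)]),
         n_dropped = length(x$dropped))
}

#' @export
autoplot.pca_selection <- function(object, ...) {
  td <- tidy(object)
  td$feature <- factor(td$feature, levels = rev(td$feature))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$score, y = .data$feature,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "max |loading| over retained PCs", y = NULL,
                  fill = "selected") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Serialize a selection to JSON
#'
#' @param selection A `pca_selection`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_selection()` returns the selection.
#' @export
write_selection <- function(selection, path) {
  obj <- selection
  obj$loadings <- NULL  # scores, variance fractions and standardization suffice
  # named atomic vectors lose their names as JSON arrays; store as objects
  obj$scores <- as.list(obj$scores)
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  # 17 significant digits round-trip IEEE doubles exactly, so a reloaded
  # model standardizes (and therefore predicts) identically
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$scores <- unlist(obj$scores)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$dropped <- as.character(obj$dropped)
  structure(obj, class = "pca_selection")
}
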