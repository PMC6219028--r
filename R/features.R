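# Per-pixel windowed texture features. The per-window functions operate on a
# K x K gray-value matrix and are thin wrappers over the compiled kernels;
# extract_features() runs the same kernels over every mask pixel of a frame.

#' Feature-extraction configuration
#'
#' Bundles the tunable parameters of the extraction stage. The defaults are
#' the package's reference settings: 5x5 windows for all feature families
#' except the 3x3 LBP neighborhood; GLCM at distance 1 and 135 degrees with
#' 16 uniform gray bins, single-direction accumulation; horizontal (0
#' degree) runs for the run-length matrix, also at 16 bins.
#'
#' @param window Odd window size for FOS/GLCM/LEM/GLRLM (default 5).
#' @param lbp_window LBP neighborhood size; only 3 is supported.
#' @param glcm_d Co-occurrence pixel distance.
#' @param glcm_theta Co-occurrence angle in degrees (0, 45, 90, or 135).
#'   135 pairs pixel (r, c) with (r - d, c - d).
#' @param glcm_levels Number of uniform gray bins over \[0, 255\] for the
#'   co-occurrence matrix.
#' @param glcm_symmetric If `TRUE`, accumulate each pair in both orders.
#' @param glrlm_theta Run direction in degrees (0, 45, 90, or 135).
#' @param glrlm_levels Gray bins for the run-length matrix.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window = 5L, lbp_window = 3L, glcm_d = 1L,
                           glcm_theta = 135L, glcm_levels = 16L,
                           glcm_symmetric = FALSE, glrlm_theta = 0L,
                           glrlm_levels = 16L) {
  check_odd <- function(k, what) {
    if (length(k) != 1 || is.na(k) || k < 3 || k %% 2 == 0)
      ivustex_abort(paste0(what, " must be an odd integer >= 3"), "parameter")
  }
  check_odd(window, "window")
  if (!identical(as.integer(lbp_window), 3L))
    ivustex_abort("lbp_window must be 3", "parameter")
  if (!glcm_theta %in% c(0, 45, 90, 135) || !glrlm_theta %in% c(0, 45, 90, 135))
    ivustex_abort("angles must be one of 0, 45, 90, 135 degrees", "parameter")
  if (glcm_levels < 2 || glrlm_levels < 2)
    ivustex_abort("quantization must use at least 2 gray levels", "parameter")
  if (glcm_d < 1 || glcm_d >= window)
    ivustex_abort("glcm_d must be in [1, window - 1] so pixel pairs exist",
                  "parameter")
  structure(list(window = as.integer(window),
                 lbp_window = 3L,
                 glcm_d = as.integer(glcm_d),
                 glcm_theta = as.integer(glcm_theta),
                 glcm_levels = as.integer(glcm_levels),
                 glcm_symmetric = isTRUE(glcm_symmetric),
                 glrlm_theta = as.integer(glrlm_theta),
                 glrlm_levels = as.integer(glrlm_levels)),
            class = "feature_config")
}

# edge-excluding mirror: -1 -> 1, n -> n - 2 (0-based); matches the
# compiled kernel
reflect_index <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  vapply(i, function(x) {
    while (x < 0 || x >= n) {
      if (x < 0) x <- -x
      if (x >= n) x <- 2L * n - 2L - x
    }
    x
  }, integer(1))
}

#' Extract a square window around a pixel
#'
#' Returns the K x K patch of gray values centered on `center`; pixels
#' falling outside the frame are filled by edge-excluding mirror reflection
#' (index -1 maps to +1), so every frame pixel — including border pixels —
#' has a full window.
#'
#' @param frame Integer matrix of gray values.
#' @param center Pixel coordinate `c(row, col)`, 0-based.
#' @param k Odd window size.
#' @return K x K numeric matrix.
#' @export
#' @examples
#' f <- matrix(0:24, 5, 5)
#' extract_window(f, c(0, 0), 3)
extract_window <- function(frame, center, k = 5L) {
  if (length(k) != 1 || k < 1 || k %% 2 == 0)
    ivustex_abort("window size k must be a positive odd integer", "parameter")
  nr <- nrow(frame); nc <- ncol(frame)
  r <- center[1]; c <- center[2]
  if (r < 0 || r >= nr || c < 0 || c >= nc)
    ivustex_abort("window center lies outside the frame", "bounds")
  half <- (k - 1) / 2
  rows <- reflect_index(seq.int(r - half, r + half), nr) + 1L
  cols <- reflect_index(seq.int(c - half, c + half), nc) + 1L
  w <- frame[rows, cols, drop = FALSE]
  storage.mode(w) <- "double"
  w
}

check_window <- function(window, min_k = 3L) {
  if (!is.matrix(window) || nrow(window) != ncol(window))
    ivustex_abort("window must be a square matrix", "parameter")
  if (nrow(window) < min_k || nrow(window) %% 2 == 0)
    ivustex_abort(paste0("window must be odd-sized and at least ",
                         min_k, "x", min_k), "parameter")
  if (any(!is.finite(window)) || any(window < 0 | window > 255))
    ivustex_abort("window values must be gray levels in [0, 255]", "format")
  storage.mode(window) <- "double"
  window
}

#' First-order statistics of a window
#'
#' Population moments over all window pixels: mean, variance, standard
#' deviation, excess kurtosis, and skewness. For a zero-variance window,
#' skewness and kurtosis are defined as 0.
#'
#' @param window Square gray-value matrix (reference size 5x5).
#' @return Named numeric vector of length 5.
#' @export
compute_fos <- function(window) {
  window <- check_window(window)
  setNames(cpp_fos(window), feature_names("fos"))
}

#' Grey level co-occurrence matrix features of a window
#'
#' Quantizes the window to `levels` uniform bins over \[0, 255\],
#' accumulates ordered pixel pairs at the `(d, theta)` offset, normalizes
#' the counts to probabilities, and evaluates 17 Haralick-style features.
#' Formulas weight by the 1-based bin index; entropies use the natural log
#' with `0 * log(0) := 0`; the information measure of correlation is the
#' first Haralick variant and the normalized inverse difference moment
#' divides the squared level difference by `levels^2`.
#'
#' @inheritParams compute_fos
#' @param d Pixel distance.
#' @param theta Angle in degrees (0, 45, 90, 135).
#' @param levels Number of gray bins.
#' @param symmetric Accumulate pairs in both orders.
#' @return Named numeric vector of length 17.
#' @export
compute_glcm_features <- function(window, d = 1L, theta = 135L, levels = 16L,
                                  symmetric = FALSE) {
  window <- check_window(window)
  if (!theta %in% c(0, 45, 90, 135))
    ivustex_abort("theta must be one of 0, 45, 90, 135", "parameter")
  if (levels < 2) ivustex_abort("levels must be >= 2", "parameter")
  out <- tryCatch(
    cpp_glcm(window, as.integer(d), as.integer(theta), as.integer(levels),
             isTRUE(symmetric)),
    error = function(e) ivustex_abort(conditionMessage(e), "degenerate"))
  setNames(out, feature_names("glcm"))
}

#' Laws' energy measures of a window
#'
#' Builds the nine 5x5 Laws masks from the vectors `L5 = (1,4,6,4,1)`,
#' `E5 = (-1,-2,0,2,1)`, `S5 = (-1,0,2,0,-1)`, `R5 = (1,-4,6,-4,1)`
#' (asymmetric outer-product pairs such as E5L5/L5E5 are averaged with
#' their transpose), correlates each mask with the reflect-padded window to
#' obtain a same-size texture image, and returns the mean squared response
#' (MSS) and mean absolute response (MAS) of each.
#'
#' @inheritParams compute_fos
#' @return Named numeric vector of length 18 (9 MSS then 9 MAS).
#' @export
compute_lem_features <- function(window) {
  window <- check_window(window, min_k = 5L)
  setNames(cpp_lem(window), feature_names("lem"))
}

#' Extended grey level run length matrix features of a window
#'
#' Quantizes the window, collects maximal runs of equal level along the
#' `theta` direction, and evaluates the five conventional run-length
#' features (SRE, LRE, GLN, RLN, RP) plus the six gray-level-weighted
#' extensions (LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE). The gray level in
#' the weighting formulas is the 1-based bin index.
#'
#' @inheritParams compute_fos
#' @param theta Run direction in degrees (0, 45, 90, 135).
#' @param levels Number of gray bins.
#' @return Named numeric vector of length 11.
#' @export
compute_glrlm_features <- function(window, theta = 0L, levels = 16L) {
  window <- check_window(window)
  if (!theta %in% c(0, 45, 90, 135))
    ivustex_abort("theta must be one of 0, 45, 90, 135", "parameter")
  if (levels < 2) ivustex_abort("levels must be >= 2", "parameter")
  setNames(cpp_glrlm(window, as.integer(theta), as.integer(levels)),
           feature_names("glrlm"))
}

#' Local binary pattern codes of a 3x3 neighborhood
#'
#' Thresholds the 8 neighbors against the center with `s(x) = 1` iff
#' `x >= 0` (so a flat neighborhood codes as all ones). Neighbors are taken
#' clockwise from the top-left pixel, bit `n` weighted `2^n` in acquisition
#' order. The rotation-invariant uniform code (`riu2`) is the number of set
#' bits when the circular 0/1 transition count `U` is at most 2, and
#' `N + 1 = 9` otherwise.
#'
#' @param window 3x3 gray-value matrix.
#' @return Named numeric vector `c(lbp_basic, lbp_riu2)`.
#' @export
compute_lbp_features <- function(window) {
  if (!is.matrix(window) || !identical(dim(window), c(3L, 3L)))
    ivustex_abort("LBP requires a 3x3 window (exactly 8 neighbors)",
                  "parameter")
  if (any(!is.finite(window)) || any(window < 0 | window > 255))
    ivustex_abort("window values must be gray levels in [0, 255]", "format")
  storage.mode(window) <- "double"
  setNames(cpp_lbp(window), feature_names("lbp"))
}

#' Laws masks
#'
#' The nine 5x5 Laws texture masks used by [compute_lem_features()], after
#' transpose-averaging, in canonical order.
#'
#' @return Named list of nine 5x5 matrices.
#' @export
laws_masks <- function() {
  v <- list(l5 = c(1, 4, 6, 4, 1), e5 = c(-1, -2, 0, 2, 1),
            s5 = c(-1, 0, 2, 0, -1), r5 = c(1, -4, 6, -4, 1))
  pairs <- list(c("e5", "l5"), c("s5", "l5"), c("r5", "l5"), c("e5", "e5"),
                c("s5", "e5"), c("r5", "e5"), c("s5", "s5"), c("r5", "s5"),
                c("r5", "r5"))
  masks <- lapply(pairs, function(p) {
    m <- outer(v[[p[1]]], v[[p[2]]])
    (m + t(m)) / 2
  })
  names(masks) <- .lem_mask_names
  masks
}

#' Extract all 54 features for every plaque pixel
#'
#' Computes, for each `TRUE` pixel of `mask`, the raw center-pixel
#' intensity plus the FOS (5), GLCM (17), LEM (18), extended GLRLM (11),
#' and LBP (2) features from windows centered on the pixel — 54 features in
#' all. Windows are reflect-padded at the frame border, so the mask
#' constrains only window centers, never window contents. Rows are emitted
#' in row-major (row, then col) order, with 0-based coordinates; the result
#' is deterministic given the frame and configuration.
#'
#' @param frame Integer gray-value matrix (see [read_frame()]).
#' @param mask Logical matrix of plaque pixels, same shape as `frame`.
#' @param labels Optional integer label map over [label_palette()]; adds a
#'   `label` factor column restricted to the four tissue classes.
#' @param config A [feature_config()].
#' @return A tibble with columns `row`, `col`, optionally `label`, then the
#'   54 canonical feature columns.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(size = 64, r1 = 10, r2 = 24, seed = 1))
#' feats <- extract_features(ph$frame, ph$mask, ph$labels)
#' dim(feats)
extract_features <- function(frame, mask, labels = NULL,
                             config = feature_config()) {
  frame <- validate_frame(frame)
  mask <- validate_mask(mask, frame)
  if (!any(mask))
    ivustex_abort("mask has no plaque pixels to extract", "empty_input")
  if (!inherits(config, "feature_config"))
    config <- do.call(feature_config, config)
  if (!is.null(labels)) labels <- validate_labels(labels, frame, mask)
  res <- cpp_extract_all(frame, mask, config$window, config$glcm_d,
                         config$glcm_theta, config$glcm_levels,
                         config$glcm_symmetric, config$glrlm_theta,
                         config$glrlm_levels)
  feats <- res$features
  colnames(feats) <- feature_names()
  out <- tibble(row = res$row, col = res$col)
  if (!is.null(labels)) {
    code <- labels[cbind(res$row + 1L, res$col + 1L)]
    cls <- tissue_classes()
    out$label <- factor(ifelse(code == 0L, NA_character_, cls[code]),
                        levels = cls)
  }
  dplyr::bind_cols(out, as_tibble(feats))
}
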