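# Reading and writing the pipeline's disk artifacts: grayscale frames
# (8-bit PNG/TIFF), plaque masks and label maps (integer-coded PNG using
# label_palette()), and feature tables (CSV).
#
# Coordinates are row-major and 0-based throughout: (row, col) with row 0 at
# the top of the image.

validate_frame <- function(pixels, what = "frame") {
  if (!is.matrix(pixels))
    ivustex_abort(paste0(what, " must be a 2-D matrix"), "format")
  if (any(!is.finite(pixels)))
    ivustex_abort(paste0(what, " contains non-finite values"), "format")
  if (any(pixels < 0 | pixels > 255))
    ivustex_abort(paste0(what, " has gray values outside [0, 255]"), "format")
  if (any(pixels != round(pixels)))
    ivustex_abort(paste0(what, " has non-integer gray values"), "format")
  if (nrow(pixels) < 5 || ncol(pixels) < 5)
    ivustex_abort(paste0(what, " must be at least 5x5 pixels"), "format")
  storage.mode(pixels) <- "integer"
  pixels
}

validate_mask <- function(mask, frame) {
  if (!is.matrix(mask))
    ivustex_abort("mask must be a 2-D logical matrix", "format")
  storage.mode(mask) <- "logical"
  if (any(is.na(mask)))
    ivustex_abort("mask contains missing values", "format")
  if (!identical(dim(mask), dim(frame)))
    ivustex_abort("mask shape does not match frame shape", "dimension")
  mask
}

validate_labels <- function(labels, frame, mask = NULL) {
  if (!is.matrix(labels))
    ivustex_abort("label map must be a 2-D integer matrix", "format")
  if (!identical(dim(labels), dim(frame)))
    ivustex_abort("label map shape does not match frame shape", "dimension")
  if (any(!labels %in% label_palette()))
    ivustex_abort(
      "label map contains values outside the palette 0 (NONE), 1 (FT), 2 (FFT), 3 (NC), 4 (DC)",
      "label_palette")
  storage.mode(labels) <- "integer"
  if (!is.null(mask) && any(labels != 0L & !mask))
    ivustex_abort("label map has labeled pixels outside the plaque mask",
                  "label_palette")
  labels
}

read_gray_image <- function(path) {
  if (!file.exists(path))
    ivustex_abort(paste0("file not found: ", path), "io")
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else ivustex_abort(paste0("multi-channel image, expected single-channel grayscale: ", path),
                       "format")
  }
  round(img * 255)
}

#' Read a grayscale IVUS frame
#'
#' Reads a single-channel 8-bit PNG or TIFF into an integer matrix of gray
#' values in \[0, 255\]. Multi-channel images and out-of-range values are
#' rejected rather than coerced: intensity is itself a classification
#' feature, so silent clipping would corrupt the threshold stage.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Integer matrix (rows x cols) of gray values.
#' @export
read_frame <- function(path) validate_frame(read_gray_image(path), "frame")

#' @rdname read_frame
#' @param frame Integer matrix of gray values in \[0, 255\].
#' @export
write_frame <- function(frame, path) {
  frame <- validate_frame(frame)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(frame / 255, path, bits.per.sample = 8L)
  } else {
    png::writePNG(frame / 255, path)
  }
  invisible(path)
}

#' Read and write plaque masks and label maps
#'
#' Masks and label maps are stored as 8-bit PNG whose pixel values are the
#' integer codes of [label_palette()] (masks: 0/1). `read_mask()` returns a
#' logical matrix; `read_label_map()` returns an integer matrix over
#' `{0, 1, 2, 3, 4}`. Any other pixel value is a palette error.
#'
#' @param path PNG file path.
#' @return See description.
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  if (any(!img %in% c(0, 1)))
    ivustex_abort(paste0("mask image has values other than 0/1: ", path),
                  "label_palette")
  img == 1
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  storage.mode(mask) <- "integer"
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname read_mask
#' @export
read_label_map <- function(path) {
  img <- read_gray_image(path)
  if (any(!img %in% label_palette()))
    ivustex_abort(paste0("label image has values outside the 0-4 palette: ", path),
                  "label_palette")
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_mask
#' @param labels Integer matrix over the label palette.
#' @export
write_label_map <- function(labels, path) {
  if (any(!labels %in% label_palette()))
    ivustex_abort("label map contains values outside the 0-4 palette",
                  "label_palette")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Load a frame / mask / label-map triple
#'
#' Reads and cross-validates the three artifacts that describe one IVUS
#' frame: the grayscale image, the binary plaque-region mask, and
#' (optionally) the per-pixel tissue label map. All shape and palette
#' violations raise classed errors; nothing is silently coerced.
#'
#' @param frame_path Path to the grayscale frame (PNG/TIFF, 8-bit, single
#'   channel).
#' @param mask_path Path to the 0/1 mask PNG.
#' @param label_path Optional path to the palette-coded label PNG.
#' @return A list with elements `frame` (integer matrix), `mask` (logical
#'   matrix), and `labels` (integer matrix or `NULL`).
#' @export
load_dataset <- function(frame_path, mask_path, label_path = NULL) {
  frame <- read_frame(frame_path)
  mask <- validate_mask(read_mask(mask_path), frame)
  if (!any(mask))
    ivustex_abort("mask has no plaque pixels", "empty_input")
  labels <- NULL
  if (!is.null(label_path))
    labels <- validate_labels(read_label_map(label_path), frame, mask)
  list(frame = frame, mask = mask, labels = labels)
}

#' Save and read feature tables
#'
#' Feature tables are CSV files with a header of `row,col[,label]` followed
#' by the 54 canonical feature names (see [feature_names()]). Coordinates
#' are 0-based, row-major. Values round-trip losslessly (readr writes
#' shortest round-trip decimal representations).
#'
#' @param features A feature tibble as produced by [extract_features()].
#' @param path CSV file path.
#' @return `save_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
save_feature_table <- function(features, path) {
  check_feature_frame(features)
  keep <- c(intersect(c("row", "col", "label"), names(features)),
            feature_names())
  readr::write_csv(features[keep], path, progress = FALSE)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    ivustex_abort(paste0("file not found: ", path), "io")
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tbl))
    tbl$label <- factor(tbl$label, levels = tissue_classes())
  check_feature_frame(tbl)
  tbl
}

# every downstream stage requires the full canonical feature schema
check_feature_frame <- function(features, required = feature_names()) {
  missing <- setdiff(required, names(features))
  if (length(missing) > 0)
    ivustex_abort(paste0("feature table is missing required columns: ",
                         paste(head(missing, 5), collapse = ", "),
                         if (length(missing) > 5) ", ..."),
                  "schema")
  invisible(features)
}
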