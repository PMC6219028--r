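# Canonical names and ordering of the 54 per-pixel features. Every feature
# table in the package uses exactly these column names in this order:
# intensity, then FOS (5), GLCM (17), LEM (9 MSS + 9 MAS), extended
# GLRLM (11), LBP (2).

.lem_mask_names <- c("e5l5", "s5l5", "r5l5", "e5e5", "s5e5", "r5e5",
                     "s5s5", "r5s5", "r5r5")

.feature_catalog <- local({
  fos <- c("mean", "variance", "sd", "kurtosis", "skewness")
  glcm <- c("autocorrelation", "contrast", "cluster_prominence",
            "cluster_shade", "dissimilarity", "energy", "entropy",
            "homogeneity", "maximum_probability", "variance", "sum_average",
            "sum_variance", "sum_entropy", "difference_variance",
            "difference_entropy", "imc1", "idmn")
  glrlm <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
             "srlge", "srhge", "lrlge", "lrhge")
  data.frame(
    name = c("intensity",
             paste0("fos_", fos),
             paste0("glcm_", glcm),
             paste0("lem_mss_", .lem_mask_names),
             paste0("lem_mas_", .lem_mask_names),
             paste0("glrlm_", glrlm),
             "lbp_basic", "lbp_riu2"),
    family = c("intensity", rep("fos", 5), rep("glcm", 17), rep("lem", 18),
               rep("glrlm", 11), rep("lbp", 2)),
    stringsAsFactors = FALSE
  )
})

#' Canonical feature names
#'
#' The 54 per-pixel texture features computed by [extract_features()], in
#' their canonical column order: raw `intensity`, 5 first-order statistics
#' (`fos_*`), 17 grey level co-occurrence matrix features (`glcm_*`),
#' 18 Laws' energy measures (`lem_mss_*`, `lem_mas_*`), 11 extended grey
#' level run length matrix features (`glrlm_*`), and 2 local binary
#' pattern codes (`lbp_*`).
#'
#' @param family Optional character vector restricting the result to one or
#'   more families: `"intensity"`, `"fos"`, `"glcm"`, `"lem"`, `"glrlm"`,
#'   `"lbp"`.
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_names())  # 54
#' feature_names("lbp")
feature_names <- function(family = NULL) {
  if (is.null(family)) return(.feature_catalog$name)
  bad <- setdiff(family, unique(.feature_catalog$family))
  if (length(bad) > 0)
    ivustex_abort(paste0("unknown feature family: ", paste(bad, collapse = ", ")),
                  "parameter")
  .feature_catalog$name[.feature_catalog$family %in% family]
}

#' Feature families
#'
#' @return A tibble with columns `name` and `family` describing the 54
#'   canonical features.
#' @export
feature_families <- function() as_tibble(.feature_catalog)

#' Tissue classes and label palette
#'
#' Plaque tissue classes in their canonical order, and the integer palette
#' used in label images: 0 = unlabeled (outside the plaque), 1 = FT
#' (fibrous tissue), 2 = FFT (fibro-fatty tissue), 3 = NC (necrotic core),
#' 4 = DC (dense calcium).
#'
#' @return `tissue_classes()` returns the character vector
#'   `c("FT", "FFT", "NC", "DC")`; `label_palette()` returns a named
#'   integer vector including `NONE = 0`.
#' @export
tissue_classes <- function() c("FT", "FFT", "NC", "DC")

#' @rdname tissue_classes
#' @export
label_palette <- function() {
  c(NONE = 0L, FT = 1L, FFT = 2L, NC = 3L, DC = 4L)
}
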