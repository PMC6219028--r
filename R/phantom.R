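# Synthetic IVUS-like phantoms: an annular plaque region (between the
# "intima" at radius r1 and the "media-adventitia" at r2) partitioned into
# contiguous tissue blobs, with multiplicative unit-mean speckle. Class mean
# intensities are ordered FFT < FT < NC < DC: necrotic core and dense
# calcium are brighter than the fibrous classes, and calcium is brightest
# (echogenic on ultrasound).

#' Phantom specification
#'
#' Parameters of the synthetic IVUS phantom. Defaults are the package's
#' reference conditions: a 400x400 frame, annulus radii 60/150 px, class
#' means 60/90/150/210 (FFT/FT/NC/DC) with global multiplicative speckle of
#' scale 0.1, 32 blob seeds, and class area proportions 0.35/0.25/0.22/0.18
#' (FT/FFT/NC/DC).
#'
#' @param size Frame side length in pixels.
#' @param r1,r2 Inner (lumen) and outer annulus radii in pixels;
#'   `0 < r1 < r2 < size / 2`.
#' @param mu Named class mean intensities, ordered `FFT < FT < NC < DC`.
#' @param sigma Speckle scale: the per-pixel multiplicative factor has unit
#'   mean and standard deviation `sigma` (gamma law). `0` disables noise.
#' @param sigma_class Optional named per-class speckle scales overriding
#'   `sigma` (used by the hard FT/FFT-overlap regime, where texture — not
#'   mean intensity — must separate the fibrous classes).
#' @param mu_background Mean intensity outside the annulus (lumen and
#'   adventitia), given the global `sigma` speckle.
#' @param n_seeds Number of Voronoi blob seeds partitioning the annulus.
#' @param proportions Named target class area proportions (sum to 1).
#' @param seed RNG seed; the phantom is fully determined by the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 400L, r1 = 60, r2 = 150,
                         mu = c(FFT = 60, FT = 90, NC = 150, DC = 210),
                         sigma = 0.1, sigma_class = NULL,
                         mu_background = 25,
                         n_seeds = 32L,
                         proportions = c(FT = 0.35, FFT = 0.25,
                                         NC = 0.22, DC = 0.18),
                         seed = 1L) {
  if (!(r1 > 0 && r2 > r1 && r2 < size / 2))
    ivustex_abort("radii must satisfy 0 < r1 < r2 < size / 2", "parameter")
  if (!all(tissue_classes() %in% names(mu)))
    ivustex_abort("mu must name FT, FFT, NC, DC", "parameter")
  if (!(mu[["FFT"]] < mu[["FT"]] && mu[["FT"]] < mu[["NC"]] &&
        mu[["NC"]] < mu[["DC"]]))
    ivustex_abort("class means must be ordered FFT < FT < NC < DC",
                  "parameter")
  if (sigma < 0) ivustex_abort("sigma must be nonnegative", "parameter")
  if (!all(tissue_classes() %in% names(proportions)) ||
      abs(sum(proportions) - 1) > 1e-8 || any(proportions <= 0))
    ivustex_abort("proportions must name all four classes, be positive and sum to 1",
                  "parameter")
  sc <- setNames(rep(sigma, 4), tissue_classes())
  if (!is.null(sigma_class)) {
    if (any(sigma_class < 0))
      ivustex_abort("sigma_class must be nonnegative", "parameter")
    sc[names(sigma_class)] <- sigma_class
  }
  if (n_seeds < 4)
    ivustex_abort("need at least one blob seed per class", "parameter")
  structure(list(size = as.integer(size), r1 = r1, r2 = r2,
                 mu = mu[tissue_classes()],
                 sigma = sigma, sigma_class = sc,
                 mu_background = mu_background,
                 n_seeds = as.integer(n_seeds),
                 proportions = proportions[tissue_classes()],
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Hard FT/FFT-overlap phantom specification
#'
#' A variant whose FT and FFT mean intensities nearly coincide while their
#' speckle scales differ, so raw intensity alone barely separates the two
#' fibrous classes and windowed texture must carry the signal. Used to
#' check that the texture features add information beyond intensity.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
hard_phantom_spec <- function(...) {
  args <- list(mu = c(FFT = 82, FT = 95, NC = 150, DC = 210),
               sigma_class = c(FFT = 0.18, FT = 0.05, NC = 0.1, DC = 0.1))
  do.call(phantom_spec, modifyList(args, list(...)))
}

# unit-mean multiplicative speckle: gamma(shape = 1/s^2, rate = 1/s^2)
speckle_factor <- function(n, s) {
  if (s == 0) return(rep(1, n))
  rgamma(n, shape = 1 / s^2, rate = 1 / s^2)
}

#' Generate one phantom frame
#'
#' Builds the annular plaque mask, partitions it into contiguous class
#' blobs (seeded Voronoi cells greedily assigned to classes so empirical
#' areas track the target proportions), and renders pixel values as
#' `clip(mu_class * speckle, 0, 255)` rounded to integers. Fully
#' deterministic given the spec (including its seed); the global RNG state
#' is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `frame` (integer matrix), `mask` (logical matrix),
#'   `labels` (integer matrix over [label_palette()]), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    ivustex_abort("spec must be a phantom_spec", "parameter")
  n <- spec$size
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  mask <- d > spec$r1 & d <= spec$r2
  idx <- which(mask)
  rr <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  cls <- tissue_classes()
  withr::with_seed(spec$seed, {
    # seed points uniform in the annulus (rejection sampling)
    sr <- numeric(0); sc <- numeric(0)
    while (length(sr) < spec$n_seeds) {
      m <- 4L * spec$n_seeds
      x <- stats::runif(m, 1, n); y <- stats::runif(m, 1, n)
      keep <- sqrt((x - ctr)^2 + (y - ctr)^2) > spec$r1 &
        sqrt((x - ctr)^2 + (y - ctr)^2) <= spec$r2
      sr <- c(sr, x[keep]); sc <- c(sc, y[keep])
    }
    sr <- sr[seq_len(spec$n_seeds)]; sc <- sc[seq_len(spec$n_seeds)]
    # nearest seed per annulus pixel
    d2 <- outer(rr, sr, function(a, b) (a - b)^2) +
      outer(cc, sc, function(a, b) (a - b)^2)
    cell <- max.col(-d2, ties.method = "first")
    # greedy cell -> class assignment chasing target proportions:
    # largest cells first, each to the class with the largest remaining
    # area deficit (holds empirical proportions within roughly one cell)
    area <- tabulate(cell, nbins = spec$n_seeds)
    deficit <- spec$proportions * length(idx)
    cell_class <- integer(spec$n_seeds)
    for (ci in order(-area)) {
      k <- which.max(deficit)
      cell_class[ci] <- k
      deficit[k] <- deficit[k] - area[ci]
    }
    code <- cell_class[cell]  # 1..4 in tissue_classes() order
    labels <- matrix(0L, n, n)
    labels[idx] <- code
    frame <- matrix(spec$mu_background *
                      speckle_factor(n * n, spec$sigma), n, n)
    for (k in seq_along(cls)) {
      sel <- idx[code == k]
      frame[sel] <- spec$mu[[cls[k]]] *
        speckle_factor(length(sel), spec$sigma_class[[cls[k]]])
    }
  })
  frame <- matrix(as.integer(round(pmin(pmax(frame, 0), 255))), n, n)
  list(frame = frame, mask = mask, labels = labels, spec = spec)
}

#' Generate a multi-frame phantom dataset
#'
#' Draws `n_frames` independent phantoms from per-frame seeds derived from
#' `seed`; `n_frames = 1` reproduces [generate_phantom()] with the first
#' derived seed. Train/test splitting is left to the caller.
#'
#' @param spec A [phantom_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Base seed for deriving per-frame seeds (defaults to the
#'   spec's seed).
#' @return A list of `n_frames` phantom triples.
#' @export
generate_dataset <- function(spec = phantom_spec(), n_frames = 1L,
                             seed = spec$seed) {
  if (n_frames < 1) ivustex_abort("n_frames must be >= 1", "parameter")
  frame_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_frames))
  lapply(frame_seeds, function(s) {
    sp <- spec
    sp$seed <- s
    generate_phantom(sp)
  })
}

#' Plot a phantom
#'
#' @param phantom A triple from [generate_phantom()].
#' @param what `"frame"` or `"labels"`.
#' @return A ggplot raster of the frame or label map.
#' @export
plot_phantom <- function(phantom, what = c("frame", "labels")) {
  what <- match.arg(what)
  m <- phantom[[what]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)) - 1L,
                           col = seq_len(ncol(m)) - 1L)
  df$value <- m[cbind(df$row + 1L, df$col + 1L)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (what == "frame") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 255), name = "gray")
  } else {
    df$tissue <- factor(c("NONE", tissue_classes())[df$value + 1L],
                        levels = c("NONE", tissue_classes()))
    p + ggplot2::geom_raster(data = df,
                             ggplot2::aes(fill = .data$tissue)) +
      ggplot2::scale_fill_manual(values = c(NONE = "black", FT = "#1b9e77",
                                            FFT = "#d95f02", NC = "#7570b3",
                                            DC = "#e7298a"), name = "tissue")
  }
}
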