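# PCA loading-based feature selection.

# build a feature-schema tibble whose columns are controlled noise; only
# the named columns carry variance
synthetic_feature_frame <- function(n, signal = list(), noise_sd = 0,
                                    seed = 1) {
  withr::with_seed(seed, {
    out <- as.data.frame(matrix(if (noise_sd > 0)
      stats::rnorm(n * 54, sd = noise_sd) else 0, n, 54))
    names(out) <- feature_names()
    for (nm in names(signal)) out[[nm]] <- signal[[nm]]
    as_tibble <- tibble::as_tibble
    as_tibble(out)
  })
}

test_that("a feature carrying its own variance axis is selected first with k = 1", {
  # 53 mutually correlated noise columns (no single one owns a component)
  # plus one independent signal column that owns its own axis
  withr::with_seed(5, {
    n <- 300
    common <- rnorm(n)
    d <- synthetic_feature_frame(n, seed = 5)
    for (nm in setdiff(feature_names(), "glcm_contrast"))
      d[[nm]] <- common + rnorm(n)
    d$glcm_contrast <- rnorm(n, sd = 10)
  })
  sel <- fit_pca_selector(d, k = 1)
  expect_identical(sel$selected, "glcm_contrast")
})

test_that("zero-variance columns are dropped, never selected, never divided by", {
  d <- synthetic_feature_frame(100, noise_sd = 1, seed = 6)
  d$fos_mean <- 5  # constant column
  sel <- fit_pca_selector(d, k = 10)
  expect_true("fos_mean" %in% sel$dropped)
  expect_false("fos_mean" %in% sel$selected)
  expect_false("fos_mean" %in% names(sel$center))
  expect_equal(unname(sel$scores["fos_mean"]), 0)
})

test_that("an all-constant matrix is a degeneracy error and k is validated", {
  d <- synthetic_feature_frame(50)
  expect_error(fit_pca_selector(d), class = "ivustex_error_degeneracy")
  d2 <- synthetic_feature_frame(50, noise_sd = 1, seed = 7)
  expect_error(fit_pca_selector(d2, k = 55), class = "ivustex_error_parameter")
  expect_error(fit_pca_selector(d2[1, ]), class = "ivustex_error_degeneracy")
})

test_that("loading scores match an independent eigendecomposition oracle", {
  withr::with_seed(8, {
    d <- synthetic_feature_frame(300, noise_sd = 1, seed = 8)
    # correlated structure on six columns
    z <- rnorm(300)
    d$fos_mean <- z + rnorm(300, sd = 0.2)
    d$fos_variance <- z + rnorm(300, sd = 0.2)
    d$glcm_energy <- -z + rnorm(300, sd = 0.5)
  })
  target <- 0.8
  sel <- fit_pca_selector(d, variance_target = target)

  x <- scale(as.matrix(d[feature_names()]))
  eg <- eigen(stats::cor(as.matrix(d[feature_names()])), symmetric = TRUE)
  ev <- eg$values / sum(eg$values)
  m <- which(cumsum(ev) >= target - 1e-12)[1]
  expect_identical(sel$retained, m)
  expect_equal(unname(sel$explained_variance), ev, tolerance = 1e-9)
  oracle_scores <- apply(abs(eg$vectors[, seq_len(m), drop = FALSE]), 1, max)
  expect_equal(unname(sel$scores[feature_names()]), oracle_scores,
               tolerance = 1e-9)
})

test_that("selection is deterministic and monotone in the variance target", {
  d <- synthetic_feature_frame(200, noise_sd = 1, seed = 9)
  s1 <- fit_pca_selector(d, variance_target = 0.9)
  s2 <- fit_pca_selector(d, variance_target = 0.9)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$loadings, s2$loadings)

  retained <- vapply(c(0.5, 0.7, 0.9, 0.99, 1.0), function(v)
    fit_pca_selector(d, variance_target = v)$retained, integer(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("apply_selection subsets in order and reuses stored standardization", {
  f <- small_features()$features
  sel <- fit_pca_selector(f, k = 21)
  out <- apply_selection(f, sel)
  expect_identical(names(out), c("row", "col", "label", sel$selected))
  expect_equal(ncol(out) - 3L, 21L)

  # stored center/scale, never recomputed: standardizing a shifted subset
  # must use the training-time parameters
  sub <- f[1:50, ]
  a <- apply_selection(sub, sel)
  manual <- scale(as.matrix(sub[sel$selected]),
                  center = sel$center[sel$selected],
                  scale = sel$scale[sel$selected])
  expect_equal(as.matrix(a[sel$selected]), manual, ignore_attr = TRUE)

  full <- fit_pca_selector(f, k = 54)
  expect_setequal(full$selected, setdiff(feature_names(), full$dropped))

  bad <- sel
  bad$selected <- c(bad$selected, "not_a_feature")
  expect_error(apply_selection(f, bad), class = "ivustex_error_schema")
  expect_error(apply_selection(f[, 1:10], sel), class = "ivustex_error_schema")
})

test_that("selections serialize to JSON and back", {
  f <- small_features()$features
  sel <- fit_pca_selector(f, k = 15, net_id = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, p)
  got <- read_selection(p)
  expect_identical(got$selected, sel$selected)
  expect_equal(got$scores, sel$scores, tolerance = 1e-12)
  expect_equal(got$center, sel$center, tolerance = 1e-12)
  expect_equal(got$scale, sel$scale, tolerance = 1e-12)
  a <- apply_selection(f[1:20, ], got)
  b <- apply_selection(f[1:20, ], sel)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("tidy and glance summarize a selection", {
  f <- small_features()$features
  sel <- fit_pca_selector(f, k = 10)
  td <- tidy(sel)
  expect_identical(nrow(td), 54L)
  expect_identical(sum(td$selected), 10L)
  gl <- glance(sel)
  expect_identical(gl$n_selected, 10L)
  expect_gte(gl$cum_variance, sel$variance_target)
})
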