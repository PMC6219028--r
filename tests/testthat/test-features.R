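# Window extraction and the 54 per-window features, checked against
# trivial closed-form cases and literal brute-force oracles.

test_that("extract_window mirrors out-of-frame pixels and validates input", {
  f <- matrix(100L, 10, 10)
  expect_equal(extract_window(f, c(5, 5), 5), matrix(100, 5, 5))

  f2 <- matrix(seq_len(100), 10, 10)
  w <- extract_window(f2, c(0, 0), 3)
  # corner window: index -1 mirrors to +1 on both axes
  expect_equal(w[1, 1], f2[2, 2])
  expect_equal(w[1, 2], f2[2, 1])
  expect_equal(w[2, 1], f2[1, 2])
  expect_equal(w[2, 2], f2[1, 1])

  expect_error(extract_window(f, c(5, 5), 4), class = "ivustex_error_parameter")
  expect_error(extract_window(f, c(10, 5), 3), class = "ivustex_error_bounds")
})

test_that("first-order statistics match the literal population moments", {
  const <- matrix(7, 5, 5)
  expect_equal(unname(compute_fos(const)), c(7, 0, 0, 0, 0))

  # twenty 0s and five 10s (oracle-confirmed closed forms)
  w <- matrix(c(rep(0, 20), rep(10, 5)), 5, 5)
  got <- compute_fos(w)
  expect_equal(unname(got), oracle_fos(as.vector(w)), tolerance = 1e-12)
  expect_equal(unname(got), c(2, 16, 4, 0.25, 1.5), tolerance = 1e-12)

  withr::with_seed(11, {
    for (i in 1:20) {
      w <- random_window()
      got <- compute_fos(w)
      expect_equal(unname(got), oracle_fos(as.vector(w)), tolerance = 1e-9)
      expect_equal(got[["fos_sd"]]^2, got[["fos_variance"]], tolerance = 1e-12)
    }
  })
})

test_that("GLCM features handle constant and checkerboard windows", {
  g <- compute_glcm_features(matrix(100, 5, 5))
  expect_equal(g[["glcm_energy"]], 1)
  expect_equal(g[["glcm_entropy"]], 0)
  expect_equal(g[["glcm_contrast"]], 0)
  expect_equal(g[["glcm_dissimilarity"]], 0)
  expect_equal(g[["glcm_maximum_probability"]], 1)

  # two-level checkerboard: diagonal (135 degree) neighbors share a level
  cb <- outer(1:5, 1:5, function(r, c) ifelse((r + c) %% 2 == 0, 200, 40))
  expect_equal(compute_glcm_features(cb, d = 1, theta = 135)[["glcm_contrast"]], 0)
})

test_that("GLCM features equal the exhaustive-pair oracle on random windows", {
  withr::with_seed(21, {
    for (i in 1:30) {
      w <- random_window()
      d <- sample(1:2, 1)
      th <- sample(c(0, 45, 90, 135), 1)
      ng <- sample(c(4, 8, 16), 1)
      sym <- sample(c(TRUE, FALSE), 1)
      got <- compute_glcm_features(w, d = d, theta = th, levels = ng,
                                   symmetric = sym)
      expect_equal(unname(got), oracle_glcm(w, d, th, ng, sym),
                   tolerance = 1e-9)
    }
  })
})

test_that("Laws energy measures are zero on constant fields and match the loop oracle", {
  expect_equal(unname(compute_lem_features(matrix(123, 5, 5))), rep(0, 18))

  withr::with_seed(31, {
    for (i in 1:20) {
      w <- random_window()
      got <- compute_lem_features(w)
      expect_equal(unname(got), oracle_lem(w), tolerance = 1e-9)
      expect_true(all(got >= 0))
      mss <- unname(got[1:9]); mas <- unname(got[10:18])
      expect_identical(mss == 0, mas == 0)
    }
  })
})

test_that("the nine Laws masks are the documented kernels", {
  m <- laws_masks()
  expect_length(m, 9)
  expect_named(m, c("e5l5", "s5l5", "r5l5", "e5e5", "s5e5", "r5e5",
                    "s5s5", "r5s5", "r5r5"))
  # every mask zero-sum (at least one zero-sum factor vector)
  expect_true(all(vapply(m, sum, numeric(1)) == 0))
  e5l5 <- (outer(c(-1, -2, 0, 2, 1), c(1, 4, 6, 4, 1)) +
             t(outer(c(-1, -2, 0, 2, 1), c(1, 4, 6, 4, 1)))) / 2
  expect_equal(m$e5l5, e5l5)
})

test_that("run-length features handle constant and all-singleton windows", {
  g <- compute_glrlm_features(matrix(77, 5, 5), theta = 0)
  expect_equal(g[["glrlm_rp"]], 0.2)
  expect_equal(g[["glrlm_sre"]], 1 / 25)
  expect_equal(g[["glrlm_lre"]], 25)
  expect_equal(g[["glrlm_gln"]], 5)
  expect_equal(g[["glrlm_rln"]], 5)

  # horizontally alternating extremes: every run has length 1
  alt <- matrix(rep(c(0, 255), length.out = 25), 5, 5, byrow = TRUE)
  g2 <- compute_glrlm_features(alt, theta = 0)
  expect_equal(g2[["glrlm_rp"]], 1)
  expect_equal(g2[["glrlm_sre"]], 1)
  expect_equal(g2[["glrlm_lre"]], 1)
})

test_that("run-length features equal the scan-line oracle in all directions", {
  withr::with_seed(41, {
    for (i in 1:20) {
      w <- matrix(sample(0:255, 25, TRUE), 5, 5)
      # low-level windows too, so long runs appear
      if (i %% 2 == 0) w <- matrix(sample(c(10, 200), 25, TRUE), 5, 5)
      for (th in c(0, 45, 90, 135)) {
        got <- compute_glrlm_features(w, theta = th)
        expect_equal(unname(got), oracle_glrlm(w, th), tolerance = 1e-9)
      }
    }
  })
})

test_that("LBP codes follow the documented bit order and riu2 rule", {
  flat <- matrix(50, 3, 3)
  expect_equal(unname(compute_lbp_features(flat)), c(255, 8))

  peak <- matrix(10, 3, 3); peak[2, 2] <- 200
  expect_equal(unname(compute_lbp_features(peak)), c(0, 0))

  # circular bit pattern 1,0,0,0,0,0,0,1: bits 0 and 7 set, U = 2, riu2 = 2
  w <- matrix(0, 3, 3)
  w[2, 2] <- 100
  w[1, 1] <- 200  # neighbor 0 (top-left)
  w[2, 1] <- 200  # neighbor 7 (left)
  got <- compute_lbp_features(w)
  expect_equal(unname(got), c(2^0 + 2^7, 2))
  expect_equal(unname(got), oracle_lbp(w))

  withr::with_seed(51, {
    for (i in 1:30) {
      w3 <- random_window(3)
      expect_equal(unname(compute_lbp_features(w3)), oracle_lbp(w3))
    }
  })
  expect_error(compute_lbp_features(matrix(0, 5, 5)),
               class = "ivustex_error_parameter")
})

test_that("extract_features emits one 54-feature row per mask pixel", {
  sf <- small_features()
  f <- sf$features
  expect_equal(nrow(f), sum(sf$phantom$mask))
  expect_identical(names(f)[-(1:3)], feature_names())
  expect_true(all(is.finite(as.matrix(f[feature_names()]))))
  # intensity column is the raw center-pixel gray value
  expect_equal(f$intensity,
               as.numeric(sf$phantom$frame[cbind(f$row + 1, f$col + 1)]))
  expect_error(extract_features(sf$phantom$frame,
                                matrix(FALSE, 96, 96)),
               class = "ivustex_error_empty_input")
})

test_that("bulk extraction agrees with per-window computation incl. borders", {
  ph <- small_features()$phantom
  f <- small_features()$features
  # probe a corner-adjacent pixel and two interior pixels
  mask_px <- cbind(f$row, f$col)
  probe <- unique(rbind(mask_px[1, ], mask_px[nrow(mask_px) %/% 2, ],
                        mask_px[nrow(mask_px), ]))
  for (i in seq_len(nrow(probe))) {
    r <- probe[i, 1]; c <- probe[i, 2]
    w5 <- extract_window(ph$frame, c(r, c), 5)
    w3 <- extract_window(ph$frame, c(r, c), 3)
    expected <- oracle_all54(w5, w3)
    got <- as.numeric(f[f$row == r & f$col == c, feature_names()])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("extraction is deterministic and constant frames give identical rows", {
  ph <- small_features()$phantom
  f1 <- extract_features(ph$frame, ph$mask)
  f2 <- extract_features(ph$frame, ph$mask)
  expect_identical(f1, f2)

  const <- matrix(120L, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  fc <- extract_features(const, mask)
  vals <- as.matrix(fc[feature_names()])
  expect_true(all(apply(vals, 2, function(v) diff(range(v)) == 0)))
})

test_that("zero-sum-mask features are invariant to gray shifts", {
  withr::with_seed(61, {
    w <- matrix(sample(30:180, 25, TRUE), 5, 5)
    lem0 <- compute_lem_features(w)
    lem1 <- compute_lem_features(w + 40)
    expect_equal(lem0, lem1, tolerance = 1e-9)
    # a shift of exactly one bin width moves every level by one:
    # contrast/dissimilarity depend only on level differences
    g0 <- compute_glcm_features(w)
    g1 <- compute_glcm_features(w + 16)
    expect_equal(g0[["glcm_contrast"]], g1[["glcm_contrast"]])
    expect_equal(g0[["glcm_dissimilarity"]], g1[["glcm_dissimilarity"]])
  })
})

test_that("degenerate and invalid parameterizations are rejected", {
  expect_error(feature_config(window = 4), class = "ivustex_error_parameter")
  expect_error(feature_config(glcm_d = 5), class = "ivustex_error_parameter")
  expect_error(compute_glcm_features(matrix(9, 5, 5), d = 1, theta = 30),
               class = "ivustex_error_parameter")
  expect_error(compute_glcm_features(matrix(9, 5, 5), levels = 1),
               class = "ivustex_error_parameter")
  # offset larger than the window leaves no valid pixel pair
  expect_error(compute_glcm_features(matrix(9, 5, 5), d = 5),
               class = "ivustex_error_degenerate")
})
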