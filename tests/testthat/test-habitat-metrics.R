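test_that("summary statistics use vegetated, non-nodata cells only", {
  w <- make_window(matrix(10, 5, 5))
  expect_equal(summary_stats(w),
               c(MEAN = 10, SD = 0, MIN = 10, MAX = 10))

  w2 <- make_window(matrix(c(2, 4, 6), 1, 3))
  s <- summary_stats(w2)
  expect_equal(s[["MEAN"]], 4)
  expect_equal(s[["SD"]], sqrt(mean((c(2, 4, 6) - 4)^2)))
  expect_equal(s[["MIN"]], 2)
  expect_equal(s[["MAX"]], 6)

  # masking contract: adding background and nodata changes nothing
  w3 <- make_window(rbind(c(2, 4, 6), c(0, NA, 0)))
  expect_equal(summary_stats(w3), s)

  expect_true(all(is.na(summary_stats(make_window(matrix(0, 3, 3))))))
})

test_that("FRAC is exactly 1 for square patches", {
  one <- make_window(matrix(c(9, 0, 0, 0), 2, 2))
  pm <- label_patches(classify_binary(one))
  b <- patch_metrics_2d(pm, landscape_area_m2(one))
  expect_equal(b[["B.FRAC.MN"]], 1)

  sq <- matrix(0, 6, 6); sq[2:4, 3:5] <- 12  # 3x3 square patch
  pm <- label_patches(classify_binary(make_window(sq)))
  expect_equal(patch_metrics_2d(pm, 36 * 900)[["B.FRAC.MN"]], 1)
})

test_that("uniform vegetated window has one patch and zero edge", {
  w <- make_window(matrix(15, 8, 8))
  b <- patch_metrics_2d(label_patches(classify_binary(w)),
                        landscape_area_m2(w))
  expect_equal(b[["B.NP"]], 1)
  expect_equal(b[["B.TE"]], 0)
  expect_equal(b[["B.ED"]], 0)
})

test_that("set B matches the brute-force oracle on random binary maps", {
  set.seed(17)
  for (i in 1:8) {
    cls <- random_class_map(16, 16, 1, p_bg = runif(1, 0.2, 0.6))
    h <- matrix(0, 16, 16); h[!is.na(cls) & cls == 1] <- 10
    h[is.na(cls)] <- NA
    w <- make_window(h)
    got <- patch_metrics_2d(label_patches(classify_binary(w)),
                            landscape_area_m2(w))
    ora <- oracle_metrics_b(cls, 30)
    expect_equal(got[["B.NP"]], ora$NP)
    expect_equal(got[["B.AREA.MN"]], ora$AREA.MN)
    expect_equal(got[["B.AREA.SD"]], ora$AREA.SD)
    expect_equal(got[["B.ED"]], ora$ED)
    expect_equal(got[["B.TE"]], ora$TE)
    expect_equal(got[["B.FRAC.MN"]], ora$FRAC.MN)
    expect_equal(got[["B.FRAC.SD"]], ora$FRAC.SD)
  }
})

metrics_c_of <- function(h) {
  w <- make_window(h)
  cm <- classify_height(w, c(5, 10, 15, 25))
  pm <- label_patches(cm)
  patch_metrics_height(pm, build_edge_table(pm), landscape_area_m2(w))
}

test_that("set C closed forms: single class, equal classes, hand case", {
  cc <- metrics_c_of(matrix(7, 6, 6))
  expect_equal(cc[["C.NP"]], 1)
  expect_equal(cc[["C.CWED"]], 0)
  expect_equal(cc[["C.SHDI"]], 0)

  # two equal-area classes: SHDI = ln 2
  h <- cbind(matrix(3, 4, 2), matrix(8, 4, 2))
  expect_equal(metrics_c_of(h)[["C.SHDI"]], log(2))

  # hand computation: 4x4 halves, classes 1|2, depth d12, no background
  cc <- metrics_c_of(h)
  cm <- classify_height(make_window(h), c(5, 10, 15, 25))
  d12 <- default_contrast(cm)[2, 3]
  expect_equal(cc[["C.TE"]], 120)
  expect_equal(cc[["C.CWED"]], d12 * 120 / (16 * 900 / 1e4))
  # with midpoints 2.5 and 7.5 over range 2.5..30: d = 5 / 27.5
  expect_equal(d12, 5 / 27.5)
})

test_that("set C matches the brute-force oracle on random maps", {
  set.seed(23)
  for (i in 1:8) {
    cls <- random_class_map(14, 14, 4, p_bg = runif(1, 0.1, 0.5))
    h <- heights_from_classes(cls)
    w <- make_window(h)
    cm <- classify_height(w, c(5, 10, 15, 25))
    pm <- label_patches(cm)
    got <- patch_metrics_height(pm, build_edge_table(pm),
                                landscape_area_m2(w))
    ora <- oracle_metrics_c(cls, 30, default_contrast(cm))
    expect_equal(got[["C.NP"]], ora$NP)
    expect_equal(got[["C.AREA.MN"]], ora$AREA.MN)
    expect_equal(got[["C.AREA.SD"]], ora$AREA.SD)
    expect_equal(got[["C.TE"]], ora$TE)
    expect_equal(got[["C.FRAC.MN"]], ora$FRAC.MN)
    expect_equal(got[["C.FRAC.SD"]], ora$FRAC.SD)
    expect_equal(got[["C.CWED"]], ora$CWED)
    expect_equal(got[["C.ECON.MN"]], ora$ECON.MN)
    expect_equal(got[["C.ECON.SD"]], ora$ECON.SD)
    expect_equal(got[["C.SHDI"]], ora$SHDI)
  }
})

test_that("height segmentation only adds structure: C vs B invariants", {
  set.seed(41)
  for (i in 1:10) {
    cfg <- landscape_config(grid_rows = 24, grid_cols = 24,
                            veg_fraction = runif(1, 0.3, 0.9),
                            autocorr_range = runif(1, 0, 300),
                            clustering = runif(1, 0, 5), seed = i)
    w <- as_window(gen_height_raster(cfg))
    m <- compute_metrics(w)
    expect_gte(m[["C.TE"]], m[["B.TE"]])
    expect_gte(m[["C.NP"]], m[["B.NP"]])
    expect_lte(m[["C.CWED"]],
               m[["C.TE"]] / landscape_area_m2(w) * 1e4 + 1e-9)
    expect_gte(m[["C.SHDI"]], 0)
    expect_lte(m[["C.SHDI"]], log(5) + 1e-12)
  }
})

test_that("compute_metrics returns all 26 metrics in canonical order", {
  w <- as_window(gen_height_raster(landscape_config(
    grid_rows = 32, grid_cols = 32, seed = 2)))
  m <- compute_metrics(w)
  expect_identical(names(m), metric_names())
  expect_equal(length(m), 26L)
  expect_true(all(is.finite(m)))
})
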