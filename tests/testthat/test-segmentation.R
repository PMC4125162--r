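test_that("extract_buffer keeps exactly the cells whose centers fall inside", {
  r <- height_raster(matrix(1, 10, 10), cell_size = 1)
  w <- extract_buffer(r, c(5, 5), 3)
  # brute-force centers-within-radius count
  cx <- rep((1:10) - 0.5, each = 10)
  cy <- rep(10 - (1:10) + 0.5, times = 10)
  expect_equal(sum(!is.na(w$values)),
               sum((cx - 5)^2 + (cy - 5)^2 <= 9))

  # radius beyond the diagonal keeps the whole raster
  big <- extract_buffer(r, c(5, 5), 100)
  expect_equal(dim(big$values), dim(r$values))
  expect_true(all(!is.na(big$values)))

  expect_error(extract_buffer(r, c(1e6, 1e6), 3), "outside")
})

test_that("rasterized buffer area approximates the analytic circle", {
  n <- 101
  r <- height_raster(matrix(1, n, n), cell_size = 30)
  w <- extract_buffer(r, c(n / 2 * 30, n / 2 * 30), 1200)
  area <- sum(!is.na(w$values)) * 30^2
  expect_lt(abs(area - pi * 1200^2) / (pi * 1200^2), 0.01)
})

test_that("classify_height implements left-open interval membership", {
  w <- make_window(matrix(c(0, 3, 7, 12, 5, 10), 2, 3), cell_size = 30)
  cm <- classify_height(w, thresholds = c(5, 10))
  # 0 -> background; 3,5 -> class 1; 7,10 -> class 2; 12 -> class 3
  expect_equal(sort(as.vector(cm$class_index)), c(0L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(cm$class_index[1, 1], 0L)

  zero <- classify_height(make_window(matrix(0, 4, 4)), c(5, 10))
  expect_true(all(zero$class_index == 0L))

  expect_error(classify_height(w, c(10, 5)), "ascending")

  # random grid: histogram matches an exhaustive per-cell interval test
  set.seed(42)
  h <- matrix(runif(400, 0, 30), 20, 20)
  h[sample(400, 30)] <- NA
  cm <- classify_height(make_window(h), thresholds = c(5, 10, 15, 25))
  th <- c(0, 5, 10, 15, 25, Inf)
  manual <- matrix(NA_integer_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    if (is.na(h[i, j])) next
    manual[i, j] <- if (h[i, j] <= 0) 0L else
      as.integer(which(h[i, j] > th[-6] & h[i, j] <= th[-1])[1])
  }
  expect_identical(cm$class_index, manual)
})

test_that("label_patches matches the flood-fill oracle", {
  uni <- classify_height(make_window(matrix(7, 5, 5)), c(5, 10))
  expect_equal(nrow(label_patches(uni)$patches), 1L)

  chk <- make_window(matrix(c(3, 7, 7, 3), 2, 2))  # 2x2 checkerboard
  cmk <- classify_height(chk, c(5, 10))
  expect_equal(nrow(label_patches(cmk, connectivity = 4)$patches), 4L)
  expect_equal(nrow(label_patches(cmk, connectivity = 8)$patches), 2L)

  set.seed(7)
  for (i in 1:10) {
    cls <- random_class_map(12, 12, 3)
    h <- heights_from_classes(cls)
    cm <- classify_height(make_window(h), c(5, 10, 15, 25))
    for (conn in c(4, 8)) {
      pm <- label_patches(cm, connectivity = conn)
      ora <- oracle_label(cls, conn)
      expect_equal(max(pm$label), max(ora))
      expect_identical(label_partition(pm$label), label_partition(ora))
    }
  }
})

test_that("patch areas partition the classified area", {
  set.seed(11)
  cls <- random_class_map(15, 15, 4, p_bg = 0.2)
  cm <- classify_height(make_window(heights_from_classes(cls)),
                        c(5, 10, 15, 25))
  pm <- label_patches(cm)
  veg_cells <- sum(!is.na(cls) & cls > 0)
  expect_equal(sum(pm$patches$area_m2), veg_cells * 900)
})

test_that("edge tables match hand counts and the pair-enumeration oracle", {
  # uniform map: no edges
  uni <- label_patches(classify_height(make_window(matrix(7, 4, 4)),
                                       c(5, 10)))
  expect_equal(nrow(build_edge_table(uni)), 0L)

  # 4x4 halves: shared boundary = 4 faces x 30 m
  h <- cbind(matrix(3, 4, 2), matrix(8, 4, 2))
  pm <- label_patches(classify_height(make_window(h), c(5, 10)))
  et <- build_edge_table(pm)
  expect_equal(nrow(et), 1L)
  expect_equal(et$length_m, 120)

  set.seed(13)
  for (i in 1:8) {
    cls <- random_class_map(10, 14, 4)
    cm <- classify_height(make_window(heights_from_classes(cls)),
                          c(5, 10, 15, 25))
    et <- build_edge_table(label_patches(cm))
    expect_equal(sum(et$length_m),
                 oracle_total_edge_faces(cls) * 30)
    # depth values agree with the contrast matrix entries
    ctr <- default_contrast(cm)
    expect_equal(et$depth,
                 ctr[cbind(et$class_i + 1, et$class_j + 1)])
  }
})

test_that("edge length is invariant to label permutation and transposition", {
  set.seed(29)
  cls <- random_class_map(12, 12, 3, p_na = 0)
  h <- heights_from_classes(cls)
  te <- function(hm) {
    pm <- label_patches(classify_height(make_window(hm), c(5, 10, 15, 25)))
    sum(build_edge_table(pm)$length_m)
  }
  expect_equal(te(h), te(t(h)))
  # permute class identities (1<->3): heights swapped between class bands
  h2 <- h
  h2[!is.na(cls) & cls == 1] <- 12.5
  h2[!is.na(cls) & cls == 3] <- 2.5
  expect_equal(te(h), te(h2))
})

test_that("refining thresholds never decreases total edge length", {
  set.seed(31)
  for (i in 1:6) {
    h <- matrix(runif(15 * 15, 0, 30), 15, 15)
    w <- make_window(h)
    te <- function(th) {
      pm <- label_patches(classify_height(w, th))
      sum(build_edge_table(pm)$length_m)
    }
    expect_gte(te(c(5, 10, 15, 25)), te(c(10, 25)))
    expect_gte(te(c(5, 10, 15, 20, 25)), te(c(5, 10, 15, 25)))
  }
})

test_that("default contrast matrix is a valid depth matrix", {
  cm <- classify_height(make_window(matrix(runif(64, 0, 40), 8, 8)),
                        c(5, 10, 15, 25))
  d <- default_contrast(cm)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(d[1, -1] == 1))  # background vs vegetated: max contrast
  # midpoints: open-top class midpoint = top threshold + half previous width
  expect_equal(cm$class_midpoints, c(2.5, 7.5, 12.5, 20, 30))
})
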