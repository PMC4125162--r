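#' Classify heights into vertical habitat classes
#'
#' Segments a landscape window into discrete height classes with global
#' thresholds: class 0 is non-vegetated (height <= `veg_cutoff`), and a
#' vegetated cell with height `h` falls in class `j` iff
#' `t[j-1] < h <= t[j]` (with `t0 = veg_cutoff` and the last class
#' open-topped). Nodata propagates.
#'
#' Class midpoints (used by the default contrast matrix) are interval
#' midpoints; the open-topped class gets the top threshold plus half the
#' previous class width.
#'
#' @param window a `landscape_window` or `height_raster`.
#' @param thresholds strictly ascending class boundary heights, meters;
#'   first must exceed `veg_cutoff`.
#' @param veg_cutoff heights at or below this are non-vegetated (default 0).
#' @return a `height_class_map`: integer class grid plus thresholds and
#'   class midpoints.
#' @export
classify_height <- function(window, thresholds = c(5, 10, 15, 25),
                            veg_cutoff = 0) {
  stopifnot(inherits(window, "height_raster"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0) ||
      thresholds[1] <= veg_cutoff)
    stop("thresholds must be strictly ascending and exceed veg_cutoff")
  h <- window$values
  cls <- matrix(NA_integer_, nrow(h), ncol(h))
  ok <- !is.na(h)
  # class j iff t[j-1] < h <= t[j]; findInterval with left-open intervals
  cls[ok] <- ifelse(h[ok] <= veg_cutoff, 0L,
                    findInterval(h[ok], thresholds, left.open = TRUE) + 1L)
  m <- length(thresholds) + 1L
  bounds <- c(veg_cutoff, thresholds)
  mid <- (bounds[-length(bounds)] + bounds[-1]) / 2
  top_width <- if (length(thresholds) >= 2)
    diff(utils::tail(thresholds, 2)) else thresholds[1] - veg_cutoff
  mid <- c(mid, utils::tail(thresholds, 1) + top_width / 2)
  structure(list(class_index = cls, thresholds = thresholds,
                 veg_cutoff = veg_cutoff, n_veg_class = m,
                 class_midpoints = mid, cell_size = window$cell_size),
            class = "height_class_map")
}

#' Binary vegetated / non-vegetated classification
#'
#' The substrate of the traditional (2-D) patch metrics: one vegetated class
#' covering every cell with height above the cutoff.
#' @inheritParams classify_height
#' @export
classify_binary <- function(window, veg_cutoff = 0) {
  stopifnot(inherits(window, "height_raster"))
  h <- window$values
  cls <- matrix(NA_integer_, nrow(h), ncol(h))
  ok <- !is.na(h)
  cls[ok] <- as.integer(h[ok] > veg_cutoff)
  structure(list(class_index = cls, thresholds = numeric(0),
                 veg_cutoff = veg_cutoff, n_veg_class = 1L,
                 class_midpoints = NA_real_, cell_size = window$cell_size),
            class = "height_class_map")
}

#' Default depth (contrast) matrix for height classes
#'
#' Contrast between two vegetated classes is the absolute difference of
#' their class midpoints scaled to `[0, 1]` by the midpoint range; the
#' vegetated / non-vegetated boundary carries maximal contrast 1.
#'
#' @param class_map a `height_class_map`.
#' @return `(m+1) x (m+1)` symmetric matrix with zero diagonal, indexed by
#'   class code 0..m (0 = background).
#' @export
default_contrast <- function(class_map) {
  stopifnot(inherits(class_map, "height_class_map"))
  mid <- class_map$class_midpoints
  m <- length(mid)
  d <- matrix(1, m + 1, m + 1)
  if (m > 1) {
    span <- max(mid) - min(mid)
    d[-1, -1] <- abs(outer(mid, mid, `-`)) / span
  } else {
    d[-1, -1] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(0:m, 0:m)
  d
}

#' Delineate contiguity patches of a height-class map
#'
#' Groups adjacent same-class vegetated cells into patches (connected
#' components). Background (class 0) and nodata are unlabeled. Patch area is
#' cell count times cell area; patch perimeter counts every cell face not
#' shared with the same patch, including window boundary and nodata faces.
#'
#' @param class_map a `height_class_map`.
#' @param connectivity 4 or 8 (default 8, the usual patch-delineation rule).
#' @param contrast optional contrast matrix used for the per-patch edge
#'   contrast sums; defaults to [default_contrast()].
#' @return a `patch_map`: the label grid and a patch table
#'   (`patch_id`, `class_index`, `area_m2`, `perimeter_m`, plus per-patch
#'   boundary length and depth-weighted boundary length used by the edge
#'   contrast index).
#' @export
label_patches <- function(class_map, connectivity = 8, contrast = NULL) {
  stopifnot(inherits(class_map, "height_class_map"))
  cls <- class_map$class_index
  lab <- cc_label(cls, as.integer(connectivity))
  n_patch <- max(lab)
  cs <- class_map$cell_size
  if (is.null(contrast)) contrast <- default_contrast(class_map)
  if (n_patch > 0) {
    st <- patch_stats(cls, lab, contrast, n_patch)
    tab <- data.table::data.table(
      patch_id = seq_len(n_patch), class_index = st[["class"]],
      area_m2 = st$ncell * cs^2, perimeter_m = st$perim_faces * cs,
      edge_length_m = st$edge_faces * cs,
      edge_depth_sum_m = st$edge_depth_sum * cs)
  } else {
    tab <- data.table::data.table(patch_id = integer(), class_index = integer(),
                                  area_m2 = numeric(), perimeter_m = numeric(),
                                  edge_length_m = numeric(),
                                  edge_depth_sum_m = numeric())
  }
  structure(list(label = lab, patches = tab, class_map = class_map,
                 connectivity = as.integer(connectivity),
                 contrast = contrast, cell_size = cs),
            class = "patch_map")
}

#' Build the depth-weighted edge table
#'
#' Tabulates, for every unordered pair of classes, the total shared boundary
#' length between 4-adjacent cells of different classes, with its depth
#' (contrast) weight. Window-boundary and nodata faces accrue no edge.
#'
#' @param patch_map a `patch_map` from [label_patches()].
#' @param contrast optional `(m+1) x (m+1)` contrast matrix (class code
#'   0..m); defaults to [default_contrast()] of the underlying class map.
#' @param include_background include vegetated/background (class 0) edges.
#' @return `data.table` with columns `class_i`, `class_j` (`class_i <
#'   class_j`), `length_m`, `depth`.
#' @export
build_edge_table <- function(patch_map, contrast = NULL,
                             include_background = TRUE) {
  stopifnot(inherits(patch_map, "patch_map"))
  cm <- patch_map$class_map
  if (is.null(contrast)) contrast <- patch_map$contrast
  m <- cm$n_veg_class
  if (nrow(contrast) < m + 1 || ncol(contrast) < m + 1)
    stop("contrast matrix smaller than class count")
  if (any(abs(contrast - t(contrast)) > 1e-12) || any(diag(contrast) != 0))
    stop("contrast matrix must be symmetric with zero diagonal")
  cnt <- edge_face_counts(cm$class_index, m)
  idx <- which(upper.tri(cnt, diag = FALSE) & cnt > 0, arr.ind = TRUE)
  out <- data.table::data.table(
    class_i = idx[, 1] - 1L, class_j = idx[, 2] - 1L,
    length_m = cnt[idx] * patch_map$cell_size,
    depth = contrast[idx])
  if (!include_background) out <- out[out$class_i != 0L, ]
  data.table::setorderv(out, c("class_i", "class_j"))
  out[]
}
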