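# Second-order (co-occurrence) texture of the raw height grid: the joint
# probability of quantized height pairs at fixed pixel offsets. One
# whole-window GLCM per landscape; offsets are the four 1-pixel directions
# (0, 45, 90, 135 degrees), symmetric, pooled.

#' Quantize a height grid to grey levels
#'
#' Linear min-max binning of heights into `levels` integer grey levels
#' `0..levels-1` over the window's observed range; a constant window maps to
#' level 0 everywhere. Nodata stays `NA`.
#'
#' @param window a `landscape_window` or `height_raster`.
#' @param levels number of grey levels (>= 2).
#' @return integer matrix of levels, `NA` for nodata.
#' @export
quantize_heights <- function(window, levels = 32) {
  stopifnot(inherits(window, "height_raster"), levels >= 2)
  h <- window$values
  if (all(is.na(h))) stop("empty window")
  rng <- range(h, na.rm = TRUE)
  g <- matrix(NA_integer_, nrow(h), ncol(h))
  ok <- !is.na(h)
  if (rng[2] > rng[1]) {
    g[ok] <- pmin(as.integer(floor((h[ok] - rng[1]) / (rng[2] - rng[1]) *
                                     levels)), levels - 1L)
  } else {
    g[ok] <- 0L
  }
  g
}

# the four 1-pixel offsets as (row, col) displacements
glcm_default_offsets <- function() {
  matrix(c(0L, 1L,    # 0 deg
           -1L, 1L,   # 45 deg
           -1L, 0L,   # 90 deg
           -1L, -1L), # 135 deg
         ncol = 2, byrow = TRUE)
}

#' Grey-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of grey-level pairs over the given pixel
#' offsets (pooled), skipping pairs that touch nodata or leave the grid, and
#' normalizes to probabilities. With `symmetric = TRUE` each pair counts in
#' both orders.
#'
#' @param grid integer grey-level matrix from [quantize_heights()].
#' @param offsets integer matrix of `(row, col)` displacements, one per row.
#' @param levels grey level count (default inferred as `max(grid) + 1`).
#' @param symmetric symmetrize the matrix (default TRUE).
#' @return a `glcm`: the normalized probability matrix with attributes.
#' @export
compute_glcm <- function(grid, offsets = glcm_default_offsets(),
                         levels = NULL, symmetric = TRUE) {
  storage.mode(grid) <- "integer"
  if (is.null(levels)) levels <- max(grid, na.rm = TRUE) + 1L
  offsets <- matrix(as.integer(offsets), ncol = 2)
  cnt <- glcm_counts(grid, offsets, as.integer(levels), symmetric)
  tot <- sum(cnt)
  if (tot == 0) stop("no valid pixel pairs for the given offsets")
  structure(cnt / tot, class = "glcm", levels = levels,
            symmetric = symmetric, n_pairs = tot)
}

#' Texture statistics of a GLCM (metric set D)
#'
#' The five co-occurrence statistics used as texture habitat metrics, with
#' `P` the normalized co-occurrence matrix over grey levels `i, j`:
#' entropy `-sum P ln P`, contrast `sum (i-j)^2 P`, angular second moment
#' `sum P^2`, homogeneity `sum P / (1 + (i-j)^2)` and dissimilarity
#' `sum |i-j| P`.
#'
#' @param glcm a normalized GLCM from [compute_glcm()].
#' @return named numeric `(ENTROPY, CONTRAST, ASM, HOMOGENEITY,
#'   DISSIMILARITY)`.
#' @export
texture_stats <- function(glcm) {
  P <- unclass(glcm)
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  g <- nrow(P)
  d <- abs(outer(seq_len(g), seq_len(g), `-`))
  nz <- P > 0
  c(ENTROPY = -sum(P[nz] * log(P[nz])),
    CONTRAST = sum(d^2 * P),
    ASM = sum(P^2),
    HOMOGENEITY = sum(P / (1 + d^2)),
    DISSIMILARITY = sum(d * P))
}

#' All texture metrics of a landscape window
#'
#' Convenience wrapper: quantize, pool the four-direction symmetric GLCM,
#' and return the five set-D statistics.
#' @inheritParams quantize_heights
#' @export
texture_metrics <- function(window, levels = 32) {
  g <- quantize_heights(window, levels)
  texture_stats(compute_glcm(g, levels = as.integer(levels)))
}
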