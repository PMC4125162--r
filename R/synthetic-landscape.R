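#' Synthetic landscape configuration
#'
#' Parameters of the synthetic canopy-height generator. The generator
#' emulates a 30 m basal-area-weighted tree-height map: a thresholded,
#' rescaled Gaussian random field gives the vegetated mask, and vegetated
#' heights are drawn from a truncated normal and placed on the landscape by
#' rank-reordering onto a smoothed field, so that `clustering` controls how
#' strongly tall trees aggregate without changing the marginal height
#' distribution.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 8).
#' @param cell_size cell size, meters.
#' @param veg_fraction fraction of cells that are vegetated, in `[0, 1]`.
#' @param height_mean,height_sd mean / sd (meters) of vegetated heights
#'   before truncation at zero.
#' @param autocorr_range spatial correlation length of the vegetated-mask
#'   field, meters (0 = white noise).
#' @param clustering degree to which tall trees aggregate (>= 0; 0 = heights
#'   placed at random among vegetated cells). Interpreted as a Gaussian
#'   smoothing length in cells for the height-placement field.
#' @param nodata_fraction fraction of cells set to nodata, in `[0, 1]`;
#'   `veg_fraction + nodata_fraction` must be <= 1.
#' @param seed integer RNG seed; identical configs give identical rasters.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 128, grid_cols = 128, cell_size = 30,
                             veg_fraction = 0.6, height_mean = 15,
                             height_sd = 6, autocorr_range = 300,
                             clustering = 2, nodata_fraction = 0,
                             seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, veg_fraction = veg_fraction,
              height_mean = height_mean, height_sd = height_sd,
              autocorr_range = autocorr_range, clustering = clustering,
              nodata_fraction = nodata_fraction, seed = as.integer(seed))
  if (cfg$grid_rows < 8 || cfg$grid_cols < 8)
    stop("grid dimensions must be >= 8")
  if (veg_fraction < 0 || veg_fraction > 1 ||
      nodata_fraction < 0 || nodata_fraction > 1 ||
      veg_fraction + nodata_fraction > 1)
    stop("veg_fraction and nodata_fraction must lie in [0,1] and sum <= 1")
  if (autocorr_range < 0 || clustering < 0)
    stop("autocorr_range and clustering must be >= 0")
  if (height_mean <= 0 || height_sd < 0)
    stop("height_mean must be > 0 and height_sd >= 0")
  class(cfg) <- "landscape_config"
  cfg
}

# periodic Gaussian smoothing of a matrix by FFT; sigma in cells.
# sigma = 0 returns the input unchanged.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), sd = sigma)
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), sd = sigma)
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic canopy-height raster
#'
#' @param config a [landscape_config()].
#' @return a [height_raster()]; non-vegetated cells have height 0, nodata
#'   cells are `NA`.
#' @export
gen_height_raster <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc

  # vegetated mask from an autocorrelated field thresholded at the
  # (1 - veg_fraction) quantile
  sigma_mask <- config$autocorr_range / config$cell_size
  u <- gauss_smooth(matrix(stats::rnorm(n), nr, nc), sigma_mask)

  # nodata cells chosen uniformly first, disjoint from the mask quantile
  nodata <- rep(FALSE, n)
  if (config$nodata_fraction > 0)
    nodata[sample.int(n, round(config$nodata_fraction * n))] <- TRUE

  avail <- which(!nodata)
  n_veg <- round(config$veg_fraction * n)
  n_veg <- min(n_veg, length(avail))
  veg <- integer(0)
  if (n_veg > 0)
    veg <- avail[order(u[avail], decreasing = TRUE)[seq_len(n_veg)]]

  vals <- matrix(0, nr, nc)
  if (n_veg > 0) {
    # truncated-normal marginal heights
    lo <- stats::pnorm(0, config$height_mean, max(config$height_sd, 1e-12))
    h <- stats::qnorm(stats::runif(n_veg, lo, 1),
                      config$height_mean, config$height_sd)
    h <- pmax(h, 0.01)
    # placement: rank-reorder heights onto a smoothed field so tall trees
    # cluster; clustering = 0 places them at random
    t_field <- gauss_smooth(matrix(stats::rnorm(n), nr, nc),
                            config$clustering)
    vals[veg[order(t_field[veg])]] <- sort(h)
  }
  vals[nodata] <- NA_real_
  height_raster(vals, cell_size = config$cell_size)
}
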