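# Metric naming follows the FRAGSTATS abbreviations: NP, AREA, TE, ED,
# FRAC, CWED, ECON, SHDI, prefixed B. (binary vegetation map) or
# C. (height-segmented map). All densities use the non-nodata landscape
# area; SDs are population SDs (FRAGSTATS convention).

#' The 26 habitat metric names
#'
#' Names of the four metric sets in canonical order: summary height
#' statistics (A), traditional patch-based metrics (B), height-structured
#' patch-based metrics (C), and co-occurrence texture metrics (D).
#' @return character vector of length 26.
#' @export
metric_names <- function() {
  c("MEAN", "SD", "MIN", "MAX",
    "B.NP", "B.AREA.MN", "B.AREA.SD", "B.ED", "B.TE", "B.FRAC.MN",
    "B.FRAC.SD",
    "C.NP", "C.AREA.MN", "C.AREA.SD", "C.TE", "C.FRAC.MN", "C.FRAC.SD",
    "C.CWED", "C.ECON.MN", "C.ECON.SD", "C.SHDI",
    "ENTROPY", "CONTRAST", "ASM", "HOMOGENEITY", "DISSIMILARITY")
}

#' Which set a metric belongs to
#' @param names metric names; default all 26.
#' @return named character vector mapping metric name to "A".."D".
#' @export
metric_set <- function(names = metric_names()) {
  sets <- c(rep("A", 4), rep("B", 7), rep("C", 10), rep("D", 5))
  names(sets) <- metric_names()
  sets[names]
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# fractal dimension index of one patch: 2 ln(0.25 P) / ln(A), P in m, A in
# m^2; exactly 1 for squares. Undefined when A = 1 m^2 (ln A = 0).
frac_dim <- function(perimeter_m, area_m2) {
  out <- 2 * log(0.25 * perimeter_m) / log(area_m2)
  out[area_m2 == 1] <- NA_real_
  out
}

#' Summary height statistics (metric set A)
#'
#' Mean, population standard deviation, minimum and maximum of canopy height
#' over vegetated (height > cutoff), non-nodata cells.
#'
#' @param window a `landscape_window` or `height_raster`.
#' @param veg_cutoff vegetation height cutoff (default 0 m).
#' @return named numeric `(MEAN, SD, MIN, MAX)`; all `NA` when the window
#'   has no vegetated cell.
#' @export
summary_stats <- function(window, veg_cutoff = 0) {
  stopifnot(inherits(window, "height_raster"))
  h <- window$values
  h <- h[!is.na(h) & h > veg_cutoff]
  if (!length(h))
    return(c(MEAN = NA_real_, SD = NA_real_, MIN = NA_real_, MAX = NA_real_))
  c(MEAN = mean(h), SD = pop_sd(h), MIN = min(h), MAX = max(h))
}

# shared patch-structure summaries for sets B and C
patch_structure <- function(patch_map) {
  p <- patch_map$patches
  list(np = nrow(p),
       area_mn = mean(p$area_m2) / 1e4,     # ha
       area_sd = pop_sd(p$area_m2 / 1e4),
       frac = frac_dim(p$perimeter_m, p$area_m2))
}

#' Traditional patch-based metrics (metric set B)
#'
#' Patch metrics of the binary vegetated / non-vegetated map: number of
#' patches, mean/SD patch area (ha), total vegetated edge (m), edge density
#' (m/ha) and mean/SD fractal dimension index. Edges are faces between
#' vegetated and background cells; window boundary and nodata faces do not
#' count.
#'
#' @param patch_map a `patch_map` built from [classify_binary()].
#' @param landscape_area_m2 non-nodata landscape area, m^2.
#' @return named numeric of the 7 set-B metrics.
#' @export
patch_metrics_2d <- function(patch_map, landscape_area_m2) {
  stopifnot(inherits(patch_map, "patch_map"))
  if (patch_map$class_map$n_veg_class != 1L)
    stop("set B requires the binary vegetation classification")
  s <- patch_structure(patch_map)
  if (s$np == 0)
    return(c(B.NP = 0, B.AREA.MN = NA_real_, B.AREA.SD = NA_real_,
             B.ED = NA_real_, B.TE = NA_real_, B.FRAC.MN = NA_real_,
             B.FRAC.SD = NA_real_))
  cnt <- edge_face_counts(patch_map$class_map$class_index, 1L)
  te <- cnt[1, 2] * patch_map$cell_size
  c(B.NP = s$np, B.AREA.MN = s$area_mn, B.AREA.SD = s$area_sd,
    B.ED = te / (landscape_area_m2 / 1e4), B.TE = te,
    B.FRAC.MN = mean(s$frac, na.rm = TRUE),
    B.FRAC.SD = pop_sd(s$frac))
}

#' Height-structured patch-based metrics (metric set C)
#'
#' Patch and depth-weighted edge metrics of the height-segmented map. In
#' addition to the set-B analogues computed over height-class patches:
#' * `C.CWED`: contrast-weighted edge density, `sum(e_ik * d_ik) / A` in
#'   m/ha, summing every inter-class face (vegetated/background faces carry
#'   depth 1);
#' * `C.ECON.MN/SD`: mean/SD over patches of the edge contrast index, the
#'   length-weighted mean depth of a patch's boundary (patches whose whole
#'   boundary is window border or nodata have no defined ECON and are
#'   dropped);
#' * `C.SHDI`: Shannon's diversity index over vegetated-class area
#'   proportions.
#'
#' @param patch_map a `patch_map` built from [classify_height()].
#' @param edges edge table from [build_edge_table()] including background
#'   edges.
#' @param landscape_area_m2 non-nodata landscape area, m^2.
#' @return named numeric of the 10 set-C metrics.
#' @export
patch_metrics_height <- function(patch_map, edges, landscape_area_m2) {
  stopifnot(inherits(patch_map, "patch_map"))
  s <- patch_structure(patch_map)
  if (s$np == 0)
    return(stats::setNames(c(0, rep(NA_real_, 9)),
                           c("C.NP", "C.AREA.MN", "C.AREA.SD", "C.TE",
                             "C.FRAC.MN", "C.FRAC.SD", "C.CWED",
                             "C.ECON.MN", "C.ECON.SD", "C.SHDI")))
  te <- sum(edges$length_m)
  cwed <- sum(edges$length_m * edges$depth) / (landscape_area_m2 / 1e4)
  p <- patch_map$patches
  econ <- ifelse(p$edge_length_m > 0,
                 p$edge_depth_sum_m / p$edge_length_m, NA_real_)
  area_by_class <- tapply(p$area_m2, p$class_index, sum)
  prop <- area_by_class / sum(area_by_class)
  shdi <- -sum(prop * log(prop))
  c(C.NP = s$np, C.AREA.MN = s$area_mn, C.AREA.SD = s$area_sd,
    C.TE = te, C.FRAC.MN = mean(s$frac, na.rm = TRUE),
    C.FRAC.SD = pop_sd(s$frac), C.CWED = cwed,
    C.ECON.MN = if (all(is.na(econ))) NA_real_ else mean(econ, na.rm = TRUE),
    C.ECON.SD = pop_sd(econ), C.SHDI = shdi)
}

#' Compute all 26 habitat metrics for one landscape
#'
#' Runs the four metric sets on a landscape window: summary height
#' statistics (A), traditional patch metrics on the binary vegetation map
#' (B), height-structured patch/edge metrics on the height-segmented map
#' (C), and grey-level co-occurrence texture metrics of the raw height grid
#' (D).
#'
#' @param window a `landscape_window` or `height_raster`.
#' @param thresholds height-class boundaries, meters.
#' @param veg_cutoff vegetation cutoff, meters.
#' @param connectivity patch connectivity (default 8).
#' @param contrast optional contrast matrix (default [default_contrast()]).
#' @param glcm_levels grey levels for the texture set (default 32).
#' @return named numeric vector of the 26 metrics, in [metric_names()]
#'   order.
#' @export
compute_metrics <- function(window, thresholds = c(5, 10, 15, 25),
                            veg_cutoff = 0, connectivity = 8,
                            contrast = NULL, glcm_levels = 32) {
  stopifnot(inherits(window, "height_raster"))
  area <- landscape_area_m2(window)
  a <- summary_stats(window, veg_cutoff)

  pm_b <- label_patches(classify_binary(window, veg_cutoff), connectivity)
  b <- patch_metrics_2d(pm_b, area)

  cm <- classify_height(window, thresholds, veg_cutoff)
  pm_c <- label_patches(cm, connectivity, contrast)
  edges <- build_edge_table(pm_c, contrast)
  cc <- patch_metrics_height(pm_c, edges, area)

  d <- texture_metrics(window, levels = glcm_levels)

  out <- c(a, b, cc, d)
  out[metric_names()]
}
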