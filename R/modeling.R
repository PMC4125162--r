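# Richness model comparison: correlation screen, selection of the
# best-performing height-structured metrics (BPHMs: 2 from set C + 2 from
# set D by mean |r| across guilds), six linear model configurations with
# BCa bootstrap intervals for adjusted-r2 and AIC, and the parallel
# random-forest suite (2000 trees) with OOB permutation importance.

#' Pearson correlation of each metric with each guild's richness
#'
#' @param metrics data.frame/data.table with `route_id` and metric columns.
#' @param richness output of [mean_richness()] (`route_id`, `guild`,
#'   `mean_richness`).
#' @param metric_cols metric columns to use; default every column of
#'   `metrics` except `route_id` that is in [metric_names()], falling back
#'   to all non-id numeric columns.
#' @return `data.table` (`metric`, `guild`, `r`, `n`); zero-variance
#'   metrics give `NA` with a warning.
#' @export
correlate <- function(metrics, richness, metric_cols = NULL) {
  mt <- data.table::as.data.table(metrics)
  rc <- data.table::as.data.table(richness)
  if (is.null(metric_cols)) {
    metric_cols <- intersect(names(mt), metric_names())
    if (!length(metric_cols)) metric_cols <- setdiff(names(mt), "route_id")
  }
  out <- list()
  for (g in unique(rc$guild)) {
    sub <- merge(rc[rc$guild == g, c("route_id", "mean_richness")], mt,
                 by = "route_id")
    if (nrow(sub) < 3) stop("need >= 3 complete route rows per guild")
    r <- vapply(metric_cols, function(m) {
      x <- sub[[m]]
      if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) return(NA_real_)
      stats::cor(x, sub$mean_richness, use = "complete.obs")
    }, 1.0)
    out[[g]] <- data.table::data.table(metric = metric_cols, guild = g,
                                       r = r, n = nrow(sub))
  }
  res <- data.table::rbindlist(out)
  if (anyNA(res$r)) warning("zero-variance metric(s): correlation set to NA")
  res[]
}

#' Select the best-performing height-structured metrics (BPHMs)
#'
#' From the correlation table, picks the 2 metrics of set C and the 2 of
#' set D with the highest mean `|r|` across guilds. Ties break
#' alphabetically with a warning.
#'
#' @param cor_table output of [correlate()] covering all set C and D
#'   metrics for every guild.
#' @return character vector of 4 metric names (2 from C, 2 from D).
#' @export
select_bphm <- function(cor_table) {
  ct <- data.table::as.data.table(cor_table)
  sets <- metric_set()
  pick <- function(set_id) {
    cand <- names(sets)[sets == set_id]
    sub <- ct[ct$metric %in% cand, ]
    if (!all(cand %in% sub$metric))
      stop("correlations missing for some set ", set_id, " metrics")
    sc <- sub[, list(score = mean(abs(r))), by = "metric"]
    if (anyNA(sc$score)) stop("missing guild correlation for set ", set_id)
    data.table::setorderv(sc, c("score", "metric"), order = c(-1, 1))
    if (nrow(sc) > 2 && sc$score[2] == sc$score[3])
      warning("tie in mean |r| for set ", set_id,
              "; broken alphabetically")
    sc$metric[1:2]
  }
  c(pick("C"), pick("D"))
}

#' The predictor sets of the model suite
#'
#' The six configurations compared for each guild (plus `ALL` for the
#' random forest): each of the four metric sets alone, and sets A and B
#' each combined with the four BPHMs.
#' @param bphm character vector of 4 BPHM names.
#' @return named list of predictor name vectors.
#' @export
predictor_sets <- function(bphm) {
  sets <- metric_set()
  base <- lapply(c(A = "A", B = "B", C = "C", D = "D"),
                 function(s) names(sets)[sets == s])
  c(base,
    list(`A+BPHM` = unique(c(base$A, bphm)),
         `B+BPHM` = unique(c(base$B, bphm)),
         ALL = names(sets)))
}

#' Ordinary least squares richness model
#'
#' Fits `mean_richness ~ predictors` by OLS and reports adjusted r-squared
#' and the Gaussian profile AIC `n log(RSS/n) + 2 (p + 2)` (constant
#' convention is internal; only differences between models matter).
#'
#' @param data data.frame with the response column and predictors.
#' @param predictors character vector of predictor columns.
#' @param response response column name (default `"mean_richness"`).
#' @return list with `adj_r2`, `aic`, `n`, `p`, and the `lm` fit.
#' @export
fit_linear <- function(data, predictors, response = "mean_richness") {
  df <- stats::na.omit(as.data.frame(data)[, c(response, predictors)])
  n <- nrow(df); p <- length(predictors)
  if (n <= p + 2) stop("need n > p + 2 complete rows")
  fml <- stats::reformulate(sprintf("`%s`", predictors), response)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-10 * sum((df[[response]] - mean(df[[response]]))^2) ||
      rss == 0)
    stop("degenerate fit: residual sum of squares is (near) zero")
  r2 <- summary(fit)$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  aic <- n * log(rss / n) + 2 * (p + 2)
  list(adj_r2 = adj, aic = aic, r2 = r2, n = n, p = p, fit = fit)
}

# statistic evaluators used by the bootstrap
lm_statistic <- function(data, predictors, response, what = c("adj_r2", "aic")) {
  what <- match.arg(what)
  function(idx) {
    f <- try(fit_linear(data[idx, , drop = FALSE], predictors, response),
             silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    f[[what]]
  }
}

#' BCa bootstrap interval for a model statistic
#'
#' Case-resampling bootstrap over routes with the bias-corrected and
#' accelerated interval: the bias correction `z0` comes from the proportion
#' of bootstrap statistics below the full-sample estimate and the
#' acceleration `a` from the jackknife skewness of the statistic. Falls
#' back to the percentile interval (with a warning) when the bootstrap
#' distribution is degenerate.
#'
#' @param data data.frame of route-level rows.
#' @param predictors,response as in [fit_linear()].
#' @param statistic `"adj_r2"` or `"aic"`.
#' @param n_boot bootstrap replicates (default 3000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `point`, `lo`, `hi`, `z0`, `a`, `n_boot`, `boot`
#'   (the replicate values).
#' @export
bootstrap_bca <- function(data, predictors, response = "mean_richness",
                          statistic = c("adj_r2", "aic"), n_boot = 3000,
                          level = 0.95, seed = 1L) {
  statistic <- match.arg(statistic)
  data <- stats::na.omit(as.data.frame(data)[, c(response, predictors)])
  n <- nrow(data)
  if (n < 20) stop("need n >= 20 for the bootstrap")
  stat <- lm_statistic(data, predictors, response, statistic)
  t0 <- stat(seq_len(n))
  set.seed(seed)
  tb <- vapply(seq_len(n_boot),
               function(b) stat(sample.int(n, n, replace = TRUE)), 1.0)
  tb <- tb[!is.na(tb)]
  tj <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)), 1.0)
  c(list(point = t0), bca_interval(t0, tb, tj, level), list(boot = tb))
}

#' BCa interval from bootstrap and jackknife replicates
#'
#' The interval machinery behind [bootstrap_bca()], usable for any scalar
#' statistic: bias correction `z0 = qnorm(#(t* < t0) / B)`, acceleration
#' `a = sum((tbar - t_i)^3) / (6 * sum((tbar - t_i)^2)^1.5)` from jackknife
#' replicates, and adjusted percentile endpoints.
#'
#' @param t0 full-sample statistic.
#' @param tb bootstrap replicate statistics.
#' @param tj jackknife (leave-one-out) replicate statistics.
#' @param level confidence level.
#' @return list with `lo`, `hi`, `z0`, `a`, `n_boot`.
#' @export
bca_interval <- function(t0, tb, tj, level = 0.95) {
  tb <- tb[!is.na(tb)]
  alpha <- (1 - level) / 2
  if (length(unique(tb)) == 1)
    return(list(lo = tb[1], hi = tb[1], z0 = 0, a = 0,
                n_boot = length(tb)))
  prop <- mean(tb < t0)
  if (prop == 0 || prop == 1) {
    warning("degenerate bootstrap distribution; percentile fallback")
    q <- stats::quantile(tb, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(list(lo = q[1], hi = q[2], z0 = NA_real_, a = NA_real_,
                n_boot = length(tb)))
  }
  z0 <- stats::qnorm(prop)
  tj <- tj[!is.na(tj)]
  dm <- mean(tj) - tj
  denom <- 6 * sum(dm^2)^1.5
  a <- if (denom == 0) 0 else sum(dm^3) / denom
  za <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  q <- stats::quantile(tb, adj, names = FALSE, type = 6)
  list(lo = q[1], hi = q[2], z0 = z0, a = a, n_boot = length(tb))
}

#' Random-forest richness model
#'
#' Regression random forest (CART trees on bootstrap samples with random
#' feature subsets). Reports the OOB explained variance
#' `1 - OOB MSE / Var(y)` and the permutation importance of each metric as
#' %IncMSE: the mean increase of a tree's OOB MSE when the metric is
#' permuted among its OOB cases, as a percentage of the mean per-tree OOB
#' MSE.
#'
#' @param data data.frame with the response and metric columns.
#' @param predictors character vector of predictor columns.
#' @param response response column (default `"mean_richness"`).
#' @param n_trees trees in the forest (default 2000, enough for the OOB
#'   residual error to converge).
#' @param mtry variables tried per split; default `max(1, floor(p / 3))`.
#' @param nodesize minimal node size to attempt a split (default 5).
#' @param seed integer seed (forest has its own RNG stream).
#' @return list with `var_explained`, `oob_mse`, `importance` (named
#'   %IncMSE vector, decreasing), `n`, `n_trees`, `mtry`, `seed`.
#' @export
fit_rf <- function(data, predictors, response = "mean_richness",
                   n_trees = 2000, mtry = NULL, nodesize = 5, seed = 1L) {
  df <- stats::na.omit(as.data.frame(data)[, c(response, predictors)])
  n <- nrow(df)
  if (n < 5) stop("too few complete rows")
  if (n_trees < 100)
    warning("n_trees < 100: OOB residual error may not have converged")
  p <- length(predictors)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  X <- as.matrix(df[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  res <- rf_regress(X, as.numeric(df[[response]]), as.integer(n_trees),
                    as.integer(mtry), as.integer(nodesize),
                    as.integer(seed))
  imp <- sort(stats::setNames(res$importance, predictors),
              decreasing = TRUE)
  list(var_explained = res$var_explained, oob_mse = res$oob_mse,
       importance = imp, n = n, n_trees = n_trees, mtry = mtry,
       nodesize = nodesize, seed = seed)
}

#' Run the full model-comparison suite
#'
#' For each guild: correlation screen, BPHM selection (2 from set C, 2 from
#' set D by mean |r| across guilds), the six linear configurations
#' `{A, B, C, D, A+BPHM, B+BPHM}` with BCa intervals for adjusted-r2 and
#' AIC, and random forests on the same six plus the all-inclusive 26-metric
#' model.
#'
#' @param metrics per-route metric table (`route_id` + 26 metrics).
#' @param richness output of [mean_richness()].
#' @param n_boot bootstrap replicates (default 3000).
#' @param n_trees random-forest trees (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed master seed; per-model seeds derive from it.
#' @return list with `results` (one row per fitted model: guild, type,
#'   predictor set, adj_r2 + CI, AIC + CI, var_explained), `importance`
#'   (long table of RF %IncMSE), `bphm`, `correlations`.
#' @export
run_model_suite <- function(metrics, richness, n_boot = 3000,
                            n_trees = 2000, level = 0.95, seed = 1L) {
  cors <- correlate(metrics, richness)
  bphm <- select_bphm(cors)
  psets <- predictor_sets(bphm)
  mt <- data.table::as.data.table(metrics)
  rc <- data.table::as.data.table(richness)
  guilds <- unique(rc$guild)
  rows <- list(); imp_rows <- list()
  for (gi in seq_along(guilds)) {
    g <- guilds[gi]
    dat <- as.data.frame(merge(rc[rc$guild == g,
                                  c("route_id", "mean_richness")], mt,
                               by = "route_id"))
    for (si in seq_along(psets)) {
      ps_name <- names(psets)[si]
      ps <- psets[[si]]
      sub_seed <- (seed * 1000L + gi * 100L + si) %% .Machine$integer.max
      if (ps_name != "ALL") {
        lf <- fit_linear(dat, ps)
        ci_r2 <- bootstrap_bca(dat, ps, statistic = "adj_r2",
                               n_boot = n_boot, level = level,
                               seed = sub_seed)
        ci_aic <- bootstrap_bca(dat, ps, statistic = "aic",
                                n_boot = n_boot, level = level,
                                seed = sub_seed + 1L)
        rows[[length(rows) + 1]] <- data.table::data.table(
          guild = g, model = "linear", predictor_set = ps_name,
          n_predictors = length(ps), adj_r2 = lf$adj_r2,
          adj_r2_lo = ci_r2$lo, adj_r2_hi = ci_r2$hi, aic = lf$aic,
          aic_lo = ci_aic$lo, aic_hi = ci_aic$hi,
          var_explained = NA_real_)
      }
      rf <- fit_rf(dat, ps, n_trees = n_trees, seed = sub_seed)
      rows[[length(rows) + 1]] <- data.table::data.table(
        guild = g, model = "rf", predictor_set = ps_name,
        n_predictors = length(ps), adj_r2 = NA_real_,
        adj_r2_lo = NA_real_, adj_r2_hi = NA_real_, aic = NA_real_,
        aic_lo = NA_real_, aic_hi = NA_real_,
        var_explained = rf$var_explained)
      imp_rows[[length(imp_rows) + 1]] <- data.table::data.table(
        guild = g, predictor_set = ps_name,
        metric = names(rf$importance), inc_mse_pct = unname(rf$importance))
    }
  }
  list(results = data.table::rbindlist(rows),
       importance = data.table::rbindlist(imp_rows),
       bphm = bphm, correlations = cors,
       settings = list(n_boot = n_boot, n_trees = n_trees, level = level,
                       seed = seed))
}
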