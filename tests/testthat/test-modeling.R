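rich_of <- function(y, ids) data.table::data.table(
  route_id = ids, guild = "all", n_years = 5, mean_richness = y)

test_that("correlate matches the covariance formula and flags degeneracy", {
  set.seed(1)
  n <- 60
  mt <- data.table::data.table(route_id = 1:n, X1 = rnorm(n),
                               X2 = runif(n), X3 = 1)
  y <- 2 * mt$X1
  ct <- correlate(mt, rich_of(y, 1:n), metric_cols = c("X1", "X2"))
  expect_equal(ct$r[ct$metric == "X1"], 1)
  # direct covariance-formula oracle
  r_manual <- sum((mt$X2 - mean(mt$X2)) * (y - mean(y))) /
    sqrt(sum((mt$X2 - mean(mt$X2))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r[ct$metric == "X2"], r_manual)

  expect_warning(
    ct3 <- correlate(mt, rich_of(y, 1:n), metric_cols = c("X1", "X3")),
    "zero-variance")
  expect_true(is.na(ct3$r[ct3$metric == "X3"]))
})

test_that("null metrics rarely exceed the 3/sqrt(n) band", {
  set.seed(2)
  n <- 500
  hits <- 0
  for (i in 1:20) {
    mt <- data.table::data.table(route_id = 1:n, X = rnorm(n))
    ct <- correlate(mt, rich_of(rnorm(n), 1:n), metric_cols = "X")
    if (abs(ct$r) >= 3 / sqrt(n)) hits <- hits + 1
  }
  expect_lte(hits, 2)  # ~99% of seeds stay inside the band
})

fake_cor_table <- function(vals) {
  sets <- metric_set()
  cd <- names(sets)[sets %in% c("C", "D")]
  out <- data.table::CJ(metric = cd, guild = c("g1", "g2", "g3"))
  out$r <- 0.05
  for (m in names(vals)) out$r[out$metric == m] <- vals[[m]]
  out$n <- 100
  out
}

test_that("select_bphm picks top-2 per set with alphabetical tie-break", {
  ct <- fake_cor_table(list(C.TE = 0.8, C.CWED = -0.7, ENTROPY = 0.9,
                            ASM = -0.85))
  expect_setequal(select_bphm(ct), c("C.TE", "C.CWED", "ENTROPY", "ASM"))

  # invariant to guild row order
  ct2 <- ct[order(ct$guild, decreasing = TRUE), ]
  expect_setequal(select_bphm(ct2), select_bphm(ct))

  # all equal: alphabetical first two per set, with a warning
  ct3 <- fake_cor_table(list())
  expect_warning(b <- select_bphm(ct3), "tie")
  sets <- metric_set()
  expect_equal(b, c(sort(names(sets)[sets == "C"])[1:2],
                    sort(names(sets)[sets == "D"])[1:2]))

  expect_error(select_bphm(ct[ct$metric != "C.NP", ]), "missing")
})

test_that("fit_linear reproduces lm's adjusted r2 and AIC differences", {
  set.seed(3)
  n <- 40
  d <- data.frame(mean_richness = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
  d$mean_richness <- 2 + d$x1 + 0.5 * d$x2 + rnorm(n)
  f1 <- fit_linear(d, "x1")
  f2 <- fit_linear(d, c("x1", "x2"))
  o1 <- lm(mean_richness ~ x1, d)
  o2 <- lm(mean_richness ~ x1 + x2, d)
  expect_equal(f1$adj_r2, summary(o1)$adj.r.squared)
  expect_equal(f2$adj_r2, summary(o2)$adj.r.squared)
  # AIC constant convention differs; differences must agree exactly
  expect_equal(f2$aic - f1$aic, AIC(o2) - AIC(o1))
  # closed form: adj = 1 - (1 - R2)(n-1)/(n-p-1)
  expect_equal(f1$adj_r2, 1 - (1 - f1$r2) * (n - 1) / (n - 2))

  # degenerate and rank-deficient designs are errors
  d$yc <- d$mean_richness
  expect_error(fit_linear(d, "yc"), "degenerate")
  d$x3 <- d$x1
  expect_error(fit_linear(d, c("x1", "x3")), "collinear")
})

test_that("OLS recovers planted coefficients within 3 SE", {
  set.seed(4)
  n <- 500
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(1.5, -2, 0.7)
  d <- data.frame(mean_richness = drop(X %*% beta) + rnorm(n), X)
  f <- fit_linear(d, c("a", "b", "c"))
  cf <- summary(f$fit)$coefficients
  expect_true(all(abs(cf[-1, "Estimate"] - beta) <
                    3 * cf[-1, "Std. Error"]))
  # adding predictors never lowers raw R2 (adj may fall)
  f2 <- fit_linear(cbind(d, junk = rnorm(n)), c("a", "b", "c", "junk"))
  expect_gte(f2$r2, f$r2)
})

test_that("BCa intervals are reproducible and match boot's on lm adj-r2", {
  set.seed(5)
  n <- 60
  d <- data.frame(mean_richness = rnorm(n), x = rnorm(n))
  d$mean_richness <- 1 + 0.8 * d$x + rnorm(n)
  ci1 <- bootstrap_bca(d, "x", statistic = "adj_r2", n_boot = 400,
                       seed = 11)
  ci2 <- bootstrap_bca(d, "x", statistic = "adj_r2", n_boot = 400,
                       seed = 11)
  expect_identical(ci1[c("lo", "hi")], ci2[c("lo", "hi")])
  expect_lte(ci1$lo, ci1$point)
  expect_gte(ci1$hi, ci1$point)

  skip_if_not_installed("boot")
  stat <- function(dd, idx) {
    f <- lm(mean_richness ~ x, dd[idx, ])
    summary(f)$adj.r.squared
  }
  set.seed(99)
  b <- boot::boot(d, stat, R = 2000)
  bc <- boot::boot.ci(b, type = "bca")$bca[4:5]
  ci <- bootstrap_bca(d, "x", statistic = "adj_r2", n_boot = 2000,
                      seed = 12)
  expect_lt(abs(ci$lo - bc[1]), 0.06)
  expect_lt(abs(ci$hi - bc[2]), 0.06)
})

test_that("BCa machinery beats percentile coverage for a skewed statistic", {
  # toy: mean of a log-normal, true value exp(0.5)
  set.seed(6)
  truth <- exp(0.5)
  n <- 200; B <- 400; reps <- 250
  cover_bca <- cover_pct <- 0
  for (r in 1:reps) {
    x <- rlnorm(n)
    t0 <- mean(x)
    tb <- vapply(1:B, function(b) mean(sample(x, n, TRUE)), 1.0)
    tj <- vapply(1:n, function(i) mean(x[-i]), 1.0)
    ci <- bca_interval(t0, tb, tj)
    q <- quantile(tb, c(0.025, 0.975), names = FALSE, type = 6)
    cover_bca <- cover_bca + (truth >= ci$lo && truth <= ci$hi)
    cover_pct <- cover_pct + (truth >= q[1] && truth <= q[2])
  }
  expect_gte(cover_bca, cover_pct)
  # BCa coverage within binomial tolerance of nominal 95%
  expect_gt(cover_bca / reps, 0.95 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("constant bootstrap distribution collapses to a point interval", {
  ci <- bca_interval(1, rep(1, 100), rep(1, 20))
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
})

test_that("random forest behaves on noise, planted signal, and reruns", {
  set.seed(7)
  n <- 500; p <- 26
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, metric_names()))
  d0 <- data.frame(mean_richness = rnorm(n), X, check.names = FALSE)
  f0 <- fit_rf(d0, metric_names(), n_trees = 300, seed = 1)
  expect_lte(f0$var_explained, 0.05)

  # response a deterministic function of 2 of the 26 metrics
  y <- 2 * X[, "C.CWED"] - 3 * X[, "ENTROPY"]
  d1 <- data.frame(mean_richness = y, X, check.names = FALSE)
  f1 <- fit_rf(d1, metric_names(), n_trees = 300, seed = 1)
  expect_setequal(names(f1$importance)[1:2], c("C.CWED", "ENTROPY"))
  expect_gt(f1$var_explained, 0.7)

  # determinism under a fixed seed; stability across seeds
  f1b <- fit_rf(d1, metric_names(), n_trees = 300, seed = 1)
  expect_identical(f1$importance, f1b$importance)
  f2 <- fit_rf(d1, metric_names(), n_trees = 2000, seed = 2)
  f3 <- fit_rf(d1, metric_names(), n_trees = 2000, seed = 3)
  expect_lt(abs(f2$var_explained - f3$var_explained), 0.03)

  expect_warning(fit_rf(d1, metric_names(), n_trees = 50, seed = 1),
                 "converged")
})

test_that("run_model_suite emits 6 linear + 7 RF rows per guild", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 26), n, 26, dimnames = list(NULL, metric_names()))
  mt <- data.table::data.table(route_id = 1:n)
  mt <- cbind(mt, data.table::as.data.table(X))
  rc <- data.table::rbindlist(lapply(c("g1", "g2"), function(g)
    data.table::data.table(route_id = 1:n, guild = g, n_years = 5,
                           mean_richness = 20 + 2 * X[, "ENTROPY"] +
                             rnorm(n))))
  suite <- run_model_suite(mt, rc, n_boot = 60, n_trees = 120, seed = 4)
  res <- suite$results
  for (g in c("g1", "g2")) {
    expect_equal(sum(res$guild == g & res$model == "linear"), 6L)
    expect_equal(sum(res$guild == g & res$model == "rf"), 7L)
  }
  expect_length(suite$bphm, 4L)
  expect_true(all(res$adj_r2[res$model == "linear"] <= 1))
  # reproducible end to end under the master seed
  suite2 <- run_model_suite(mt, rc, n_boot = 60, n_trees = 120, seed = 4)
  expect_identical(suite$results, suite2$results)
})
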