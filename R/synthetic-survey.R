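#' Synthetic survey configuration
#'
#' Parameters of the synthetic stop-level survey generator, emulating a
#' 50-stop roadside point-count protocol. True route richness is linear in
#' standardized habitat metrics plus Gaussian noise; guild structure is
#' emulated by three overlapping species pools (broad "woodland", a
#' "forest_edge" pool, and a smaller "interior_forest" pool) whose responses
#' to the habitat metrics are scaled copies of the configured effect vector.
#'
#' @param n_routes number of survey routes.
#' @param n_stops occasions (stops) per route-year (default 50).
#' @param n_species_pool total species pool size.
#' @param years survey years (default 1998:2002).
#' @param detect_prob_range range of species-specific per-occasion detection
#'   probabilities, within `(0, 1]`.
#' @param detectability_range range of the route-year detectability
#'   multiplier applied to every species' detection probability, within
#'   `(0, 1]`. Emulates observer skill and survey-condition differences
#'   between routes and years, which is what makes detection-adjusted
#'   richness estimators worthwhile; `c(1, 1)` disables it.
#' @param effect_metrics names of metrics driving richness (subset of
#'   [metric_names()] or of the supplied metrics table's columns).
#' @param effect_sizes effect (species per SD of metric) per effect metric.
#' @param noise_sd SD of route-level richness noise.
#' @param intercept mean richness of the largest pool at average habitat;
#'   default 40% of the pool size.
#' @param guild_effect_scale named multipliers of the effect vector per
#'   guild.
#' @param first_year_observer_rate probability a route-year is surveyed by a
#'   first-year observer.
#' @param unacceptable_rate probability a route-year fails the survey
#'   quality standard.
#' @param seed integer RNG seed.
#' @return a `survey_config` list.
#' @export
survey_config <- function(n_routes = 100, n_stops = 50, n_species_pool = 80,
                          years = 1998:2002,
                          detect_prob_range = c(0.2, 0.8),
                          detectability_range = c(0.05, 0.5),
                          effect_metrics = character(),
                          effect_sizes = numeric(), noise_sd = 2,
                          intercept = NULL,
                          guild_effect_scale = c(woodland = 1,
                                                 forest_edge = 0.8,
                                                 interior_forest = 0.15),
                          first_year_observer_rate = 0.1,
                          unacceptable_rate = 0.05, seed = 1L) {
  if (n_stops < 2) stop("n_stops must be >= 2")
  if (length(effect_metrics) != length(effect_sizes))
    stop("effect_metrics and effect_sizes lengths differ")
  if (any(detect_prob_range <= 0) || any(detect_prob_range > 1) ||
      detect_prob_range[1] > detect_prob_range[2])
    stop("detect_prob_range must be an interval within (0, 1]")
  if (any(detectability_range <= 0) || any(detectability_range > 1) ||
      detectability_range[1] > detectability_range[2])
    stop("detectability_range must be an interval within (0, 1]")
  if (first_year_observer_rate < 0 || first_year_observer_rate > 1 ||
      unacceptable_rate < 0 || unacceptable_rate > 1)
    stop("flag rates must be proportions")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- list(n_routes = as.integer(n_routes), n_stops = as.integer(n_stops),
              n_species_pool = as.integer(n_species_pool),
              years = as.integer(years),
              detect_prob_range = as.numeric(detect_prob_range),
              detectability_range = as.numeric(detectability_range),
              effect_metrics = as.character(effect_metrics),
              effect_sizes = as.numeric(effect_sizes),
              noise_sd = noise_sd,
              intercept = intercept %||% round(0.4 * n_species_pool),
              guild_effect_scale = guild_effect_scale,
              first_year_observer_rate = first_year_observer_rate,
              unacceptable_rate = unacceptable_rate, seed = as.integer(seed))
  class(cfg) <- "survey_config"
  cfg
}

#' Generate a synthetic stop-level detection table
#'
#' Draws, per route and guild, a true species richness
#' `round(intercept_g + sum(effect * standardized metric) + N(0, noise_sd))`
#' clipped to `[1, pool size]`, selects that many species from the guild's
#' pool (presence fixed across years), and detects each present species at
#' each stop with its species-specific detection probability. Route-year
#' quality flags are independent Bernoulli draws.
#'
#' @param config a [survey_config()].
#' @param metrics_per_route data.frame/data.table with `route_id` and one
#'   column per habitat metric; must contain every configured effect metric
#'   and every route.
#' @return a `survey_data` list: `$detections` (one row per detection
#'   event: `route_id`, `year`, `observer_id`, `first_year_flag`,
#'   `acceptable_flag`, `species_id`, `occasion_index`, `detected`),
#'   `$truth` (`route_id`, `guild`, `target_richness` -- the drawn linear
#'   model value -- and `true_richness`, the realized count of guild
#'   members present), `$species`
#'   (`species_id`, `detect_prob` and guild memberships), `$guilds` (named
#'   list of species ids) and `$config`.
#' @export
gen_survey_table <- function(config, metrics_per_route) {
  stopifnot(inherits(config, "survey_config"))
  mt <- data.table::as.data.table(metrics_per_route)
  if (!"route_id" %in% names(mt)) stop("metrics_per_route needs route_id")
  missing <- setdiff(config$effect_metrics, names(mt))
  if (length(missing))
    stop("unknown effect metric(s): ", paste(missing, collapse = ", "))
  if (nrow(mt) < config$n_routes)
    stop("metrics_per_route must cover every route")
  mt <- mt[seq_len(config$n_routes), ]
  set.seed(config$seed)

  n_sp <- config$n_species_pool
  # overlapping guild pools; species in no pool default to the broad one
  member <- cbind(woodland = stats::runif(n_sp) < 0.75,
                  forest_edge = stats::runif(n_sp) < 0.35,
                  interior_forest = stats::runif(n_sp) < 0.2)
  member[rowSums(member) == 0, "woodland"] <- TRUE
  guilds <- lapply(colnames(member), function(g) which(member[, g]))
  names(guilds) <- colnames(member)
  detect_prob <- stats::runif(n_sp, config$detect_prob_range[1],
                              config$detect_prob_range[2])

  # linear predictor from standardized effect metrics
  lp <- rep(0, config$n_routes)
  for (i in seq_along(config$effect_metrics)) {
    x <- mt[[config$effect_metrics[i]]]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    lp <- lp + config$effect_sizes[i] * z
  }

  scales <- config$guild_effect_scale[names(guilds)]
  pool_sizes <- vapply(guilds, length, 1L)
  intercepts <- round(config$intercept * pool_sizes / max(pool_sizes))

  target <- list(); presence <- vector("list", config$n_routes)
  for (g in names(guilds)) {
    mu <- intercepts[[g]] + scales[[g]] * lp +
      stats::rnorm(config$n_routes, 0, config$noise_sd)
    rich <- pmin(pmax(round(mu), 1L), pool_sizes[[g]])
    target[[g]] <- data.table::data.table(route_id = mt$route_id,
                                          guild = g,
                                          target_richness = as.integer(rich))
    for (r in seq_len(config$n_routes)) {
      sel <- sample(guilds[[g]], rich[r])
      presence[[r]] <- c(presence[[r]], sel)
    }
  }
  presence <- lapply(presence, function(x) sort(unique(x)))
  truth <- data.table::rbindlist(target)
  # realized richness: guild members actually present (pools overlap, so a
  # guild can exceed its own draw through species shared with other pools)
  truth$true_richness <- vapply(seq_len(nrow(truth)), function(i) {
    r <- match(truth$route_id[i], mt$route_id)
    sum(presence[[r]] %in% guilds[[truth$guild[i]]])
  }, 1L)

  years <- config$years
  n_yr <- length(years)
  observer <- sample.int(10 * config$n_routes, config$n_routes)
  first_year <- matrix(stats::runif(config$n_routes * n_yr) <
                         config$first_year_observer_rate,
                       config$n_routes, n_yr)
  acceptable <- matrix(stats::runif(config$n_routes * n_yr) >=
                         config$unacceptable_rate,
                       config$n_routes, n_yr)

  rows <- vector("list", config$n_routes * n_yr)
  k <- config$n_stops
  idx <- 0
  for (r in seq_len(config$n_routes)) {
    sp <- presence[[r]]
    p <- detect_prob[sp]
    for (yi in seq_len(n_yr)) {
      # route-year detectability multiplier (observer / conditions)
      u <- stats::runif(1, config$detectability_range[1],
                        config$detectability_range[2])
      det <- matrix(stats::runif(length(sp) * k) < pmin(p * u, 1),
                    length(sp), k)
      hit <- which(det, arr.ind = TRUE)
      idx <- idx + 1
      if (!nrow(hit)) next
      rows[[idx]] <- data.table::data.table(
        route_id = mt$route_id[r], year = years[yi],
        observer_id = observer[r],
        first_year_flag = first_year[r, yi],
        acceptable_flag = acceptable[r, yi],
        species_id = sp[hit[, 1]], occasion_index = hit[, 2],
        detected = TRUE)
    }
  }
  detections <- data.table::rbindlist(rows)
  species <- data.table::data.table(species_id = seq_len(n_sp),
                                    detect_prob = detect_prob)
  for (g in names(guilds)) species[[g]] <- member[, g]
  structure(list(detections = detections, truth = truth, species = species,
                 guilds = guilds, presence = presence, config = config),
            class = "survey_data")
}
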