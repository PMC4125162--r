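# Detection-adjusted route richness. Occasions are the survey stops
# (default k = 50, the 50-stop roadside point-count protocol); the
# first-order jackknife corrects the raw species count for species seen in
# only one occasion, and yearly estimates are averaged over a window of
# years (default 1998-2002).

#' Filter survey records
#'
#' Drops records flagged as not acceptable by survey standards and records
#' surveyed by first-year observers (observer-bias control). Other rows are
#' untouched.
#'
#' @param table survey detection table with logical columns
#'   `acceptable_flag` and `first_year_flag`.
#' @return the filtered table.
#' @export
filter_surveys <- function(table) {
  table <- data.table::as.data.table(table)
  stopifnot(all(c("acceptable_flag", "first_year_flag") %in% names(table)))
  table[table$acceptable_flag & !table$first_year_flag, ]
}

#' First-order jackknife richness estimate
#'
#' For a species-by-occasion detection matrix of one route-year (and
#' optionally one guild), estimates richness as
#' `S_jack1 = S_obs + f1 * (k - 1) / k`, where `S_obs` is the number of
#' species detected at all, `f1` the number detected in exactly one of the
#' `k` occasions. The estimator comes from multiple-recapture theory for
#' closed populations and lets detection probability vary among species.
#'
#' @param detections logical/0-1 matrix, species in rows, occasions in
#'   columns; or an integer vector of per-species occasion counts (then `k`
#'   must be given).
#' @param k number of occasions; defaults to `ncol(detections)`.
#' @return list with `S_obs`, `f1`, `k`, `S_jack1`.
#' @export
jackknife1 <- function(detections, k = NULL) {
  if (is.matrix(detections)) {
    counts <- rowSums(detections > 0)
    if (is.null(k)) k <- ncol(detections)
  } else {
    counts <- as.numeric(detections)
    if (is.null(k)) stop("k required when passing occasion counts")
  }
  if (k < 2) stop("insufficient occasions (k < 2)")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  list(S_obs = s_obs, f1 = f1, k = as.integer(k),
       S_jack1 = s_obs + f1 * (k - 1) / k)
}

#' Jackknife richness for every route-year (and guild)
#'
#' Applies [filter_surveys()] and [jackknife1()] to a detection table. The
#' table holds one row per detection event (`route_id`, `year`,
#' `species_id`, `occasion_index`, flags); `k` is the protocol's occasion
#' count, not the number of occasions with detections. Guild richness is
#' computed by restricting the species set to the guild's members before
#' estimation.
#'
#' @param table detection table (see [gen_survey_table()]).
#' @param k occasions per route-year (default 50).
#' @param guilds optional named list mapping guild label to a vector of
#'   `species_id`s; default a single guild `"all"` of every species.
#' @param filter apply [filter_surveys()] first (default TRUE).
#' @return `data.table` with columns `route_id`, `year`, `guild`, `S_obs`,
#'   `f1`, `k`, `S_jack1`.
#' @export
route_year_richness <- function(table, k = 50, guilds = NULL, filter = TRUE) {
  dt <- data.table::as.data.table(table)
  if (filter) dt <- filter_surveys(dt)
  dt <- dt[dt$detected, ]
  if (is.null(guilds)) guilds <- list(all = unique(dt$species_id))
  res <- lapply(names(guilds), function(g) {
    sub <- dt[dt$species_id %in% guilds[[g]], ]
    if (!nrow(sub)) return(NULL)
    # occasions-detected per species within route-year
    cnt <- sub[, list(n_occ = data.table::uniqueN(occasion_index)),
               by = c("route_id", "year", "species_id")]
    est <- cnt[, {
      j <- jackknife1(n_occ, k = k)
      list(S_obs = j$S_obs, f1 = j$f1, k = j$k, S_jack1 = j$S_jack1)
    }, by = c("route_id", "year")]
    est$guild <- g
    est
  })
  data.table::rbindlist(res, use.names = TRUE)
}

#' Mean richness per route over a year window
#'
#' Arithmetic mean of the available yearly jackknife estimates within the
#' window; routes with no estimate in the window are dropped with a
#' warning.
#'
#' @param estimates output of [route_year_richness()].
#' @param years year window (default 1998:2002).
#' @return `data.table` (`route_id`, `guild`, `n_years`, `mean_richness`).
#' @export
mean_richness <- function(estimates, years = 1998:2002) {
  dt <- data.table::as.data.table(estimates)
  all_routes <- unique(dt$route_id)
  dt <- dt[dt$year %in% years, ]
  if (!nrow(dt)) stop("no estimates within the year window")
  dropped <- setdiff(all_routes, unique(dt$route_id))
  if (length(dropped))
    warning(sprintf("%d route(s) had no acceptable year in the window: %s",
                    length(dropped), paste(utils::head(dropped, 5),
                                           collapse = ", ")))
  out <- dt[, list(n_years = .N, mean_richness = mean(S_jack1)),
            by = c("route_id", "guild")]
  data.table::setorderv(out, c("guild", "route_id"))
  out[]
}
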