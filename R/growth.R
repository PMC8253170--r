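#' Thermal time accumulation
#'
#' Development clock: sum of temperature above a base (default 0 C) times
#' the step length in days, assuming a linear response of development to
#' temperature.
#'
#' @param tair_series air temperatures (C).
#' @param base base temperature (C), default 0.
#' @param dt_days step length of each record in days (scalar or vector);
#'   default `1/24` (hourly records).
#' @return cumulative thermal time series (C d), non-decreasing.
#' @export
thermal_time <- function(tair_series, base = 0, dt_days = 1 / 24) {
  if (!length(tair_series)) stop("`tair_series` must be non-empty")
  cumsum(pmax(tair_series - base, 0) * dt_days)
}

#' Growth configuration for the light-use-efficiency coupling
#'
#' A deliberately minimal crop model: biomass grows as
#' `dB = LUE_eff * IPAR_day` with a prescribed GAI / mean-inclination
#' trajectory against thermal time (no feedback of biomass on GAI), and
#' yield is a fixed harvest index times final biomass. The mean
#' inclination is held constant from emergence to the start of stem
#' extension (GS31), ramps linearly to flag-leaf ligulation (GS39) and is
#' constant after; the clumping factor is constant throughout.
#'
#' The optional diffuse-light response scales LUE linearly with the daily
#' PAR-weighted diffuse fraction:
#' `LUE_eff = LUE * (1 + slope * (f_day - f_ref))`, a configurable hook
#' (default slope 0, i.e. constant LUE) emulating the adjustment some
#' constant-K crop models apply on cloudy days.
#'
#' @param lue light use efficiency (g DM per MJ intercepted PAR).
#' @param harvest_index fraction of final biomass in grain, in (0, 1).
#' @param tt_gs31,tt_gs39,tt_maturity thermal-time thresholds (C d).
#' @param gai_anchors 2-column matrix / data.frame of (thermal time, GAI)
#'   anchor points, interpolated linearly.
#' @param theta_gs31,theta_gs39 mean inclination (radians) before GS31 and
#'   at/after GS39.
#' @param clumping clumping factor, constant over the season.
#' @param lue_f_slope slope of the LUE response to diffuse fraction.
#' @param lue_f_ref reference diffuse fraction of the response.
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(lue = 3.0, harvest_index = 0.45,
                          tt_gs31 = 600, tt_gs39 = 900, tt_maturity = 2000,
                          gai_anchors = cbind(tt = c(0, 300, 600, 900, 1400, 2000),
                                              gai = c(0.05, 0.5, 1.5, 5, 5, 1)),
                          theta_gs31 = deg2rad(50), theta_gs39 = deg2rad(70),
                          clumping = 0.79,
                          lue_f_slope = 0, lue_f_ref = 0.5) {
  if (lue <= 0) stop("`lue` must be > 0")
  if (harvest_index <= 0 || harvest_index >= 1)
    stop("`harvest_index` must lie in (0, 1)")
  if (!(tt_gs31 < tt_gs39 && tt_gs39 < tt_maturity))
    stop("need tt_gs31 < tt_gs39 < tt_maturity")
  gai_anchors <- as.matrix(gai_anchors)
  structure(list(lue = lue, harvest_index = harvest_index,
                 tt_gs31 = tt_gs31, tt_gs39 = tt_gs39,
                 tt_maturity = tt_maturity, gai_anchors = gai_anchors,
                 theta_gs31 = theta_gs31, theta_gs39 = theta_gs39,
                 clumping = clumping, lue_f_slope = lue_f_slope,
                 lue_f_ref = lue_f_ref),
            class = "growth_config")
}

## canopy state at a given thermal time under a growth_config
canopy_at_tt <- function(growth, tt) {
  gai <- stats::approx(growth$gai_anchors[, 1], growth$gai_anchors[, 2],
                       xout = tt, rule = 2)$y
  theta <- if (tt <= growth$tt_gs31) growth$theta_gs31
    else if (tt >= growth$tt_gs39) growth$theta_gs39
    else growth$theta_gs31 + (growth$theta_gs39 - growth$theta_gs31) *
      (tt - growth$tt_gs31) / (growth$tt_gs39 - growth$tt_gs31)
  canopy_state(gai = max(gai, 0), theta_mean = theta,
               clumping = growth$clumping)
}

#' Synthetic hourly weather for a season
#'
#' Clear-sky hourly PAR from solar geometry scaled by a per-day clearness
#' index drawn from a beta distribution, a sinusoidal air temperature
#' course, and the diffuse fraction from the clearness-index partitioning.
#' A stand-in for observed station records in multi-site simulation
#' studies; it reproduces the latitudinal gradient of sun elevation and
#' day length but not real synoptic weather.
#'
#' @param latitude_deg site latitude (degrees).
#' @param sowing_doy day of year of emergence/start.
#' @param n_days number of days to generate.
#' @param mean_clearness mean of the daily clearness index (default 0.55).
#' @param seed integer seed.
#' @return a weather data.frame in the [read_weather()] layout, plus
#'   `tair_C`, with `day` (1-based season day) and `day_of_year`.
#' @export
synthetic_season_weather <- function(latitude_deg, sowing_doy = 288,
                                     n_days = 300, mean_clearness = 0.55,
                                     seed = 1L) {
  with_seed(seed, {
    hours <- 0:23 + 0.5
    res <- vector("list", n_days)
    ## beta-distributed daily clearness around the requested mean
    shp <- 8
    cl <- stats::rbeta(n_days, mean_clearness * shp, (1 - mean_clearness) * shp)
    for (d in seq_len(n_days)) {
      doy <- (sowing_doy + d - 2) %% 365 + 1
      beta <- vapply(hours, function(h)
        solar_position(latitude_deg = latitude_deg, day_of_year = doy,
                       solar_hour = h)$elevation, numeric(1))
      par0 <- extraterrestrial_par(beta)
      par <- cl[d] * par0
      f <- rep(NA_real_, 24)
      up <- beta > 0 & par > 0
      f[up] <- diffuse_fraction(par[up], par0[up], beta[up])
      ## seasonal + diurnal temperature course, cooler at high latitude
      tmean <- 12 - 0.15 * abs(latitude_deg) +
        10 * sin(2 * pi * (doy - 110) / 365) * sign(latitude_deg + 1e-9)
      tair <- tmean + 5 * sin(2 * pi * (hours - 9) / 24) +
        stats::rnorm(24, 0, 0.5)
      res[[d]] <- data.frame(day = d, day_of_year = doy, solar_hour = hours,
                             par_total_Wm2 = pmax(par, 0), beta = beta,
                             diffuse_fraction = f, tair_C = tair)
    }
    do.call(rbind, res)
  })
}

#' Run a light-use-efficiency season simulation
#'
#' Daily loop over an hourly weather table: thermal time advances the
#' phenology, the GAI / inclination trajectory sets the canopy, the light
#' model integrates FIPAR over the day, and biomass accumulates as
#' `LUE_eff * IPAR`. Stops at maturity (or the end of the weather).
#'
#' @param weather hourly weather data.frame as from
#'   [synthetic_season_weather()] (columns `day`, `solar_hour`,
#'   `par_total_Wm2`, `beta`, `diffuse_fraction`, `tair_C`).
#' @param model an [extinction_model()].
#' @param growth a [growth_config()].
#' @return an object of class `season_result`: list with `biomass` and
#'   `yield` (g m-2), `cumulative_ipar` (MJ m-2), and a per-day
#'   data.frame `days` (`tt`, `gai`, `fipar_day`, `ipar_day_MJm2`,
#'   `f_mean`, `biomass`).
#' @export
run_season <- function(weather, model, growth) {
  if (!inherits(growth, "growth_config")) stop("`growth` must be a growth_config")
  days <- unique(weather$day)
  biomass <- 0; tt <- 0
  rows <- vector("list", length(days))
  for (i in seq_along(days)) {
    w <- weather[weather$day == days[i], ]
    tt_day <- sum(pmax(w$tair_C, 0)) / 24
    tt <- tt + tt_day
    if (tt > growth$tt_maturity) break
    cs <- canopy_at_tt(growth, tt)
    if (cs$gai > 0 && any(w$beta > deg2rad(1) & w$par_total_Wm2 > 0)) {
      dl <- fipar_daily(w, model, cs)
      lue_eff <- growth$lue *
        (1 + growth$lue_f_slope * (dl$f_mean - growth$lue_f_ref))
      biomass <- biomass + max(lue_eff, 0) * dl$ipar_day_MJm2
      rows[[i]] <- data.frame(day = days[i], tt = tt, gai = cs$gai,
                              fipar_day = dl$fipar_day,
                              ipar_day_MJm2 = dl$ipar_day_MJm2,
                              f_mean = dl$f_mean, biomass = biomass)
    } else {
      rows[[i]] <- data.frame(day = days[i], tt = tt, gai = cs$gai,
                              fipar_day = NA_real_, ipar_day_MJm2 = 0,
                              f_mean = NA_real_, biomass = biomass)
    }
  }
  daily <- do.call(rbind, rows)
  structure(list(biomass = biomass,
                 yield = growth$harvest_index * biomass,
                 cumulative_ipar = sum(daily$ipar_day_MJm2),
                 days = daily),
            class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("<season_result> IPAR %.1f MJ m-2, biomass %.1f g m-2, yield %.1f g m-2\n",
              x$cumulative_ipar, x$biomass, x$yield))
  invisible(x)
}

#' Relative differences in season outcomes across light models
#'
#' Runs every model at every site and reports, per site and model, the
#' relative difference `(X_model - X_ref) / X_ref` from the reference
#' model for cumulative IPAR, biomass and yield.
#'
#' @param sites a list of site configs, each a list with `latitude_deg`
#'   and optionally `sowing_doy`, `n_days`, `mean_clearness`, `seed`,
#'   `name`.
#' @param models named list of [extinction_model()] objects.
#' @param growth a [growth_config()] shared across runs.
#' @param reference_model name of the reference model (must be in
#'   `models`).
#' @return a data.frame with columns `site`, `latitude_deg`, `model`,
#'   `rel_ipar`, `rel_biomass`, `rel_yield` plus the absolute reference
#'   values.
#' @export
uncertainty_table <- function(sites, models, growth,
                              reference_model = "KellC") {
  if (!reference_model %in% names(models))
    stop("`reference_model` must be one of the supplied models")
  out <- list()
  for (s in seq_along(sites)) {
    site <- sites[[s]]
    nm <- if (!is.null(site$name)) site$name else sprintf("site%d", s)
    wx <- synthetic_season_weather(
      latitude_deg = site$latitude_deg,
      sowing_doy = if (is.null(site$sowing_doy)) 288 else site$sowing_doy,
      n_days = if (is.null(site$n_days)) 300 else site$n_days,
      mean_clearness = if (is.null(site$mean_clearness)) 0.55
                       else site$mean_clearness,
      seed = if (is.null(site$seed)) 100L + s else site$seed)
    runs <- lapply(models, run_season, weather = wx, growth = growth)
    ref <- runs[[reference_model]]
    if (ref$cumulative_ipar <= 0 || ref$biomass <= 0)
      stop("reference model produced zero outcome at site ", nm)
    out[[s]] <- data.frame(
      site = nm, latitude_deg = site$latitude_deg, model = names(models),
      rel_ipar = vapply(runs, function(r)
        (r$cumulative_ipar - ref$cumulative_ipar) / ref$cumulative_ipar,
        numeric(1)),
      rel_biomass = vapply(runs, function(r)
        (r$biomass - ref$biomass) / ref$biomass, numeric(1)),
      rel_yield = vapply(runs, function(r)
        (r$yield - ref$yield) / ref$yield, numeric(1)),
      ref_ipar = ref$cumulative_ipar, ref_yield = ref$yield,
      row.names = NULL)
  }
  do.call(rbind, out)
}
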