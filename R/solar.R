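#' Solar position from latitude, day of year and solar hour
#'
#' Astronomical sun elevation and azimuth from the standard declination /
#' hour-angle formulas. Time is true solar time: solar noon is at hour 12
#' and no equation-of-time or longitude correction is applied, matching
#' weather records declared in solar hours.
#'
#' @param latitude site latitude in radians (use [deg2rad] helpers at the
#'   boundary; `latitude_deg` is accepted as a convenience).
#' @param day_of_year integer day of year (1-366).
#' @param solar_hour decimal solar hour in `[0, 24)`.
#' @param latitude_deg optional latitude in degrees, overriding `latitude`.
#' @return an object of class `solar_position`: a list with `elevation`
#'   and `azimuth` (radians; azimuth clockwise from north in `[0, 2*pi)`),
#'   `declination`, `day_of_year` and `solar_hour`. Elevation is negative
#'   at night.
#' @examples
#' sp <- solar_position(latitude_deg = 48.85, day_of_year = 172, solar_hour = 12)
#' rad2deg(sp$elevation)  # ~ 64.6
#' @export
solar_position <- function(latitude = NULL, day_of_year, solar_hour,
                           latitude_deg = NULL) {
  if (!is.null(latitude_deg)) latitude <- deg2rad(latitude_deg)
  stopifnot_scalar(latitude, "latitude")
  stopifnot_scalar(day_of_year, "day_of_year")
  stopifnot_scalar(solar_hour, "solar_hour")
  if (latitude < -pi / 2 || latitude > pi / 2)
    stop("`latitude` must lie in [-pi/2, pi/2] radians")
  if (day_of_year < 1 || day_of_year > 366)
    stop("`day_of_year` must lie in [1, 366]")
  if (solar_hour < 0 || solar_hour >= 24)
    stop("`solar_hour` must lie in [0, 24)")

  ## Cooper's declination; hour angle zero at solar noon
  decl <- deg2rad(23.45) * sin(2 * pi * (284 + day_of_year) / 365)
  ha <- pi / 12 * (solar_hour - 12)
  sin_el <- sin(latitude) * sin(decl) + cos(latitude) * cos(decl) * cos(ha)
  sin_el <- max(-1, min(1, sin_el))
  elevation <- asin(sin_el)

  ## azimuth measured clockwise from north
  cos_el <- cos(elevation)
  if (cos_el < 1e-12) {
    azimuth <- 0
  } else {
    cos_az <- (sin(decl) - sin(latitude) * sin_el) / (cos(latitude) * cos_el)
    cos_az <- max(-1, min(1, cos_az))
    azimuth <- acos(cos_az)
    if (ha > 0) azimuth <- 2 * pi - azimuth
    azimuth <- azimuth %% (2 * pi)
  }
  structure(list(elevation = elevation, azimuth = azimuth,
                 declination = decl, day_of_year = day_of_year,
                 solar_hour = solar_hour),
            class = "solar_position")
}

#' @export
print.solar_position <- function(x, ...) {
  cat(sprintf("<solar_position> day %d, hour %.2f: elevation %.2f deg, azimuth %.2f deg\n",
              x$day_of_year, x$solar_hour,
              rad2deg(x$elevation), rad2deg(x$azimuth)))
  invisible(x)
}

#' Extraterrestrial PAR on a horizontal surface
#'
#' Top-of-atmosphere photosynthetically active radiation, taken as half of
#' the solar constant (1367 W m-2) times the sine of sun elevation. Used as
#' the normalizer of the clearness index in [diffuse_fraction()].
#'
#' @param solar a [solar_position()] object, or a numeric elevation in
#'   radians.
#' @return flux in W m-2 (0 when the sun is below the horizon).
#' @export
extraterrestrial_par <- function(solar) {
  beta <- if (inherits(solar, "solar_position")) solar$elevation else solar
  0.5 * 1367 * pmax(sin(beta), 0)
}

#' Diffuse fraction of incident PAR from the clearness index
#'
#' Partitions measured PAR into diffuse and direct components with the
#' hourly piecewise clearness-index relations of Spitters et al. (1986):
#' fully diffuse below a clearness of 0.22, a quadratic roll-off to 0.35, a
#' linear branch, and a sun-elevation-dependent clear-sky floor
#' `f0 = 0.847 - 1.61 sin(beta) + 1.04 sin(beta)^2`. The result is clamped
#' to `[0, 1]`.
#'
#' @param par_total measured PAR flux (W m-2), vectorised.
#' @param extraterrestrial_par top-of-atmosphere PAR flux (W m-2); must be
#'   positive.
#' @param solar a [solar_position()] (or elevation in radians) with
#'   elevation > 0.
#' @return diffuse fraction(s) in `[0, 1]`.
#' @seealso [constant_diffuse_fraction()] for a substitutable strategy.
#' @export
diffuse_fraction <- function(par_total, extraterrestrial_par, solar) {
  beta <- if (inherits(solar, "solar_position")) solar$elevation else solar
  if (any(par_total < 0)) stop("`par_total` must be >= 0")
  if (any(extraterrestrial_par <= 0))
    stop("`extraterrestrial_par` must be > 0")
  if (any(beta <= 0)) stop("sun elevation must be > 0 to partition PAR")
  R <- par_total / extraterrestrial_par
  sb <- sin(beta)
  f0 <- 0.847 - 1.61 * sb + 1.04 * sb^2
  Kcrit <- (1.47 - f0) / 1.66
  f <- ifelse(R <= 0.22, 1,
       ifelse(R <= 0.35, 1 - 6.4 * (R - 0.22)^2,
       ifelse(R <= Kcrit, 1.47 - 1.66 * R, f0)))
  pmin(1, pmax(0, f))
}

#' Constant diffuse-fraction strategy
#'
#' Returns a partitioning function usable wherever [diffuse_fraction()] is,
#' for sensitivity runs with a prescribed sky condition (e.g. `f = 1` for
#' fully overcast).
#'
#' @param f the fixed diffuse fraction in `[0, 1]`.
#' @return a function `(par_total, extraterrestrial_par, solar) -> f`.
#' @export
constant_diffuse_fraction <- function(f) {
  stopifnot_scalar(f, "f")
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  function(par_total, extraterrestrial_par = NULL, solar = NULL)
    rep(f, length(par_total))
}

#' Standard-overcast-sky weights of sun-elevation classes
#'
#' Fraction of the diffuse flux on a horizontal plane contributed by each
#' elevation class of a standard overcast sky, whose radiance brightens
#' toward the zenith as `L(beta) ~ (1 + 2 sin(beta))`. The weight of class
#' `[a, b]` is the analytic integral of `L(beta) sin(beta) cos(beta)` over
#' the class, normalized over the hemisphere. With the classic 30-degree
#' classes this yields (0.179, 0.514, 0.307), matching the rounded triplet
#' (0.178, 0.514, 0.308) in wide use.
#'
#' @param class_edges increasing vector of elevation edges (radians)
#'   partitioning `[0, pi/2]`.
#' @param radiance sky radiance as a function of elevation; default the
#'   standard overcast sky. Non-default radiances are integrated by
#'   quadrature.
#' @return numeric vector of class weights summing to 1.
#' @examples
#' overcast_weights(deg2rad(c(0, 30, 60, 90)))
#' @export
overcast_weights <- function(class_edges,
                             radiance = function(beta) 1 + 2 * sin(beta)) {
  if (length(class_edges) < 2 || any(diff(class_edges) <= 0))
    stop("`class_edges` must be strictly increasing with >= 2 edges")
  if (abs(class_edges[1]) > 1e-12 ||
      abs(class_edges[length(class_edges)] - pi / 2) > 1e-9)
    stop("`class_edges` must partition [0, pi/2]")
  ## antiderivative of (1 + 2 sin b) sin b cos b = sin^2(b)/2 + (2/3) sin^3(b)
  soc <- function(beta) sin(beta)^2 / 2 + 2 / 3 * sin(beta)^3
  is_soc <- isTRUE(all.equal(radiance(c(0, 0.3, 1)),
                             1 + 2 * sin(c(0, 0.3, 1))))
  if (is_soc) {
    cum <- soc(class_edges)
  } else {
    cum <- vapply(class_edges, function(b) {
      if (b == 0) return(0)
      g <- gl_nodes(64, 0, b)
      sum(g$w * radiance(g$x) * sin(g$x) * cos(g$x))
    }, numeric(1))
  }
  w <- diff(cum)
  w / sum(w)
}

#' Read a delimited weather file
#'
#' Expected columns: `date` (ISO-8601), `solar_hour` (decimal),
#' `par_total_Wm2`, and optionally `diffuse_fraction` and `tair_C`. When
#' `diffuse_fraction` is absent it is filled in from the clearness index
#' via `partition` at each daylight time step.
#'
#' @param path file path of a delimited text file (any whitespace/comma
#'   separator `read.table` can sniff via `sep`).
#' @param latitude_deg site latitude in degrees, needed to compute solar
#'   positions (and to partition PAR when `diffuse_fraction` is missing).
#' @param sep field separator, default comma.
#' @param partition partitioning strategy, default [diffuse_fraction()].
#' @return a data.frame with the input columns plus `day_of_year`,
#'   `beta` (solar elevation, radians) and `diffuse_fraction`.
#' @export
read_weather <- function(path, latitude_deg, sep = ",",
                         partition = diffuse_fraction) {
  w <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("date", "solar_hour", "par_total_Wm2")
  if (!all(need %in% names(w)))
    stop("weather file must contain columns: ", paste(need, collapse = ", "))
  w$day_of_year <- as.POSIXlt(as.Date(w$date))$yday + 1L
  w$beta <- mapply(function(d, h)
    solar_position(latitude_deg = latitude_deg, day_of_year = d,
                   solar_hour = h)$elevation,
    w$day_of_year, w$solar_hour)
  if (is.null(w$diffuse_fraction)) w$diffuse_fraction <- NA_real_
  day <- w$beta > 0 & w$par_total_Wm2 > 0
  fill <- day & !is.finite(w$diffuse_fraction)
  if (any(fill)) {
    w$diffuse_fraction[fill] <- partition(
      w$par_total_Wm2[fill], extraterrestrial_par(w$beta[fill]), w$beta[fill])
  }
  w$diffuse_fraction[!day] <- NA_real_
  w
}
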