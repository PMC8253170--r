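#' Fraction of intercepted PAR from an extinction coefficient
#'
#' The Beer-Lambert big-leaf relation `FIPAR = 1 - exp(-K * GAI)`.
#'
#' @param K extinction coefficient (> 0), vectorised.
#' @param gai green area index (>= 0), vectorised.
#' @return FIPAR in `[0, 1)`.
#' @export
fipar_from_k <- function(K, gai) {
  if (any(K <= 0)) stop("`K` must be > 0")
  if (any(gai < 0)) stop("`gai` must be >= 0")
  1 - exp(-K * gai)
}

#' Direct-beam FIPAR of a model for a canopy
#'
#' `1 - exp(-K(beta) * GAI)` with K from [k_direct()].
#'
#' @inheritParams k_direct
#' @return FIPAR in `[0, 1)`, same length as `beta`.
#' @export
fipar_dir <- function(model, beta, canopy) {
  1 - exp(-k_direct(model, beta, canopy) * canopy$gai)
}

#' Diffuse-PAR extinction coefficient, average-inclination model
#'
#' The GECROS form: the overcast sky is collapsed onto three elevation
#' classes (centred at 15, 45 and 75 degrees, with standard-overcast-sky
#' weights 0.178/0.514/0.308) and the transmitted fractions are combined
#' before taking the log:
#' `Kdif = -1/GAI * ln(0.178 e^{-K15 GAI} + 0.514 e^{-K45 GAI} + 0.308 e^{-K75 GAI})`.
#' As `GAI -> 0` this tends to the weighted mean of the three class
#' coefficients, which is returned at `gai = 0`.
#'
#' @param gai green area index (>= 0).
#' @param theta average element inclination (radians).
#' @return the diffuse K.
#' @export
k_avr_dif <- function(gai, theta) {
  stopifnot_scalar(gai, "gai")
  if (gai < 0) stop("`gai` must be >= 0")
  w <- c(0.178, 0.514, 0.308)
  kb <- k_avr_dir(deg2rad(c(15, 45, 75)), theta)
  if (gai == 0) return(sum(w * kb))
  -1 / gai * log(sum(w * exp(-kb * gai)))
}

#' Diffuse-sky FIPAR of a model for a canopy
#'
#' Dispatch mirrors the conventions of the source crop growth models:
#' \itemize{
#'   \item constant-K families (`Kcst`, `Kcstds`, `KcstHS`): the constant
#'     K applies to any direction, so diffuse FIPAR equals
#'     [fipar_from_k()] exactly;
#'   \item spherical family (`Ksph`, `KsphC`): a constant diffuse
#'     coefficient (`k_meas_dif`, default 0.6) is used;
#'   \item average-inclination (`Kavr`): the three-class overcast-sky
#'     coefficient of [k_avr_dif()];
#'   \item ellipsoidal family (`Kell`, `KellC`): the hemispheric
#'     cosine-weighted integral
#'     `FIPARdif = 2 * integral FIPARdir(beta) cos(beta) sin(beta) dbeta`
#'     by Gauss-Legendre quadrature (order `model$quad_order`).
#' }
#'
#' @inheritParams k_direct
#' @return diffuse FIPAR in `[0, 1)`.
#' @export
fipar_dif_integral <- function(model, canopy) {
  if (!inherits(model, "extinction_model")) stop("`model` must be an extinction_model")
  gai <- canopy$gai
  if (gai == 0) return(0)
  switch(model$name,
    Kcst   = ,
    Kcstds = ,
    KcstHS = fipar_from_k(k_direct(model, pi / 2, canopy), gai),
    Ksph   = ,
    KsphC  = fipar_from_k(model$k_meas_dif, gai),
    Kavr   = fipar_from_k(
      k_avr_dif(gai, if (is.null(model$theta)) canopy$theta_mean
                     else model$theta), gai),
    {  # ellipsoidal family: hemispheric integral of the directional FIPAR
      g <- gl_nodes(model$quad_order)
      2 * sum(g$w * fipar_dir(model, g$x, canopy) * cos(g$x) * sin(g$x))
    })
}

#' Instantaneous FIPAR under mixed illumination
#'
#' Convex combination of the diffuse and direct components weighted by the
#' diffuse fraction: `FIPAR = f * FIPARdif + (1 - f) * FIPARdir`.
#'
#' @param f diffuse fraction(s) in `[0, 1]`.
#' @param fipar_dif diffuse-sky FIPAR in `[0, 1]`.
#' @param fipar_dir direct-beam FIPAR in `[0, 1]`.
#' @return instantaneous FIPAR.
#' @export
fipar_instant <- function(f, fipar_dif, fipar_dir) {
  if (any(c(f, fipar_dif, fipar_dir) < 0) ||
      any(c(f, fipar_dif, fipar_dir) > 1))
    stop("all arguments must lie in [0, 1]")
  f * fipar_dif + (1 - f) * fipar_dir
}

#' Daily integration of FIPAR over a weather record
#'
#' Runs a light interception model over the time steps of one day and
#' integrates: the daily FIPAR is the PAR-weighted mean of the
#' instantaneous values over daylight steps, and the daily intercepted
#' PAR (IPAR, MJ m-2 d-1) is the sum of `FIPAR * PAR * dt`. Records with
#' sun elevation below 1 degree or zero PAR are treated as night and
#' skipped. The time step is inferred from the spacing of `solar_hour`;
#' irregular spacing uses trapezoidal-style local step widths.
#'
#' @param records a data.frame with columns `solar_hour`, `par_total_Wm2`,
#'   `beta` (solar elevation, radians) and `diffuse_fraction` (as returned
#'   by [read_weather()], one calendar day's rows).
#' @param model an [extinction_model()].
#' @param canopy a [canopy_state()].
#' @return an object of class `daily_light_record`: list with the
#'   instantaneous series (`fipar_dir`, `fipar_instant`), the scalar
#'   diffuse FIPAR, `fipar_day`, `ipar_day_MJm2`, `par_day_MJm2`, `f_mean`
#'   and `beta_max`. `fipar_day` is `NA` (with a warning) for an all-dark
#'   day.
#' @export
fipar_daily <- function(records, model, canopy) {
  need <- c("solar_hour", "par_total_Wm2", "beta", "diffuse_fraction")
  if (!all(need %in% names(records)))
    stop("`records` must contain columns: ", paste(need, collapse = ", "))
  h <- records$solar_hour
  if (is.unsorted(h)) stop("`records` must be in chronological order")
  ## local step width in hours (trapezoid-style for irregular spacing)
  dt <- if (length(h) == 1L) 1 else {
    dh <- diff(h)
    n <- length(h)
    c(dh[1], if (n > 2) (dh[-1] + dh[-(n - 1)]) / 2, dh[n - 1])
  }
  day <- records$beta > deg2rad(1) & records$par_total_Wm2 > 0
  fdif <- fipar_dif_integral(model, canopy)
  fdir <- rep(NA_real_, nrow(records))
  finst <- rep(NA_real_, nrow(records))
  if (any(day)) {
    fdir[day] <- fipar_dir(model, records$beta[day], canopy)
    finst[day] <- fipar_instant(records$diffuse_fraction[day], fdif, fdir[day])
  }
  par_w <- records$par_total_Wm2[day] * dt[day]      # W m-2 * h
  if (!any(day) || sum(par_w) <= 0) {
    warning("no daylight PAR in `records`: fipar_day undefined")
    fipar_day <- NA_real_; ipar <- 0; par_day <- 0; f_mean <- NA_real_
  } else {
    fipar_day <- sum(finst[day] * par_w) / sum(par_w)
    ipar <- sum(finst[day] * par_w) * 3600 * 1e-6     # MJ m-2 d-1
    par_day <- sum(par_w) * 3600 * 1e-6
    f_mean <- sum(records$diffuse_fraction[day] * par_w) / sum(par_w)
  }
  structure(list(fipar_dir = fdir, fipar_dif = fdif, fipar_instant = finst,
                 fipar_day = fipar_day, ipar_day_MJm2 = ipar,
                 par_day_MJm2 = par_day, f_mean = f_mean,
                 beta_max = max(records$beta)),
            class = "daily_light_record")
}

#' @export
print.daily_light_record <- function(x, ...) {
  cat(sprintf("<daily_light_record> fipar_day %.3f, ipar %.3f MJ m-2\n",
              x$fipar_day, x$ipar_day_MJm2))
  invisible(x)
}

#' Cumulative intercepted PAR over a series of days
#'
#' @param daily a list of [fipar_daily()] results (or a numeric vector of
#'   daily IPAR values, MJ m-2 d-1) in chronological order.
#' @return non-decreasing numeric vector of the running IPAR sum.
#' @export
cumulative_ipar <- function(daily) {
  ipar <- if (is.numeric(daily)) daily
          else vapply(daily, function(d) d$ipar_day_MJm2, numeric(1))
  cumsum(ipar)
}
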