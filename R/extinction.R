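#' Canopy state description
#'
#' Bundles the canopy descriptors the extinction models draw on: green
#' area index, mean surface inclination / ellipsoid eccentricity, clumping
#' factor, phenology (Haun stage and final leaf number) and sowing pattern.
#' Only the fields a given model needs have to be present; `chi` is derived
#' from `theta_mean` (and vice versa) when only one is given.
#'
#' @param gai green area index (m2 m-2, >= 0).
#' @param theta_mean mean surface inclination angle (radians).
#' @param chi ellipsoid eccentricity (> 0).
#' @param clumping clumping factor CGAI (> 0, 1 = random canopy).
#' @param haun_stage decimal main-stem leaf number.
#' @param final_leaf_number final main-stem leaf number.
#' @param plant_density plants m-2.
#' @param row_spacing m.
#' @return an object of class `canopy_state`.
#' @export
canopy_state <- function(gai, theta_mean = NULL, chi = NULL, clumping = 1,
                         haun_stage = NULL, final_leaf_number = NULL,
                         plant_density = NULL, row_spacing = NULL) {
  stopifnot_scalar(gai, "gai")
  if (gai < 0) stop("`gai` must be >= 0")
  stopifnot_scalar(clumping, "clumping")
  if (clumping <= 0) stop("`clumping` must be > 0")
  if (is.null(chi) && !is.null(theta_mean)) chi <- chi_from_theta_mean(theta_mean)
  if (is.null(theta_mean) && !is.null(chi)) theta_mean <- theta_mean_from_chi(chi)
  if (!is.null(haun_stage) && !is.null(final_leaf_number) &&
      (haun_stage <= 0 || haun_stage > final_leaf_number))
    stop("need 0 < haun_stage <= final_leaf_number")
  structure(list(gai = gai, theta_mean = theta_mean, chi = chi,
                 clumping = clumping, haun_stage = haun_stage,
                 final_leaf_number = final_leaf_number,
                 plant_density = plant_density, row_spacing = row_spacing),
            class = "canopy_state")
}

#' @export
print.canopy_state <- function(x, ...) {
  cat(sprintf("<canopy_state> GAI %.2f, clumping %.2f", x$gai, x$clumping))
  if (!is.null(x$theta_mean))
    cat(sprintf(", theta_mean %.1f deg (chi %.2f)",
                rad2deg(x$theta_mean), x$chi))
  cat("\n")
  invisible(x)
}

# ---- constant-family coefficients -----------------------------------------

#' Constant extinction coefficient
#'
#' The big-leaf model used by most wheat crop growth models: one K for all
#' sun elevations and sky conditions.
#'
#' @param value the coefficient (> 0).
#' @return the value, unchanged, for use wherever a directional K is
#'   expected.
#' @export
k_constant <- function(value) {
  stopifnot_scalar(value, "value")
  if (value <= 0) stop("`value` must be > 0")
  value
}

#' Density / row-spacing extinction coefficient (SALUS)
#'
#' Empirical sowing-pattern adjustment `K = 1.5 - 0.768 (d s^2)^0.1`,
#' decreasing in both plant density `d` and row spacing `s`. Over the
#' agronomic range d in 100-400 plants m-2 and s in 0.15-0.35 m it spans
#' 0.37-0.67.
#'
#' @param d plant density (plants m-2, > 0), vectorised.
#' @param s row spacing (m, > 0), vectorised.
#' @return K; values <= 0 (far outside the calibration domain) are
#'   returned as `NA` with a warning.
#' @export
k_salus <- function(d, s) {
  if (any(d <= 0) || any(s <= 0)) stop("`d` and `s` must be > 0")
  k <- 1.5 - 0.768 * (d * s^2)^0.1
  if (any(k <= 0)) {
    warning("d*s^2 outside validity domain: non-positive K returned as NA")
    k[k <= 0] <- NA_real_
  }
  k
}

#' Haun-stage dependent extinction coefficient (APSIM)
#'
#' K is 0.5 until the Haun stage reaches the threshold
#' `omega = 0.973 FLN - 0.777`, then rises linearly to 0.6 at the final
#' leaf, reflecting the steepening of leaves during stem extension:
#' `K = 0.5 (1 + 0.2 (HS - omega) / (FLN - omega))` for `HS > omega`.
#'
#' @param HS Haun stage (decimal leaves, 0 < HS <= FLN), vectorised.
#' @param FLN final leaf number.
#' @return K in `[0.5, 0.6]`.
#' @export
k_apsim_hs <- function(HS, FLN) {
  stopifnot_scalar(FLN, "FLN")
  if (any(HS <= 0) || any(HS > FLN)) stop("need 0 < HS <= FLN")
  omega <- 0.973 * FLN - 0.777
  if (FLN <= omega) stop("degenerate phenology: FLN <= omega")
  ifelse(HS <= omega, 0.5, 0.5 * (1 + 0.2 * (HS - omega) / (FLN - omega)))
}

# ---- average-inclination model --------------------------------------------

#' Projection function for a single surface inclination angle
#'
#' Goudriaan's projection of unit green area onto the plane normal to the
#' beam, for elements all inclined at `theta` with uniform azimuth:
#' `G = sin(beta) cos(theta)` when the sun is above the element plane
#' (`beta >= theta`), and
#' `G = (2/pi) (sin(beta) cos(theta) asin(tan(beta)/tan(theta)) +
#' sqrt(sin^2(theta) - sin^2(beta)))` otherwise. Continuous at
#' `beta = theta`.
#'
#' @param beta sun elevation (radians, > 0), vectorised.
#' @param theta element inclination (radians, in `[0, pi/2]`).
#' @return projection G (dimensionless).
#' @export
g_avr <- function(beta, theta) {
  if (any(beta <= 0)) stop("`beta` must be > 0")
  stopifnot_scalar(theta, "theta")
  if (theta < 0 || theta > pi / 2) stop("`theta` must lie in [0, pi/2]")
  above <- beta >= theta
  g <- sin(beta) * cos(theta)
  if (any(!above)) {
    b <- beta[!above]
    x <- pmin(1, tan(b) / tan(theta))  # guard fp noise at the branch point
    g[!above] <- 2 / pi * (sin(b) * cos(theta) * asin(x) +
                           sqrt(pmax(sin(theta)^2 - sin(b)^2, 0)))
  }
  g
}

#' Direct-beam extinction coefficient, average-inclination model
#'
#' `K = G_avr(beta, theta) / sin(beta)`; equals `cos(theta)` whenever the
#' sun is above the element plane. GECROS uses this form with a wheat
#' default of `theta = 50` degrees.
#'
#' @inheritParams g_avr
#' @return K.
#' @export
k_avr_dir <- function(beta, theta) g_avr(beta, theta) / sin(beta)

# ---- spherical model ------------------------------------------------------

#' Direct-beam extinction coefficient, spherical distribution
#'
#' `K = 0.5 / sin(beta)`: surfaces oriented as facets of a sphere project
#' a quarter of their area in any direction.
#'
#' @param beta sun elevation (radians, > 0), vectorised.
#' @return K.
#' @export
k_sph_dir <- function(beta) {
  if (any(beta <= 0)) stop("`beta` must be > 0")
  0.5 / sin(beta)
}

#' Clumping correction of the spherical model
#'
#' `Csph = Kmeasdif / (0.8 sqrt(1 - sigma))`: the measured diffuse
#' extinction coefficient relative to its theoretical spherical value,
#' absorbing departures from randomness (and, historically, unaccounted
#' stem/ear area). With the SUCROS/WOFOST wheat value `Kmeasdif = 0.6`
#' and black leaves (`sigma = 0`), `Csph = 0.75`.
#'
#' @param k_meas_dif measured extinction coefficient for diffuse PAR (> 0).
#' @param sigma leaf scattering coefficient in `[0, 1)`; 0 under the
#'   black-leaf assumption used throughout this package.
#' @return the clumping correction factor.
#' @export
c_sph <- function(k_meas_dif, sigma = 0) {
  stopifnot_scalar(k_meas_dif, "k_meas_dif")
  stopifnot_scalar(sigma, "sigma")
  if (k_meas_dif <= 0) stop("`k_meas_dif` must be > 0")
  if (sigma < 0 || sigma >= 1) stop("`sigma` must lie in [0, 1)")
  k_meas_dif / (0.8 * sqrt(1 - sigma))
}

#' Clumped spherical direct-beam coefficient
#'
#' `K = Csph * 0.5 / sin(beta)`.
#'
#' @inheritParams k_sph_dir
#' @param csph clumping correction from [c_sph()] (> 0).
#' @return K.
#' @export
k_sph_clumped <- function(beta, csph) {
  stopifnot_scalar(csph, "csph")
  if (csph <= 0) stop("`csph` must be > 0")
  csph * k_sph_dir(beta)
}

# ---- ellipsoidal model ----------------------------------------------------

#' Direct-beam extinction coefficient, ellipsoidal distribution (closed form)
#'
#' Campbell's closed form
#' `K = sqrt(chi^2 + cot^2(beta)) / (chi + 1.774 (chi + 1.182)^-0.733)`.
#' `chi = 1` recovers the spherical `0.5 / sin(beta)` to within 0.1% (the
#' Lambda approximation evaluates to 2.0013 instead of 2).
#'
#' @param beta sun elevation (radians, > 0), vectorised.
#' @param chi eccentricity (> 0).
#' @return K.
#' @export
k_ell_closed <- function(beta, chi) {
  stopifnot_scalar(chi, "chi")
  if (chi <= 0) stop("`chi` must be > 0")
  if (any(beta <= 0)) stop("`beta` must be > 0")
  sqrt(chi^2 + 1 / tan(beta)^2) / ellipse_lambda(chi)
}

## the 13 inclination classes of the discrete formulation (degrees):
## midpoints of 10-degree classes up to 80 degrees, then 2-degree classes
## to 90; the class widths matter because the spacing is uneven
.kell_classes_deg <- c(5, 15, 25, 35, 45, 55, 65, 75, 81, 83, 85, 87, 89)
.kell_widths_deg <- c(rep(10, 8), rep(2, 5))

## per-class extinction coefficient for elements at inclination theta_i:
## K = (2 beta_b / pi - 1) cos(theta) + (2/pi) sin(beta_b) sin(theta)/tan(beta)
## with beta_b = pi when theta < beta, else acos(-tan(beta)/tan(theta)).
## Algebraically identical to k_avr_dir (both are G/sin(beta)).
k_class <- function(beta, theta_i) {
  x <- -tan(beta) / tan(theta_i)
  bb <- ifelse(theta_i < beta, pi, acos(pmax(-1, pmin(1, x))))
  (2 * bb / pi - 1) * cos(theta_i) + 2 / pi * sin(bb) * sin(theta_i) / tan(beta)
}

#' Direct-beam extinction coefficient, ellipsoidal distribution (discrete)
#'
#' Discrete 13-class approximation: the density-weighted average of the
#' per-class coefficient `K(beta, theta_i)` over fixed inclination classes
#' at 5, 15, ..., 75, 81, 83, 85, 87, 89 degrees (midpoints of 10-degree
#' classes up to 80 degrees and 2-degree classes above). The class
#' frequencies are `g(theta_i)` times the class width; the widths are
#' required because the class spacing is uneven. Agrees with
#' [k_ell_closed()] to within a few percent across the useful domain.
#'
#' @inheritParams k_ell_closed
#' @return K.
#' @export
k_ell_discrete <- function(beta, chi) {
  stopifnot_scalar(chi, "chi")
  if (chi <= 0) stop("`chi` must be > 0")
  if (any(beta <= 0)) stop("`beta` must be > 0")
  th <- deg2rad(.kell_classes_deg)
  g <- ellipsoidal_pdf(th, chi) * deg2rad(.kell_widths_deg)
  vapply(beta, function(b) sum(g * k_class(b, th)) / sum(g), numeric(1))
}

#' Clumped ellipsoidal direct-beam coefficient
#'
#' `K = CGAI * Kell(beta, chi)`: the closed-form ellipsoidal coefficient
#' scaled by a direction-independent clumping factor.
#'
#' @inheritParams k_ell_closed
#' @param cgai clumping factor (> 0).
#' @return K.
#' @export
k_ell_clumped <- function(beta, chi, cgai) {
  stopifnot_scalar(cgai, "cgai")
  if (cgai <= 0) stop("`cgai` must be > 0")
  cgai * k_ell_closed(beta, chi)
}

# ---- clumping from gap-fraction inversion ---------------------------------

#' Clumping factor from effective and measured green area index
#'
#' `CGAI = GAIeff / GAImes`, the ratio of the green area index retrieved
#' by gap-fraction inversion (which assumes random element positions) to
#' the true, destructively measured one. Below 1 for aggregated (row)
#' canopies.
#'
#' @param gai_eff effective GAI.
#' @param gai_mes measured GAI (> 0).
#' @return the clumping factor.
#' @export
clumping_from_gai <- function(gai_eff, gai_mes) {
  if (any(gai_mes <= 0)) stop("`gai_mes` must be > 0")
  gai_eff / gai_mes
}

#' Effective green area index from a directional FIPAR profile
#'
#' Miller-type inversion
#' `GAIeff = 2 * integral_0^{pi/2} -ln(1 - FIPAR(beta)) cos(beta) sin(beta) dbeta`
#' computed by fixed-order Gauss-Legendre quadrature. For an unclumped
#' canopy obeying `FIPAR = 1 - exp(-K(beta) GAI)` the identity returns the
#' true GAI.
#'
#' @param fipar_dir_profile function of sun elevation (radians) returning
#'   the direct-beam FIPAR in `[0, 1)`.
#' @param order quadrature order (default 32). At grazing-angle nodes a
#'   dense canopy's FIPAR saturates to 1 in double precision; lowering the
#'   order moves the lowest node away from the horizon (order 8 keeps all
#'   nodes above ~1.8 degrees).
#' @param cap optional ceiling applied to the profile (e.g. `1 - 1e-9`);
#'   by default a saturated node is an error, since capping biases the
#'   retrieval low.
#' @return the effective GAI.
#' @export
effective_gai_from_fipar <- function(fipar_dir_profile, order = 32,
                                     cap = NULL) {
  g <- gl_nodes(order)
  fp <- fipar_dir_profile(g$x)
  if (!is.null(cap)) fp <- pmin(fp, cap)
  if (any(fp >= 1))
    stop("FIPAR = 1 at a quadrature node: profile is singular; ",
         "supply `cap` (e.g. 1 - 1e-9) or lower `order` to keep ",
         "quadrature nodes away from the horizon")
  if (any(fp < 0)) stop("FIPAR must be >= 0")
  2 * sum(g$w * (-log1p(-fp)) * cos(g$x) * sin(g$x))
}

# ---- model registry and specification -------------------------------------

#' Registry of light interception models across wheat crop growth models
#'
#' The 26 wheat crop growth models of the multi-model intercomparison
#' ensemble with the type of
#' extinction coefficient each uses (constant, spherical, or
#' average-inclination), the constant K value or range, the diffuse-PAR
#' coefficient of the spherical family, whether sheath and spike area are
#' counted, the biomass production approach and the time step. Shipped as
#' delimited text in `inst/extdata/cgm_models.tsv`.
#'
#' @return a data.frame, one row per crop growth model.
#' @examples
#' reg <- cgm_model_registry()
#' max(reg$k_max, na.rm = TRUE)  # 0.80
#' @export
cgm_model_registry <- function() {
  utils::read.table(
    system.file("extdata", "cgm_models.tsv", package = "canlight"),
    header = TRUE, sep = "\t", quote = "", fill = TRUE,
    stringsAsFactors = FALSE)
}

#' Ensemble median of the constant extinction coefficients
#'
#' Median K over the registry entries of constant type, using range
#' midpoints for models listed with a range. (An implementation
#' convention: how published ensemble medians collapse ranges is
#' generally unstated.)
#'
#' @return a single K value.
#' @export
registry_constant_median <- function() {
  reg <- cgm_model_registry()
  cst <- reg[reg$type == "constant", ]
  stats::median((cst$k_min + cst$k_max) / 2)
}

.model_names <- c("Kcst", "Kcstds", "KcstHS", "Kavr", "Ksph", "KsphC",
                  "Kell", "KellC")

#' Extinction model specification
#'
#' Names one of the eight light interception model families and carries
#' its parameters. Canopy-dependent quantities (GAI, theta_mean/chi,
#' clumping, Haun stage, sowing pattern) come from the [canopy_state()] at
#' evaluation time; the model object holds the model-level constants.
#'
#' @param name one of `"Kcst"`, `"Kcstds"`, `"KcstHS"`, `"Kavr"`,
#'   `"Ksph"`, `"KsphC"`, `"Kell"`, `"KellC"`.
#' @param k constant coefficient for `Kcst` (default 0.52, the ensemble
#'   median in use across wheat crop growth models).
#' @param theta average inclination (radians) for `Kavr`; default
#'   50 degrees (the GECROS wheat default). When `NULL`, the canopy's
#'   `theta_mean` is used.
#' @param k_meas_dif measured diffuse coefficient for the spherical family
#'   (default 0.6; drives both the diffuse FIPAR and, for `KsphC`, the
#'   clumping correction [c_sph()]).
#' @param sigma leaf scattering coefficient for [c_sph()] (default 0).
#' @param quad_order Gauss-Legendre order for hemispheric diffuse
#'   integrals (default 32).
#' @return an object of class `extinction_model`.
#' @examples
#' m <- extinction_model("KellC")
#' cs <- canopy_state(gai = 2, chi = 1.14, clumping = 0.79)
#' k_direct(m, deg2rad(45), cs)
#' @export
extinction_model <- function(name, k = 0.52, theta = deg2rad(50),
                             k_meas_dif = 0.6, sigma = 0, quad_order = 32) {
  name <- match.arg(name, .model_names)
  structure(list(name = name, k = k, theta = theta,
                 k_meas_dif = k_meas_dif, sigma = sigma,
                 quad_order = quad_order),
            class = "extinction_model")
}

#' @export
print.extinction_model <- function(x, ...) {
  cat(sprintf("<extinction_model> %s\n", x$name))
  invisible(x)
}

#' Direct-beam extinction coefficient of a model for a canopy
#'
#' Dispatches on the model family: constants ignore `beta`; `Kcstds` reads
#' density and row spacing, `KcstHS` the phenology, `Kavr` the (model or
#' canopy) mean inclination, the ellipsoidal models the canopy's `chi`,
#' and the clumped variants the relevant clumping factor, all from the
#' [canopy_state()].
#'
#' @param model an [extinction_model()].
#' @param beta sun elevation (radians, > 0), vectorised.
#' @param canopy a [canopy_state()].
#' @return K (same length as `beta`).
#' @export
k_direct <- function(model, beta, canopy) {
  if (!inherits(model, "extinction_model")) stop("`model` must be an extinction_model")
  if (!inherits(canopy, "canopy_state")) stop("`canopy` must be a canopy_state")
  n <- length(beta)
  switch(model$name,
    Kcst   = rep(k_constant(model$k), n),
    Kcstds = rep(k_salus(canopy$plant_density, canopy$row_spacing), n),
    KcstHS = rep(k_apsim_hs(canopy$haun_stage, canopy$final_leaf_number), n),
    Kavr   = k_avr_dir(beta, if (is.null(model$theta)) canopy$theta_mean
                             else model$theta),
    Ksph   = k_sph_dir(beta),
    KsphC  = k_sph_clumped(beta, c_sph(model$k_meas_dif, model$sigma)),
    Kell   = k_ell_closed(beta, canopy$chi),
    KellC  = k_ell_clumped(beta, canopy$chi, canopy$clumping))
}
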