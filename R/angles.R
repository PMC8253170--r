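#' Angle distribution of canopy surface elements
#'
#' Constructor for the inclination-angle distribution families used
#' throughout the package. `theta` is the inclination of a surface element
#' from the horizontal (0 = horizontal lamina, pi/2 = vertical stem).
#'
#' @param family one of `"ellipsoidal"`, `"spherical"`, `"fixed"`.
#' @param chi eccentricity of the ellipsoidal distribution (> 0); the
#'   spherical family is the `chi = 1` special case.
#' @param theta_fixed fixed inclination angle (radians) for the `"fixed"`
#'   family.
#' @return an object of class `angle_distribution`.
#' @export
angle_distribution <- function(family = c("ellipsoidal", "spherical", "fixed"),
                               chi = NULL, theta_fixed = NULL) {
  family <- match.arg(family)
  if (family == "ellipsoidal") {
    stopifnot_scalar(chi, "chi")
    if (chi <= 0) stop("`chi` must be > 0")
  }
  if (family == "spherical") chi <- 1
  if (family == "fixed") {
    stopifnot_scalar(theta_fixed, "theta_fixed")
    if (theta_fixed < 0 || theta_fixed > pi / 2)
      stop("`theta_fixed` must lie in [0, pi/2]")
  }
  structure(list(family = family, chi = chi, theta_fixed = theta_fixed),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  if (x$family == "fixed")
    cat(sprintf("<angle_distribution> fixed at %.1f deg\n", rad2deg(x$theta_fixed)))
  else
    cat(sprintf("<angle_distribution> %s (chi = %.3f)\n", x$family, x$chi))
  invisible(x)
}

## normalized ellipse area approximation
ellipse_lambda <- function(chi) chi + 1.774 * (chi + 1.182)^(-0.733)

#' Ellipsoidal inclination density
#'
#' Probability density (per radian) of surface inclination under the
#' ellipsoidal distribution of Campbell:
#' `g(theta) = 2 chi^3 sin(theta) / (Lambda (cos^2 theta + chi^2 sin^2 theta)^2)`
#' with the normalized ellipse area approximated as
#' `Lambda = chi + 1.774 (chi + 1.182)^-0.733`. Because Lambda is an
#' approximation, the density integrates to 1 only to within about 0.5%.
#'
#' @param theta inclination angle(s) in `[0, pi/2]`, radians.
#' @param chi eccentricity (> 0); `chi = 1` recovers the spherical density
#'   `sin(theta)` up to the Lambda approximation.
#' @return density value(s).
#' @export
ellipsoidal_pdf <- function(theta, chi) {
  stopifnot_scalar(chi, "chi")
  if (chi <= 0) stop("`chi` must be > 0")
  if (any(theta < 0 | theta > pi / 2)) stop("`theta` must lie in [0, pi/2]")
  2 * chi^3 * sin(theta) /
    (ellipse_lambda(chi) * (cos(theta)^2 + chi^2 * sin(theta)^2)^2)
}

#' Ellipsoid eccentricity from the mean canopy inclination angle
#'
#' Empirical relation `chi = (theta_mean / 9.65)^-0.6061 - 3` with the mean
#' inclination expressed in radians (the relation is only dimensionally
#' meaningful in radians; this is stated explicitly because it is easy to
#' get wrong). Decreasing in `theta_mean`: planophile canopies (small
#' mean angle) map to large chi, erectophile ones to small chi.
#'
#' For mean angles above ~87 degrees the relation returns a non-positive
#' chi; such values are outside the validity domain and are returned as
#' `NA` with a warning rather than silently clamped.
#'
#' @param theta_mean mean inclination angle (radians) in `(0, pi/2)`.
#' @return eccentricity chi.
#' @examples
#' chi_from_theta_mean(deg2rad(53))  # ~ 1.14
#' chi_from_theta_mean(deg2rad(70))  # ~ 0.50
#' @export
chi_from_theta_mean <- function(theta_mean) {
  if (any(theta_mean <= 0 | theta_mean >= pi / 2))
    stop("`theta_mean` must lie in (0, pi/2) radians")
  chi <- (theta_mean / 9.65)^(-0.6061) - 3
  if (any(chi <= 0)) {
    warning("theta_mean outside validity domain: chi <= 0 returned as NA")
    chi[chi <= 0] <- NA_real_
  }
  chi
}

#' Mean canopy inclination angle from ellipsoid eccentricity
#'
#' Inverts [chi_from_theta_mean()] by bracketed root finding on
#' `(0, pi/2)`. Round-trips the forward relation to within 1e-6 radians.
#'
#' @param chi eccentricity (> 0).
#' @return mean inclination angle in radians.
#' @examples
#' rad2deg(theta_mean_from_chi(1))  # ~ 56
#' @export
theta_mean_from_chi <- function(chi) {
  stopifnot_scalar(chi, "chi")
  if (chi <= 0) stop("`chi` must be > 0")
  ## closed-form inverse of the power law
  theta <- 9.65 * (chi + 3)^(-1 / 0.6061)
  if (theta <= 0 || theta >= pi / 2)
    stop("no solution in (0, pi/2) for chi = ", chi)
  theta
}

#' Area-weighted sample of surface inclination angles
#'
#' @param angles inclination angles (radians) in `[0, pi/2]`.
#' @param weights non-negative area weights (m2); default equal weights.
#' @param organ optional per-element organ labels (`lamina`, `stem`, `ear`).
#' @return an object of class `angle_sample`.
#' @export
angle_sample <- function(angles, weights = NULL, organ = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(angles) != length(weights))
    stop("`angles` and `weights` must have equal length")
  if (any(weights < 0)) stop("`weights` must be >= 0")
  if (any(angles < -1e-9 | angles > pi / 2 + 1e-9))
    stop("`angles` must lie in [0, pi/2]")
  structure(list(angles = pmin(pmax(angles, 0), pi / 2),
                 weights = weights, organ = organ),
            class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf("<angle_sample> %d elements, mean angle %.1f deg\n",
              length(x$angles), rad2deg(sample_mean_angle(x))))
  invisible(x)
}

#' Area-weighted mean inclination angle of a sample
#'
#' @param sample an [angle_sample()].
#' @return weighted mean angle (radians).
#' @export
sample_mean_angle <- function(sample) {
  if (!inherits(sample, "angle_sample")) stop("`sample` must be an angle_sample")
  tw <- sum(sample$weights)
  if (tw <= 0) stop("total weight must be > 0")
  sum(sample$weights * sample$angles) / tw
}

## cumulative distribution of an angle_distribution on a fine grid,
## by trapezoidal integration of the pdf; used for quantiles and KS
dist_cdf_grid <- function(dist, n_grid = 4096) {
  theta <- seq(0, pi / 2, length.out = n_grid)
  if (dist$family == "fixed") stop("fixed distributions have a degenerate CDF")
  g <- ellipsoidal_pdf(theta, dist$chi)
  cdf <- cumsum(c(0, (g[-1] + g[-n_grid]) / 2 * diff(theta)))
  cdf <- cdf / cdf[n_grid]
  list(theta = theta, cdf = cdf)
}

#' Draw random inclination angles from an angle distribution
#'
#' Inverse-CDF sampling on a fine quadrature grid (4096 points) for the
#' ellipsoidal/spherical families; the fixed family returns the fixed
#' angle.
#'
#' @param n number of draws.
#' @param dist an [angle_distribution()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return numeric vector of angles (radians).
#' @export
sample_angles <- function(n, dist, seed = NULL) {
  if (!inherits(dist, "angle_distribution"))
    stop("`dist` must be an angle_distribution")
  draw <- function() {
    if (dist$family == "fixed") return(rep(dist$theta_fixed, n))
    g <- dist_cdf_grid(dist)
    u <- stats::runif(n)
    stats::approx(g$cdf, g$theta, xout = u, ties = "ordered")$y
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Kolmogorov-Smirnov goodness of fit of an angle sample to a distribution
#'
#' Two-sample KS test of an (optionally area-weighted) empirical sample
#' against a reference sample drawn from `dist` by inverse-CDF on a fine
#' grid. Area weights are handled by resampling the empirical angles
#' proportionally to their weights (with replacement, at the original
#' sample size) before the test, under the given seed.
#'
#' @param sample an [angle_sample()].
#' @param dist an [angle_distribution()] (ellipsoidal or spherical).
#' @param reference_n size of the reference sample; must be at least the
#'   sample size. Default 4x the sample size.
#' @param seed integer seed for the reference draw (and weight resampling).
#' @return list with `statistic`, `p_value`, and `unreliable` (TRUE when
#'   the sample is degenerate, i.e. all angles equal).
#' @export
ks_fit_test <- function(sample, dist, reference_n = NULL, seed = 1L) {
  if (!inherits(sample, "angle_sample")) stop("`sample` must be an angle_sample")
  n <- length(sample$angles)
  if (n == 0) stop("`sample` must be non-empty")
  if (is.null(reference_n)) reference_n <- 4L * n
  if (reference_n < n) stop("`reference_n` must be >= the sample size")
  with_seed(seed, {
    x <- sample$angles
    if (any(sample$weights != sample$weights[1])) {
      x <- base::sample(x, size = n, replace = TRUE, prob = sample$weights)
    }
    ref <- sample_angles(reference_n, dist)
    degenerate <- length(unique(x)) == 1L
    ks <- suppressWarnings(stats::ks.test(x, ref))
    list(statistic = unname(ks$statistic), p_value = unname(ks$p.value),
         unreliable = degenerate)
  })
}

#' Read / write delimited angle-sample files
#'
#' Columns: `organ` (`lamina|stem|ear`), `theta_deg`, `area_m2`.
#'
#' @param path file path.
#' @param sample an [angle_sample()] (for writing).
#' @param sep field separator, default comma.
#' @return `read_angle_sample` returns an [angle_sample()];
#'   `write_angle_sample` returns `path` invisibly.
#' @export
read_angle_sample <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("organ", "theta_deg", "area_m2")
  if (!all(need %in% names(d)))
    stop("angle-sample file must contain columns: ",
         paste(need, collapse = ", "))
  angle_sample(deg2rad(d$theta_deg), d$area_m2, organ = d$organ)
}

#' @rdname read_angle_sample
#' @export
write_angle_sample <- function(sample, path, sep = ",") {
  if (!inherits(sample, "angle_sample")) stop("`sample` must be an angle_sample")
  organ <- if (is.null(sample$organ)) rep("lamina", length(sample$angles))
           else sample$organ
  utils::write.table(
    data.frame(organ = organ, theta_deg = rad2deg(sample$angles),
               area_m2 = sample$weights),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
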