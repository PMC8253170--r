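test_that("Beer-Lambert FIPAR basics", {
  expect_equal(fipar_from_k(0.7, 0), 0)
  expect_equal(fipar_from_k(0.5, log(2) / 0.5), 0.5)
  expect_equal(fipar_from_k(0.52, 3), 1 - exp(-1.56))
  # monotone in both arguments, bounded in [0, 1)
  gai <- seq(0, 8, by = 0.25)
  f <- fipar_from_k(0.6, gai)
  expect_true(all(diff(f) > 0) && all(f >= 0 & f < 1))
  expect_true(all(diff(fipar_from_k(seq(0.1, 1, 0.1), 2)) > 0))
})

test_that("diffuse FIPAR follows each family's convention", {
  cs <- canopy_state(gai = 2, chi = 1, clumping = 0.79)
  # constant-K: the hemispheric integral collapses exactly (2 int cos sin = 1)
  m <- extinction_model("Kcst", k = 0.52)
  expect_equal(fipar_dif_integral(m, cs), fipar_from_k(0.52, 2),
               tolerance = 1e-10)
  # zero canopy intercepts nothing
  expect_equal(fipar_dif_integral(extinction_model("KellC"),
                                  canopy_state(gai = 0, chi = 1)), 0)
  # spherical family uses the constant diffuse coefficient
  expect_equal(fipar_dif_integral(extinction_model("Ksph"), cs),
               fipar_from_k(0.6, 2))
  # ellipsoidal family: quadrature agrees with brute-force cosine-weighted
  # hemisphere sampling to well under 0.5%
  mk <- extinction_model("KellC")
  qd <- fipar_dif_integral(mk, cs)
  u <- canlight:::with_seed(99, stats::runif(1e6))
  mc <- mean(fipar_dir(mk, asin(sqrt(u)), cs))
  expect_lt(abs(qd - mc) / mc, 0.005)
})

test_that("three-class overcast coefficient for the average-inclination model", {
  th <- deg2rad(50)
  kb <- k_avr_dir(deg2rad(c(15, 45, 75)), th)
  # zero-GAI limit: the weighted mean of the class coefficients
  expect_equal(k_avr_dif(0, th), sum(c(0.178, 0.514, 0.308) * kb))
  # horizontal elements: K = 1 in every class, any GAI
  expect_equal(k_avr_dif(2, 0), 1, tolerance = 1e-12)
  expect_equal(k_avr_dif(0.5, 0), 1, tolerance = 1e-12)
  # bounded by the class coefficients
  k2 <- k_avr_dif(2, th)
  expect_gt(k2, min(kb)); expect_lt(k2, max(kb))
  # frozen regression value for the default wheat inclination
  expect_equal(k2, 0.7496616, tolerance = 1e-6)
})

test_that("instantaneous FIPAR is a convex combination", {
  expect_equal(fipar_instant(1, 0.7, 0.3), 0.7)
  expect_equal(fipar_instant(0, 0.7, 0.3), 0.3)
  expect_equal(fipar_instant(0.5, 0.2, 0.4), 0.3)
  expect_error(fipar_instant(1.2, 0.5, 0.5), "0, 1")
})

test_that("daily integration: PAR weighting, constants, and refinement", {
  cs <- canopy_state(gai = 1, chi = 0.5, clumping = 0.79)
  # constant-K model: daily FIPAR equals the analytic constant regardless
  # of the diurnal elevation course
  m <- extinction_model("Kcst", k = 0.52)
  for (doy in c(80, 172)) {
    dl <- fipar_daily(make_day(day_of_year = doy), m, cs)
    expect_equal(dl$fipar_day, fipar_from_k(0.52, 1), tolerance = 1e-12)
  }
  # daily FIPAR lies between min and max instantaneous FIPAR
  mk <- extinction_model("KellC")
  dl <- fipar_daily(make_day(), mk, cs)
  expect_gte(dl$fipar_day, min(dl$fipar_instant, na.rm = TRUE))
  expect_lte(dl$fipar_day, max(dl$fipar_instant, na.rm = TRUE))
  # halving the time step changes the daily value by < 0.2%
  dl2 <- fipar_daily(make_day(hours = seq(0.25, 23.75, by = 0.5)), mk, cs)
  expect_lt(abs(dl2$fipar_day - dl$fipar_day) / dl$fipar_day, 0.002)
  # all-dark day: undefined with a warning
  dark <- make_day(); dark$par_total_Wm2 <- 0
  expect_warning(dl0 <- fipar_daily(dark, mk, cs), "undefined")
  expect_true(is.na(dl0$fipar_day))
  expect_equal(dl0$ipar_day_MJm2, 0)
})

test_that("overcast days intercept less than clear days in erect canopies", {
  # low-GAI erectophile canopy at mid latitude, spring equinox: the diffuse
  # sky puts weight on low elevations where transmission is higher than at
  # the midday sun, so a fully overcast day intercepts less
  cs <- canopy_state(gai = 1, chi = 0.5, clumping = 0.79)
  mk <- extinction_model("KellC")
  clear <- fipar_daily(make_day(clearness = 0.75, f = 0.2), mk, cs)
  over <- fipar_daily(make_day(clearness = 0.15, f = 1.0), mk, cs)
  expect_lt(over$fipar_day, clear$fipar_day)
  # frozen magnitude for these conditions (~17% lower)
  expect_equal((over$fipar_day - clear$fipar_day) / clear$fipar_day,
               -0.168, tolerance = 5e-3)
})

test_that("directional sensitivity to mean inclination flips around mid elevations", {
  # steep sun: interception decreases with mean inclination; grazing sun:
  # it increases (erect canopies catch low sun). The vectors below are
  # indexed by increasing mean inclination (decreasing chi).
  chis <- chi_from_theta_mean(deg2rad(c(35, 45, 55, 65, 75)))
  f80 <- f15 <- numeric(length(chis))
  for (i in seq_along(chis)) {
    cs <- canopy_state(gai = 2, chi = chis[i], clumping = 0.79)
    mk <- extinction_model("KellC")
    f80[i] <- fipar_dir(mk, deg2rad(80), cs)
    f15[i] <- fipar_dir(mk, deg2rad(15), cs)
  }
  expect_true(all(diff(f80) < 0))
  expect_true(all(diff(f15) > 0))
})

test_that("cumulative IPAR is a running, non-decreasing sum", {
  expect_equal(cumulative_ipar(c(1.5)), 1.5)
  expect_equal(cumulative_ipar(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(cumulative_ipar(c(2, 2)), c(2, 4))
  cs <- canopy_state(gai = 1, chi = 1)
  m <- extinction_model("Kcst", k = 0.5)
  days <- list(fipar_daily(make_day(), m, cs),
               fipar_daily(make_day(day_of_year = 100), m, cs))
  ci <- cumulative_ipar(days)
  expect_true(all(diff(ci) >= 0))
  expect_equal(ci[1], days[[1]]$ipar_day_MJm2)
})
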