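# shared fixtures, built in code

# one day of hourly weather with a fixed clearness and diffuse fraction
make_day <- function(latitude_deg = 48.85, day_of_year = 80,
                     clearness = 0.75, f = 0.2,
                     hours = 0:23 + 0.5) {
  beta <- vapply(hours, function(h)
    solar_position(latitude_deg = latitude_deg, day_of_year = day_of_year,
                   solar_hour = h)$elevation, numeric(1))
  par0 <- extraterrestrial_par(beta)
  data.frame(solar_hour = hours, par_total_Wm2 = pmax(clearness * par0, 0),
             beta = beta, diffuse_fraction = f)
}

# stand emulating the start of stem extension: low GAI, mixed lamina/stem,
# standard 0.175 m rows, short canopy
gs31_scene <- function(seed, row_spacing = 0.175, n_rows = 4, gai = 1.2,
                       chi = 1.6, dispersion = 0.06) {
  generate_canopy(gai = gai, row_spacing = row_spacing, n_rows = n_rows,
                  row_length = 0.7, plant_density = 170,
                  lamina_dist = angle_distribution("ellipsoidal", chi = chi),
                  stem_dist = angle_distribution("fixed",
                                                 theta_fixed = deg2rad(75)),
                  organ_shares = c(lamina = 0.85, stem = 0.15, ear = 0),
                  dispersion = dispersion, tri_area = 1.5e-4,
                  canopy_height = 0.25, seed = seed)
}

# unclumped turbid-medium stand-in: independent uniform element placement
uniform_scene <- function(seed, chi = 1, gai = 1, tri_area = 1e-4) {
  generate_canopy(gai = gai, arrangement = "uniform",
                  lamina_dist = angle_distribution("ellipsoidal", chi = chi),
                  organ_shares = c(lamina = 1, stem = 0, ear = 0),
                  tri_area = tri_area, canopy_height = 0.4,
                  n_rows = 4, row_length = 0.7, seed = seed)
}

# non-overlapping horizontal triangles covering an exact ground fraction
planar_cover_scene <- function(cover = 0.3, ncell = 10, height = 0.2) {
  cell <- 1 / ncell
  a <- sqrt(2 * cover * cell^2)   # right-triangle legs, bbox inside the cell
  stopifnot(a < cell)
  x0 <- rep((seq_len(ncell) - 1) * cell, times = ncell) + 0.01 * cell
  y0 <- rep((seq_len(ncell) - 1) * cell, each = ncell) + 0.01 * cell
  n <- length(x0)
  triangle_scene(cbind(x0, y0, height), cbind(x0 + a, y0, height),
                 cbind(x0, y0 + a, height), rep("lamina", n),
                 footprint = c(1, 1))
}

# opaque strip covering half the footprint in every direction (torus)
half_slab_scene <- function(height = 0.3) {
  triangle_scene(rbind(c(0, 0, height), c(0, 0, height)),
                 rbind(c(0.5, 0, height), c(0.5, 1, height)),
                 rbind(c(0.5, 1, height), c(0, 1, height)),
                 c("lamina", "lamina"), footprint = c(1, 1))
}
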