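Package: canlight
Title: Canopy Light Interception Models for Cereal Crop Growth Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the family of Beer-Lambert light extinction
    coefficient models used in wheat crop growth models: constant
    coefficients (including density/row-spacing and Haun-stage variants),
    the average surface inclination model, the spherical distribution model
    with and without clumping, and the ellipsoidal leaf angle distribution
    model with canopy clumping. Includes solar geometry and diffuse/direct
    irradiance partitioning, instantaneous and daily integration of the
    fraction of intercepted photosynthetically active radiation (FIPAR), a
    synthetic row-structured 3D triangle canopy generator with a ray-cast
    gap-fraction reference, gap-fraction inversion to effective green area
    index and clumping factor, goodness-of-fit tools for inclination angle
    distributions, a minimal light-use-efficiency growth coupling, and an
    intercomparison harness quantifying how the choice of light model
    propagates into intercepted radiation, biomass and yield.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
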