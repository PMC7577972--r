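Package: turbflux
Title: Turbulence-Driven Nutrient Fluxes from Microstructure and Hydrographic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain from raw microstructure shear records and
    CTD/bottle hydrography to turbulent kinetic energy dissipation rates
    (iterative Nasmyth-spectrum integration), Thorpe-resorted stratification
    and Osborn eddy diffusivity, temperature-based nutrient reconstruction,
    vertical turbulent nitrate and phosphate fluxes, and Redfield-ratio
    new-production and steady-state chlorophyll depletion budgets. Includes
    a seeded synthetic-data generator (Nasmyth-spectrum shear, stratified
    density profiles with injected overturns, bottle chemistry and
    fluorescence) so every stage carries parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
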