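Package: ossify
Title: Coupled Bone Remodelling and Mineralization Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic daily-resolution simulator of coupled bone
    remodelling and matrix mineralization in a representative tissue volume.
    Bone material is tracked as an age-structured cohort array; basic
    multicellular units (BMUs) resorb preferentially young, weakly mineralized
    bone within a porosity-dependent temporal window, while a three-phase
    mineralization law (lag, primary, secondary) raises the mineral content of
    surviving cohorts. The package reproduces the boomerang-shaped relationship
    between apparent density and material density across the cancellous to
    cortical range, and its translation under overload and disuse loading.
    Includes scenario runners, initial-volume-fraction sweeps, broom-style
    tidiers, ggplot2 plotting methods and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
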