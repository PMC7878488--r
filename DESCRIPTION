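Package: rangecap
Title: Rangeland Carrying Capacity Accounting with Wild Ungulate Coexistence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating livestock carrying capacity of alpine
    rangelands while accounting for the forage demand of coexisting wild
    ungulates. Converts line-transect survey records into species abundance
    densities, interpolates them onto a regular grid by ordinary kriging,
    constrains the interpolated surfaces with a presence-only maximum-entropy
    habitat model, derives grass yield from NDVI composites, and closes a
    per-parcel ledger of theoretical, ecological and residual carrying
    capacity in sheep units. Includes a synthetic-county generator with known
    latent truths so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
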