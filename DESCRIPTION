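Package: cpcfnpm
Title: Nutrient and Promotion Profiling of Commercially Produced Complementary Food Purees and Meals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an adapted WHO-Europe nutrient and promotion profile
    model (NPM) for ready-to-eat commercially produced complementary food
    (CPCF) purees and meals marketed for children aged 6-36 months. Products
    described by structured label records are assigned to one of nine
    puree/meal subcategories from their ingredient composition, product name
    and texture; assessed against six nutrient-composition requirements with
    per-subcategory thresholds (added sugars and sweeteners, fruit content,
    energy density, sodium, total fat, protein) and seventeen labelling
    requirements in five groups; and flagged where a high-sugar front-of-pack
    warning would be required from the percentage of energy contributed by
    total sugar. Market-level reports aggregate pass proportions, high-sugar
    warning shares and median [IQR] nutrient summaries per subcategory. A
    seeded synthetic label generator with known ground truth emulates a
    realistic market so the whole pipeline is testable without proprietary
    label data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
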