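Package: procrastinatr
Title: Temporal Discounting Models of Procrastination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational models of procrastination grounded in temporal
    discounting. Converts monetary-equivalence ratings into subjective unit
    values, fits hyperbolic, present-bias and quasi-hyperbolic discounting
    models to intertemporal choices by maximum a posteriori estimation with
    Laplace-approximated log model evidence, scores one-shot now/tomorrow
    decisions with a net-value choice rule, and predicts recurrent
    task-completion delay under a deadline with both a static (one-shot
    argmax) and a dynamic (iterated daily decision) model. Includes a
    synthetic-data generator emulating the behavioral study design, model
    and parameter recovery utilities, and group-level regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
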