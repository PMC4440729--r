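Package: gcff
Title: Detection of Free-Standing Conversational Groups from Proxemic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects free-standing conversational groups (F-formations) in a
    single frame from each individual's ground-plane position and head
    orientation.  Models each person's transactional segment as an isotropic
    Gaussian centred one stride ahead of the body, and finds shared o-space
    centres by minimising a least-squares objective with a minimum description
    length penalty on the number of groups and a soft visibility (occlusion)
    constraint.  Ships the tolerant-match evaluation metrics (precision,
    recall, F1, Global Tolerant Matching, cardinality-stratified F1), a
    synthetic scene generator covering vis-a-vis, L-shape, side-by-side and
    circular arrangements, a Gaussian proxemic-noise protocol, JSON/CSV
    interchange formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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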