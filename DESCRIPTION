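Package: queentrack
Title: Foraging Trip Inference from Bidirectional RFID Reads at Bumble
    Bee Nests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers nest entrance and exit events, out-of-nest foraging
    trips, and in-nest stays of trap-nested bumble bee foundress queens
    from raw bidirectional RFID read streams (paired inner/outer antenna
    boards at the nest entrance). Implements read pairing within a strict
    time window, direction labeling, relabeling of lone reads, removal of
    spurious inner-board reads, micro-trip and power-outage filtering;
    per-queen foraging summaries, trimodal in-nest stay statistics,
    extended and overnight trip reports, queen fate flows, and
    early-versus-late foundress-stage comparisons with linear and
    negative-binomial mixed models; validation of RFID event streams
    against in-person observation logs; and a seeded synthetic-data
    generator with a per-board detection-error sensor model for
    end-to-end pipeline testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmmTMB,
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
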