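Package: velomatch
Title: Climate-Change Velocity Fields and Species Range-Shift Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the velocity of climate change from gridded
    temperature fields by two alternative methods, the gradient method
    (temporal rate of change divided by the spatial gradient, directed
    down-gradient) and a Monte-Carlo iterative grid-deformation method
    that registers an initial decadal-mean field onto a final one while
    penalizing shear of the displacement field. Tracks species range
    shifts as weighted geodesic centroids of observation records,
    applies report-frequency inclusion filters for count (bird-survey)
    and presence (trawl-survey) data, decomposes shifts into
    longitudinal, latitudinal and elevational velocities against a
    digital elevation model, and compares species velocities with the
    climate velocities by per-decade linear fits with outlier removal,
    linear mixed models with a species random term, multilinear fits and
    circular heading summaries. Includes a synthetic-data generator for
    temperature fields, elevation models and advected species records so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
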