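Package: phosvpl
Title: Simulated Phosphene Vision, Reading Acuity Psychometrics, and
    Session-Type Learning-Rate Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal studies of visual perceptual learning
    under simulated prosthetic vision. Generates center-weighted phosphene
    fields, renders gaze-contingent "veridical encoding" frames (each
    phosphene samples local image luminance and is redisplayed as a 2D
    Gaussian at that luminance), schedules video frames onto faster monitor
    refreshes, scores MNREAD-style reading trials and extracts equivalent
    acuity as the 50% point of a fitted logistic psychometric function,
    builds syncopated reading-test/video-session schedules, linearly decodes
    per-session learning rates for active (reading) versus passive (video)
    tasks from short- and long-span acuity improvements, summarises gaze
    scan paths, and simulates complete synthetic cohorts for parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
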