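Package: soleusExo
Title: Soleus-Energetics-Based Ankle Exoskeleton Torque Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates assistive ankle-exoskeleton torque profiles from soleus
    muscle-tendon dynamics using an ATP-hydrolysis-rate model of the fascicles.
    Implements two controllers: a force-scaled profile that weights the
    plantarflexion joint torque by the net ATP hydrolysis rate, and a
    deadbanded profile driven by the rate alone with a fascicle-speed deadband
    set at peak tendon lengthening velocity. Includes ingestion and
    re-normalisation of gait-cycle curve tables, reconstruction of
    human-in-the-loop reference torque profiles from their key parameters,
    profile comparison via onset/peak/offset key points, cosine similarity and
    the discrete Frechet distance, and a seedable synthetic generator of
    muscle-tendon dynamics for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
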