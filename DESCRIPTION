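Package: cervosim
Title: Multiscale Simulation of Cervical Tumour Response to
    Chemoradiotherapy and Pulsed-Dose-Rate Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@cervosim.org",
           role = c("aut", "cre"))
Description: A cellular-automaton oncosimulator of cervical tumour response
    to external-beam radiotherapy with concomitant weekly cisplatin followed
    by pulsed-dose-rate brachytherapy.  The package provides the
    linear-quadratic cell-survival mathematics with an incomplete-repair
    (Lea-Catcheside) correction for pulsed irradiation, an hourly
    cytokinetic model of stem, progenitor and differentiated tumour-cell
    compartments on a voxel lattice, tumour initialization from clinically
    meaningful tumour profiles (growth, hypoxic and dead fractions),
    profile-based parameter-space calibration against longitudinal tumour
    volumes, mean-value parameter sets, and a patient-pair scoring framework
    that quantifies the similarity of tumour regression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
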