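Package: drgsqa
Title: Dose-Rate/Gantry-Speed QA for VMAT Linacs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for routine linac quality assurance of volumetric-modulated
    arc therapy (VMAT) delivery at clinically relevant gantry speeds. Profiles
    the monitor-units-per-degree (MU/deg) kinematics of arc DICOM RT Plans
    control point by control point, computes the critical MU/deg at which a
    machine saturates its dose rate and begins modulating gantry speed,
    rescales dose-rate/gantry-speed (DRGS) strip-test plans so that they probe
    the slow gantry speeds reached by stereotactic body radiotherapy plans, and
    analyzes paired EPID strip/open-field portal images with a per-ROI percent
    deviation statistic against stored machine baselines. Includes a minimal
    DICOM reader/writer for the RT Plan and RT Image element subset the
    toolkit touches, and deterministic synthetic fixture generators (plans,
    cohorts, and EPID image pairs) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
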