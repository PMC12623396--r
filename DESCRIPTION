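Package: rspkin
Title: Motion-Capture Kinematics for Running-Specific Prostheses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Marker-based motion-capture pipeline for sprinters with
    transfemoral or transtibial amputation. Reads and writes C3D trials,
    performs wand-tip and static (CAST) landmark calibration, reconstructs
    virtual and static-only markers in dynamic trials with singular value
    decomposition rigid-pose fits, constructs the protocol coordinate
    systems of the prosthetic limb (socket, socket-clamp, functional
    prosthetic knee, foot-clamp, running prosthetic foot) and sound-side
    segments, and decomposes joint and segment rotations with Cardan
    sequences. Includes a forward-kinematics synthetic rig generator with
    ground truth for end-to-end verification, and a three-command
    processing pipeline (configure, process-static, analyze).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    xml2,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
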