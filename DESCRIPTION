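Package: skelchron
Title: Skeletochronological Back-Calculation and Validation for Sea Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Back-calculates straightline carapace lengths (SCL) from humerus
    growth-mark diameters in sea turtles using the body proportional
    hypothesis, assigns calendar years to lines of arrested growth (LAGs),
    validates back-calculated lengths against mark-recapture measurements
    with an exact Wilcoxon signed-rank test, and infers the seasonal timing
    of LAG deposition from oxytetracycline (OTC) bone marks.  Includes a
    forward simulator of individual bone and somatic growth for
    parameter-recovery testing, CSV readers and writers for turtle and bone
    tables, and a bundled ten-turtle Hawaiian green turtle validation
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
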