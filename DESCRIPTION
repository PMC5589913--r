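Package: epiratchet
Title: Quantification of Interfacial Ratcheting During Epithelial Cell Intercalation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how transient membrane compartments rectify
    oscillatory junction contractions during epithelial cell intercalation.
    Provides seeded-watershed segmentation and tracking of membrane-labelled
    time-lapse movies into a vertex-interface-cell tissue model; mean squared
    displacement (MSD) decomposition of interface-length trajectories into
    confined, diffusive and active components; rolling-window MSD-exponent
    step detection (the ratchet readout); analytic-signal (Hilbert) amplitude
    of apical-area oscillations; a-trous wavelet spot detection with
    assignment-based tracking and gap closing; compartment-interface
    association, planar-polarity, pairing and colocalization analytics; and a
    ground-truthed synthetic-data generator so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
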