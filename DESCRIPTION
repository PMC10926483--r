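Package: optomotr
Title: Optomotor Trackball Trajectory Analysis and Behavioral Response Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying insect optomotor behavior from tethered-walking
    trackball (FicTrac-style) trajectories under rotational optic-flow stimulation.
    Reads FicTrac v2 logs, aligns frames to an open-loop stimulus schedule of
    alternating leftward/rightward grating epochs, and extracts five per-animal,
    per-stimulus behavioral response features (maximum accumulated rotation, path
    tortuosity, walking pace, absolute turning velocity, and rotation asymmetry).
    Discovers behavioral response types by subsampled k-means consensus clustering
    with Monte-Carlo reference-based selection of the cluster count (PAC/RCSI),
    provides nonparametric group comparisons (Kruskal-Wallis, Mann-Whitney U,
    Bonferroni), chronic-exposure dose arithmetic, and a ground-truthed synthetic
    trajectory generator emulating distinct behavioral archetypes for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
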