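Package: icnet
Title: Informational Connectivity and Learning-Rate Analysis for
    Pre/Post Cognitive-Training fMRI Studies
Version: 0.1.0
Authors@R:
    person("icnet", "developers", email = "icnet@example.org",
           role = c("aut", "cre"))
Description: Tools for network-level analysis of task-fMRI multivoxel
    patterns in pre/post training designs: least-squares-separate
    single-trial response estimation with framewise-displacement motion
    censoring, within-context representational similarity matrices
    restricted to cross-run trial pairs, ROI-pair informational
    connectivity (correlation of representational similarity structure),
    permutation-based edgewise group-contrast inference with
    Benjamini-Hochberg false discovery rate control, multivariate
    connectivity-profile distances between contexts, and the behavioral
    training and transfer learning-rate statistics used in cognitive
    training studies. Includes a synthetic-data generator with planted
    ground-truth connectivity effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
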