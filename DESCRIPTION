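Package: foldnx
Title: Minimal Folding Transformations of Polymer Chains Under
    Non-Crossing Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes approximately minimal folding transformations of
    coarse-grained polymer chains, accounting for chain non-crossing.  A
    chain is evolved between two conformations as a "ghost" chain along
    straight per-bead paths, all unphysical self-crossing events are
    recorded via signed projection-crossing matrices, and the minimal
    extra uncrossing distance (D_nx) that a real chain would have needed
    to avoid those crossings is found by a depth-first branch-and-bound
    search over canonical leg, loop (Reidemeister-I pinch), and elbow
    uncrossing moves.  Includes a native-biased pivot-algorithm generator
    for unfolded ensembles of protein C-alpha traces, structure-derived
    order parameters (LRO, RCO, ACO, MRSD, INX), class-discrimination
    statistics, scaling-law fits, consensus minimal-pathway histograms,
    and a pathway-overlap order parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
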