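Package: calyxSFR
Title: Structure-Function Analysis of the Developing Calyx of Held Synapse
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking in vivo synaptic physiology to 3D light-microscopy
    quantification of presynaptic terminal contact area at the developing calyx
    of Held synapse in the medial nucleus of the trapezoid body (MNTB). The
    package detects excitatory postsynaptic potentials (EPSPs), action
    potentials and calyceal prespikes in whole-cell membrane-potential
    recordings, decomposes evoked responses into discrete synaptic inputs via a
    Welch-t recruitment rule over afferent stimulation intensities, segments
    biocytin-filled somata and VGluT-positive terminal clusters in anisotropic
    3D fluorescence volumes (IsoData thresholding, sphere-probe and 26-connected
    flood fill, dilation-optimised contact measurement), and fits the
    structure-function power law relating EPSP rate of rise to somatic contact
    area. A synthetic-data module generates traces and voxel volumes with full
    ground truth so that every stage of the analysis is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'calyxSFR-package.R'
    'detect.R'
    'inputs.R'
    'io.R'
    'synth_cohort.R'
    'synth_volume.R'
    'synth_traces.R'
    'pipeline.R'
    'seg3d.R'
    'stats_sfr.R'
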