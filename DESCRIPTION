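Package: radialFISH
Title: Radial Chromosome Territory Positioning from FISH Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the radial nuclear position of chromosome
    territories in fluorescence in situ hybridisation (FISH) images.
    Implements the classical 2D erosion-shell assay (five concentric
    shells of equal area, probe signal normalised to DAPI per shell,
    aggregation with standard errors, and ordinal peripheral /
    intermediate / interior categorisation), a 3D assay measuring the
    distance from each territory's geometric centre to the nearest
    nuclear edge in anisotropic confocal stacks with 0.5 micron binned
    frequency distributions, Welch t-test based between-condition
    comparisons, and the chromosome-size versus radial-position
    association. A synthetic FISH image generator with exact ground
    truth, including presets emulating proliferating, quiescent and
    senescent fibroblast conditions, makes the whole pipeline testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, graphics, grDevices, utils, EBImage, tiff
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
biocViews: CellBiology, Visualization, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'geometry.R'
    'io.R'
    'segment.R'
    'radial3d.R'
    'shells.R'
    'utils.R'
    'simulate.R'
    'stats.R'
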