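Package: opmtools
Title: Oblique Plane Microscopy Reconstruction, Optical Simulation, and
    Single-Molecule Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computational toolkit for two-photon oblique plane microscopy
    (2P-OPM). Reconstructs raw oblique (sheared) light-sheet stacks into
    Cartesian volumes by the skew/scale/rotate affine with trilinear
    resampling, and provides the matching forward acquisition model for
    closed-loop testing. Simulates the tilted remote-focus detection point
    spread function from the overlap of the secondary and tertiary objective
    acceptance cones, and designs and simulates "layer-cake" annular-zone
    Bessel-like two-photon excitation foci with a common per-zone axial
    extent. Implements image-quality statistics (coefficient-of-variation
    contrast, depth-contrast profiles, radial Fourier spectra, and a
    gain-invariant heterogeneity index), photon calibration from camera
    digital numbers, Cramer-Rao localization precision with tilt-mixed PSF
    widths, and localization-noise-corrected mean-squared-displacement
    diffusion estimation from single-particle track tables, together with
    seeded synthetic-data generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tiff, jsonlite, minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Microscopy, SingleCell, Visualization, Preprocessing
RoxygenNote: 7.3.3
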