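Package: tissuescope3d
Title: Multi-Scale 3D Reconstruction and Morphometry of Dense Tissue from
    Confocal Image Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building digital geometrical models of dense tissue
    (exemplified by mouse liver) from multi-channel 3D confocal stacks:
    Bayesian foreground/background de-noising under a depth-dependent Poisson
    noise model, tile mosaicking by global normalized cross-correlation,
    Bayesian section-surface detection with iterated-conditional-modes
    refinement and spline unbending, local maximum-entropy segmentation of
    tubular networks, triangle meshing with active-mesh tuning and expansion,
    skeletonization of sinusoidal and bile-canalicular networks into
    attributed graphs, splitting of optically merged nuclei by ellipsoid
    model selection and Laplacian-of-Gaussian seeding, marker-less cell-type
    classification from 74 nuclear features (a linear-discriminant cascade
    and a K2-learned Bayesian network), a synthetic 4-channel benchmark
    generator with point-spread-function blur and depth-dependent Poisson
    noise, and morphometric/zonation analysis (cylinder consistency,
    central-to-portal vein coordinate, ploidy clustering, log-normal
    mixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    Rcpp,
    MASS,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
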