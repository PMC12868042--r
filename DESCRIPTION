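Package: phantomForge
Title: Patient-Realistic Computational Phantoms via Unpaired Style Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning noise-free piecewise-constant digital
    anthropomorphic phantoms (CT and MRI) into patient-like volumes by
    unpaired image-to-image translation with a CycleGAN whose generator
    objective combines adversarial, cycle-consistency, intensity and
    gradient-difference terms. Includes the full surrounding pipeline:
    NIfTI/MetaImage volume I/O and in-plane resampling, CT clipping and
    body masking, [-1,1] intensity normalization with exact inversion,
    patch extraction and deterministic tiling with mean-fusion
    reconstruction, a self-contained convolutional network engine with
    manual backpropagation and Adam, a synthetic abdominal phantom
    generator for desk-scale experiments, paired similarity metrics
    (MAE, SSIM, FSIM, edge preservation/generation ratios, PSNR, NCC,
    RMSE, pluggable LPIPS), unpaired realism statistics (liver noise
    magnitude, radial noise power spectrum, histogram correlation), and
    dose-volume-histogram summaries (D95%, D2%) for dosimetric checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
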