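Package: ctdenoise
Title: Convolutional Denoising and Quality Evaluation for Low-Dose CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired high/low-dose computed-tomography denoising
    studies: a convolutional encoder-decoder network with DnCNN-style
    refinement blocks trained on paired slices, a synthetic phantom
    generator producing organ-like Hounsfield-unit regions with
    dose-dependent noise, six paired image-quality metrics (MSE, PSNR,
    SSIM, VIF, EPI, noise variance), circular-ROI Hounsfield-unit noise
    analysis, and reader-study Likert statistics (one-sample t-tests
    against the neutral midpoint, Holm adjustment, Cohen's d, confidence
    intervals) including exact reconstruction of integer score sets from
    printed summary tables. Minimal DICOM input/output is included so
    whole pipelines run from files on disk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
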