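Package: voxgan
Title: Conditional 3D GAN Reconstruction of Anatomical Volumes from Tomographic Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reconstructing volumetric anatomical models from sets of
    tomographic slices with a conditional three-dimensional generative
    adversarial network. The generator couples a multi-scale local feature
    fusion front block with a 3D U-Net encoder-decoder and a ResNet-style
    refiner; training combines least-squares adversarial objectives with a
    composite reconstruction loss made of an L1 distance term, a
    multi-threshold voxel-overlap feature term, and a slice-wise structural
    similarity term. The package also provides synthetic CT-like phantom
    generation (vertebra, liver, sphere), NIfTI and 16-bit TIFF slice-stack
    volume input/output, and a full volumetric evaluation protocol: voxel
    confusion matrices at quantile-derived thresholds, IoU, Dice, F1,
    precision, recall, L1, PSNR, UQI, VSI, volume SSIM, and a
    quartile-to-quartile threshold sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
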