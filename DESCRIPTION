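Package: fuseqa
Title: Conditional-GAN Quality Assessment for Multimodal Medical Image Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Full-reference quality assessment of multimodal medical image
    fusion (CT/MRI/PET). A generator conditioned on the mean opinion score
    (MOS) learns, adversarially against a patch discriminator, to synthesise
    fused images that match a requested quality level; a fused image is then
    scored as the MOS condition whose generated counterpart is most similar
    to it under the structural similarity index (SSIM). The package contains
    the dual-channel conditioned encoder-decoder, the hierarchical
    self-attention fusion blocks, the adversarial training loop with
    reconstruction regularisation, the five-condition SSIM scorer, the
    SRCC/KRCC/PLCC/RMSE agreement report, and a synthetic brain-phantom
    module that produces registered pseudo-modality pairs with graded-quality
    fusions and known MOS labels so the whole pipeline is trainable and
    testable offline. Network layers run on a compact reverse-mode tape
    engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
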