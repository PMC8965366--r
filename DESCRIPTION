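Package: ffgan
Title: Cross-Modality MRI-to-PET Synthesis and Diagnosis with a
    Feature-Fusion GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage hybrid deep-learning pipeline for two-class
    diagnosis from incomplete multimodal neuroimaging: pretrain a
    dual-branch multimodal fusion classifier on paired MRI/PET volumes,
    train a 3-D U-Net generator with an adversarial + L1 + feature-fusion
    loss computed through the frozen fusion model, then fine-tune the
    classifier on synthesized PET, iterating the last two stages. Includes
    a synthetic 3-D cohort generator so the complete pipeline runs at desk
    scale, patch extraction and overlap-averaged reassembly, classification
    and image-quality metrics, and Grad-CAM saliency volumes. All networks,
    losses and the reverse-mode gradient engine are implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
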