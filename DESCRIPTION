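Package: voxelflow
Title: Slice-Based Anomaly Localization in 3D Volumes with Conditional
    Normalizing Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised anomaly detection and localization for 3D
    volumetric images (e.g. brain MRI) using a 2D slice feature encoder,
    depth-wise feature aggregation and a conditional normalizing flow
    trained with feature-space noise-synthesized anomalies and a
    contrastive boundary loss. Includes a synthetic phantom generator
    with ground-truth lesion masks, NIfTI preprocessing utilities
    (center crop, intensity rescaling, resize-and-pad), per-voxel
    log-likelihood scoring with per-volume and dataset-level score
    normalization, and segmentation-oriented evaluation metrics (AUROC,
    AUPRC, PRO, maximum Dice / F1 and confusion-matrix metrics at the
    F1-optimal threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
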