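Package: cdti
Title: Ex Vivo Cardiac Diffusion Tensor Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo cardiac diffusion tensor imaging
    (cDTI): log-linear pseudo-inverse tensor estimation from diffusion
    weighted volumes, fractional anisotropy and apparent diffusion
    coefficient maps, helix-angle and secondary eigenvector angle (E2A)
    mapping in a local cardiac coordinate system, AHA 17-segment regional
    statistics with transmural profiles and gradients, multiple-acquisition
    SNR estimation with parallel-imaging normalization, and variable flip
    angle T1 / multi-echo T2* relaxometry.  Includes a synthetic left
    ventricle phantom generator (annular geometry, transmural helix-angle
    rule, Stejskal-Tanner signal simulation, Rician noise) so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
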