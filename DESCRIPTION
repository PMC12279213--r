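Package: uncertmol
Title: Uncertainty-Aware Surrogate-Based Inverse Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse molecular design by gradient optimization in a learned
    molecular latent space. Trains a multi-view variational autoencoder on
    robust string representations, 3D conformer graphs and molecular
    properties; reacquires latent-property training pairs by decoding
    prior samples and relabelling them with a pluggable forward oracle;
    fits a deep ensemble of property surrogates with stochastically gated
    updates; and optimizes latent designs under the ensemble's mean
    prediction penalized by its epistemic uncertainty, so that generated
    molecules stay in regions where the surrogate is aligned with the
    ground-truth forward process. Includes evaluation metrics (oracle
    error, novelty, uniqueness, surrogate-oracle misalignment) and a
    representation-perturbation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
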