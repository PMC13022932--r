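Package: fedbids
Title: Federated Learning for BIDS-Organised Brain-MRI Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A server/client federated-learning toolbox for regression on
    BIDS-organised T1-weighted brain MRI (brain age, cognitive scores).
    Implements sampled, sample-size-weighted federated averaging over a
    two-file (payload + completion marker) transmission protocol, per-round
    bootstrapped local training with shallow or deep transfer-learning freeze
    policies on a fully specified 3D DenseNet regression network, leak-free
    subject-level data splitting, deterministic NIfTI preprocessing
    (RAS reorientation, isotropic resampling, centre crop/zero-pad), the
    matching centralised benchmark runner, and evaluation via per-client and
    sample-size-weighted overall mean absolute error, Pearson correlation,
    and brain-age-difference bias diagnostics. Ships a synthetic BIDS phantom
    generator so the whole federation is exercisable end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
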