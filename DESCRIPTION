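Package: tcrboltz
Title: Probabilistic Models of T-Cell Receptor Repertoire Response
Version: 0.1.0
Authors@R: person("tcrboltz", "developers", role = c("aut", "cre"),
    email = "tcrboltz@example.org")
Description: Sequence-based probabilistic modeling of T-cell receptor (TRB
    CDR3) repertoires sampled before and after antigen stimulation. Provides
    clonotype table input/output and count-weighted datasets, a fixed-length
    CDR3 multiple sequence alignment built from per-length position weight
    matrices, progressive profile-profile alignment and a profile hidden
    Markov model, a Restricted Boltzmann Machine with double-rectified
    (dReLU) hidden units trained on count-weighted repertoires, an
    independent-site Left+Right selection-factor model with pluggable
    background distributions, clonal expansion calling (fold change, Fisher
    exact test, Storey q-values), probabilistic response and specificity
    scores with AUROC evaluation, a Levenshtein-kernel repertoire
    dissimilarity index, and a synthetic repertoire generator with planted
    motifs and planted clonal expansion for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
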