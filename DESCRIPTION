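Package: hyperalignR
Title: Hyperalignment and Between-Subject Decoding of fMRI Response Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a common high-dimensional representational space from
    multi-subject voxel time series by iterative orthogonal Procrustes
    alignment (hyperalignment), maps held-out task data into that space, and
    compares within-subject, anatomically aligned between-subject, and
    hyperaligned between-subject multivariate pattern classification.
    Includes a synthetic multi-subject fMRI study generator with known
    ground truth, voxel-wise preprocessing, a multiclass linear support
    vector machine with pairwise majority voting, leave-one-run-out and
    leave-one-subject-and-one-run-out cross-validation, searchlight mapping,
    subject-order permutation analysis, and leave-one-subject-out
    generalization of the common model space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    yaml,
    jsonlite,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
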