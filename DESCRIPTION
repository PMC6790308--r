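Package: langmapr
Title: Presurgical Language Mapping from Task and Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presurgical language mapping from BOLD fMRI in MNI
    template space: block-design GLM activation mapping with the canonical
    double-gamma haemodynamic response, spatial independent component
    analysis (extended Infomax) of resting-state runs, rule-based
    identification of the language resting-state network against attention,
    salience and fronto-parietal control networks, hemispheric
    lateralization indices, second-order paired comparison of task and rest
    maps, and concordance of fMRI peaks with intraoperative electrocortical
    stimulation sites under a 10-mm detection rule. Includes a seeded
    synthetic BOLD generator for validation and fixtures with the cohort,
    laterality and stimulation-outcome tables of a 50-patient awake-surgery
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
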