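Package: harmalloc
Title: Hierarchical Bayesian Modelling of Rawlsian and Utilitarian Harm Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people trade off harm to a single
    individual against harm spread over a group. Provides the harm-allocation
    task design (choice pairs of cold-pressor durations under three default
    conditions), a family of softmax utility models mixing maximin (Rawlsian)
    and utilitarian preferences with an agreeability threshold, hierarchical
    Bayesian estimation via JAGS with noncentered parameterization,
    Pareto-smoothed importance-sampling leave-one-out model comparison,
    posterior predictive checks, parameter-recovery simulation, model-free
    behavioral statistics with Greenhouse-Geisser corrected repeated-measures
    tests, and intersubject representational similarity analysis (IS-RSA)
    via voxelwise dyadic mixed-model regression with FDR cluster thresholding.
    Includes a synthetic-data generator for cohorts and voxelwise beta maps
    so the full pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    rjags,
    coda,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    methods,
    lme4,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
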