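Package: phbold
Title: Pharmacological MRI BOLD Activation Mapping and Dose-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological MRI (phMRI) BOLD studies in
    awake rodents: voxelwise percent signal change against a pre-injection
    baseline window, mass-univariate Welch t-tests with a magnitude threshold
    and a rank-based false-positive (step-up FDR) filter, affine registration
    of subjects to a segmented brain atlas, group composite maps built by
    inverse-transform trilinear sampling, regional volume-of-activation
    dose-response statistics (Kruskal-Wallis with Wilcoxon post hocs and a
    region-list FDR cutoff), and treatment-by-time ANOVA on regional BOLD
    time courses. Includes a synthetic 4D BOLD cohort generator with known
    ground truth (labeled atlas, per-subject affine transforms, injected
    dose-dependent responses, motion traces) so every stage is testable
    without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
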