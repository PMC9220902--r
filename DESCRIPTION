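Package: pdmprofiler
Title: Functional Drug-Response Profiling of Patient-Derived Microtumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing and statistical analysis of functional precision
    oncology readouts from patient-derived microtumor (PDM) models:
    reverse-phase protein array (RPPA) profile normalization (blank
    filtering, per-protein median centering, log2 transformation),
    hierarchical clustering and pathway-panel summaries; plate-based drug
    cytotoxicity analysis with robust modified Z-score outlier removal,
    DMSO-normalized fold changes, two-way ANOVA with control comparisons
    and ordinal 0-3 sensitivity grading; responder-signature mining with a
    20 percent mean-difference filter, pathway-level Mann-Whitney tests and
    Spearman correlation of protein abundance with graded sensitivity;
    treated-to-vehicle ratio (TR) time-course analysis of drug
    mode-of-action; and image-derived quantification of immune-cell
    mediated microtumor killing from fluorescence mask sums. A synthetic
    cohort generator with known ground truth emulates every input so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
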