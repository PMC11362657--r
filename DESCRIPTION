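Package: healthperf
Title: Health Performance Assessment for Insured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the health performance of an enrolled (insured)
    population from claims data. Enrollees are assigned to health-risk
    groups defined by family-doctor contract status, age band, sex,
    consultation-category pattern and visit-count level; groups are
    classified into six resource-utilization classes by cost weight
    (group mean cost relative to the per-capita reference mean); class
    headcount and expense shares are compared across years to judge
    whether population health is improving; and risk-adjusted capitation
    budgets are allocated to medical communities and settled against
    actual expenses with balance retention. A synthetic multi-year
    claims generator with latent morbidity states makes the whole
    pipeline testable without access to real insurance data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
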