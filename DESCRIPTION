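Package: msdactivity
Title: Moving Standard Deviation of Trunk Acceleration for Physical
    Activity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the moving standard deviation of the triaxial trunk
    acceleration norm (MSDA), a threshold-free continuous measure of
    physical activity suited to rehabilitation inpatients, including
    wheelchair users for whom step counts show a floor effect.  Provides a
    transparent peak-over-baseline step detector, 24-hour ensemble
    averaging of multi-day minute-level series with a measurement-error
    exclusion rule, a synthetic 48-hour trunk-accelerometry cohort
    generator stratified by Functional Independence Measure (FIM)
    mobility subgroups, and a nonparametric validation battery (Spearman
    rank correlation, Fisher-Pearson skewness g1 and Fisher kurtosis g2,
    Shapiro-Wilk normality, Kruskal-Wallis with Bonferroni-adjusted
    pairwise comparisons, and floor-effect quantification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
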