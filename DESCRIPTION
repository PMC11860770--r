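Package: sompmf
Title: Self-Organizing Map Profiling and Positive Matrix Factorization for
    Multisite Air Quality Panels
Version: 0.1.0
Authors@R:
    person("sompmf", "developers", email = "sompmf@example.org",
           role = c("aut", "cre"))
Description: Tools to disentangle multiannual, multisite hourly pollutant
    panels (benzene, toluene, PM10, NO, NO2) in a single elaboration.
    A batch self-organizing map (SOM) compresses the panel into a codebook
    of recurrent air-quality profiles; Ward hierarchical clustering with
    Davies-Bouldin model selection classifies the codebook into "air types";
    per-sample quantization errors flag outlier events such as desert dust
    intrusions; and uncertainty-weighted positive matrix factorization (PMF)
    with bootstrap validation is run on the codebook, rather than the raw
    data, to apportion emission sources.  Includes an iterative-PCA imputer
    for sparse missingness, calendar reporting of daily cluster prevalence,
    and a seeded synthetic panel generator with known source structure for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
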