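Package: radskin
Title: Transcriptome-Based Radiation Biodosimetry from Skin Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dose-by-time skin transcriptome experiments
    aimed at radiation biodosimetry. Simulates dose- and time-structured
    microarray-like log2 expression matrices with planted differential
    transcription, preprocesses them (within-sample lowess detrending,
    between-sample quantile normalization, PCA-based outlier exclusion), calls
    significantly differentially transcribed genes with an empirical-Bayes
    moderated t-statistic and Benjamini-Hochberg adjustment, summarizes
    gene-set dynamics across time points and doses (Venn partitions,
    unique/common counts, up/down-regulation trajectories, response-peak
    detection), and applies rule-based dosimetry to call lethal versus
    sublethal exposure and rank sublethal dose classes. Includes Sammon
    mapping and uncentered-Pearson hierarchical clustering for sample-level
    ordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
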