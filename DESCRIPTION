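Package: shallowseq
Title: Depth Titration Benchmarking for Shallow RNA-Seq Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how little sequencing is enough in replicated
    two-condition RNA-seq. Simulates count experiments with heavy-tailed
    expression, planted marker genes and a low-expression (transcription
    factor like) gene class; rarefies libraries to a ladder of exact read
    depths by multivariate hypergeometric subsampling; calls differential
    expression with a nonparametric noise-odds engine (M/D statistics against
    an empirical within-condition noise distribution, RPKM or upper-quartile
    normalization) and a negative-binomial exact-test engine (median-of-ratios
    size factors, method-of-moments dispersion with a parametric
    mean-dispersion fit, Benjamini-Hochberg adjustment); and summarises how
    gene discovery, effect magnitudes and marker-set recovery change with
    depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
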