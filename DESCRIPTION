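Package: ecfortho
Title: Orthogonal ECF Sigma Factor Promoter Models, Crosstalk Maps, and
    Sequestration Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computational toolkit for characterising libraries of
    extracytoplasmic function (ECF) sigma factors, their anti-sigma
    factors, and their target promoters.  Provides bipartite promoter
    models (paired -35/-10 position weight matrices joined by an
    empirically penalised variable spacer), a Gibbs sampler for two-block
    motif discovery, upstream-region mining from annotated genomes,
    host-promoter exclusion screens and UP-element redesign, sigma x
    promoter crosstalk matrices with greedy orthogonal-subset selection,
    a sigma/anti-sigma molecular-titration model of threshold-gated
    switches with Hill-fit characterisation, subgroup co-occurrence
    permutation tests, and seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
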