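Package: socialsel
Title: Selection Effectiveness in Social Versus Subsocial Spiders from
    Codon Usage and dN/dS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution analyses contrasting inbreeding
    social and outcrossing subsocial lineages on a fixed phylogeny.
    Implements Wright's effective number of codons (ENC) with codon-column
    bootstrap confidence intervals and a group permutation test;
    Goldman-Yang-style codon substitution models with branch-class dN/dS
    (single, internal/external, internal/social/subsocial, and unconstrained
    external classes) fitted by maximum likelihood with likelihood-ratio
    tests; M7/M8 beta site-model screens for positive selection;
    Nei-Gojobori synonymous distances with strict-clock node dating; and a
    codon-alignment simulator used to validate every stage against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
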