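Package: multimerevo
Title: Statistical Physics and Evolution of Protein Multimer and Fibril
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium statistical-physics model of protein aggregation
    into closed dimers and open fibrils, coupled to a strong-selection
    weak-mutation evolutionary sampler of surface sequences. Protein
    binding surfaces are 4x4 arrays of amino acids whose pairwise contact
    energies come from a statistical contact potential; a 2x2 transfer
    matrix yields the full equilibrium distribution of n-mer aggregates at
    any concentration. A Metropolis Markov chain samples sequences under
    neutral evolution or selection for dimers, for or against fibrils, or
    for oriented fibrils, and frequency analyses of the sampled surfaces
    give amino-acid interface propensity scores that can be correlated
    with structure-derived propensity scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
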