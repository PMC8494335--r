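Package: radsig
Title: Mutation Spectra, Dose Response and Signature Analysis of Ionizing-Radiation Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide mutagenesis induced by ionizing
    radiation in mutation-accumulation experiments, modelled on clonally
    amplified C. elegans lines exposed to a Cs-137 gamma source. Variants are
    classified into a fixed 119-channel scheme (96 trinucleotide-context
    single nucleotide variant channels, dinucleotide and multi-nucleotide
    variant channels, 14 indel channels and 7 structural variant channels).
    Per-class mutation rates are estimated by non-zero-intercept additive
    Poisson regression, genotypes are screened for dose dependence, and a
    hierarchical additive Poisson signature model estimates the wild-type
    radiation signature together with per-genotype log fold-changes by MCMC.
    Clustered mutations are detected with a sliding-window caller and a
    two-state hidden Markov model over inter-mutation distances. Spectra can
    be adjusted between genomes with different trinucleotide compositions and
    compared by cosine similarity. A synthetic-data generator reproduces the
    statistical structure of the experimental design so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
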