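Package: polymeiosis
Title: Simulation of Meiosis in Diploid and Tetraploid Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of meiosis for diploid and tetraploid
    organisms. Tetraploid chromosome sets form two bivalents or a
    cross-type or parallel quadrivalent, with a configurable degree of
    preferential (subgenome) pairing. Chiasma positions are drawn from a
    renewal process (exponential gaps without interference, gamma gaps
    with interference), chromatids are recombined by tail exchange, and
    the two meiotic divisions deliver gametes in which double reduction
    arises naturally from quadrivalent segregation. Populations are
    generated by gene-dropping founder-allele mosaics through a pedigree
    and realising marker genotypes and allele dosages on a genetic map.
    A test mode accumulates gamete statistics over replicated meioses and
    compares recombination fractions, double-reduction frequencies and
    pairing-configuration frequencies with closed-form expectations
    (Haldane and Kosambi map functions, quadrivalent fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
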