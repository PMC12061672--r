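Package: dmcc
Title: In Silico DraI COI-COII (DmCC) Haplotyping of Honey Bee Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial haplotyping of honey bees (Apis mellifera)
    from the COI-COII intergenic region. Annotates amplicons into P0/P/Q
    structural elements, performs the in-silico DraI restriction test (DmCC)
    with fragment profiling, calls evolutionary lineages (A/M/C), matches
    haplotypes against a reference catalog and names novel haplotypes by the
    universal lineage-serial-length-fragments-country scheme. Includes
    exact-identity sequence grouping, haplotype and nucleotide diversity,
    Tajima's D with normal and beta p-values, minimum-spanning haplotype
    networks with equally parsimonious alternative links, and a synthetic
    amplicon simulator with planted SNPs, deletions and haplotype frequency
    spectra so the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    igraph
Config/testthat/edition: 3
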