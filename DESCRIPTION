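Package: founderhap
Title: Founder-Haplotype Analysis from Family Genotypes and Phased Reference Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for tracing the haplotype background of a rare disease
    mutation in a nuclear family and placing it in a population context.
    Provides exhaustive Mendelian-constrained phasing of family genotypes
    over a small ordered marker panel (no recombination assumed), extraction
    of haplotypes from phased reference panels such as the 1000 Genomes
    Project, haplotype-spectrum inference with frequency-rank naming,
    compatibility classification of a mutation-bearing background against
    named founder haplotypes, pairwise linkage disequilibrium (D, D', r2)
    with contiguous high-LD block detection, and a seed-deterministic
    synthetic-data generator for end-to-end validation. Ships the 16-marker
    SOD1 region panel (chromosome 21, SOD1 to SCAF4) used in founder studies
    of the amyotrophic lateral sclerosis mutation p.A5V (A4V, rs121912442).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
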