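Package: methdigest
Title: Methylation-Aware Restriction Digestion and Methyltransferase
    Specificity Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting restriction-protection assays of DNA
    (cytosine-5) methyltransferases. Provides duplex DNA sequences with
    circular or linear topology, IUPAC motif scanning on both strands,
    methyltransferase specificity models (core dinucleotide plus
    flanking-nucleotide preference weights), methylation-sensitive
    restriction enzymes with explicit blocking rules, deterministic and
    population-level in silico digestion, inference of methylation
    specificity from observed band patterns, design checks for
    restriction-based selection schemes, an error-prone PCR and
    uncut-survival selection simulator, and Michaelis-Menten analysis of
    methyl transfer kinetics. Synthetic plasmid and oligonucleotide
    generators provide reproducible test substrates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
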