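Package: cernaforge
Title: Competing Endogenous RNA Network Inference from Transcriptome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from bulk transcriptome profiles. Provides a long noncoding RNA
    identification cascade (length, exon count, biotype and coding-potential
    filters with ORF and hexamer scorers), FPKM normalisation and
    threshold-based differential expression, cis-neighbour gene-pair
    discovery with orientation classification and expression-correlation
    nulls, miRNA response element prediction by seed matching with a
    complementarity/energy score, negative-pair network construction and
    MRE-sharing triad assembly, and hypergeometric over-representation
    analysis with Benjamini-Hochberg correction. A seeded synthetic-data
    generator plants ground-truth ceRNA triads so the whole chain is testable
    end to end, and run_pipeline() orchestrates all stages from one YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
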