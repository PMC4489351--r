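Package: isoloss
Title: Gain and Loss of Alternative First-Exon Isoforms Across a Species Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the repeated loss of an alternative first-exon
    isoform across a mammalian phylogeny. Detects open-reading-frame
    disrupting lesions (start-codon mutations, frameshift indels, premature
    stops, splice-donor loss, promoter rearrangement) in aligned orthologous
    first-exon regions, converts lesion reports into functional/lost/unknown
    calls, maps losses onto a rooted species tree under Dollo parsimony with
    lesion-aware splitting of events into independent losses, classifies
    isoform balance from exon-level RNA-seq read counts with a
    length-proportional chi-squared test and Bonferroni correction, and
    predicts translation products of reporter constructs under the ribosomal
    scanning model (Kozak context, leaky scanning, near-cognate initiation).
    A synthetic-data generator produces trees, lesioned alignments, reporter
    construct archetypes and read counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
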