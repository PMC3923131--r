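Package: reinitScan
Title: Detection and Ranking of Overlapping ORF Pairs Accessed by Coupled
    Translation Termination-Reinitiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scans mRNA transcripts for pairs of overlapping open reading
    frames in which a ribosome terminating ORF-1 could reinitiate a short
    distance upstream at an ORF-2 start codon. Candidate pairs (both ORFs at
    least 150 nt, overlapping by 4 to 120 nt, with at least one ORF-2 AUG
    upstream of the ORF-1 stop) are ranked by a four-factor joint probability
    score over window start-codon counts, trailing A/C context, ORF-2 length
    and overlap length, and can be filtered with BLAST-based homology
    rejection rules. Also characterizes overlap motifs (AUG clusters,
    carboxyl-terminal aspartate runs) and designs the verified mutant
    constructs used to probe the coupling mechanism (STOP displacement,
    synonymous de-AUG, A/G transition sets, constrained scrambles, residue
    swaps and AUG knockouts), with a planted-candidate simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
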