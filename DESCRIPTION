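Package: cdbgmap
Title: Read Mapping on Compacted de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("cdbgmap", "authors", email = "cdbgmap@example.org", role = c("aut", "cre"))
Description: Builds a compacted de Bruijn graph (CDBG) from short sequencing
    reads by counting k-mers, filtering them by abundance and merging maximal
    non-branching paths into unitigs, then maps reads onto the graph. Reads
    fully contained in a unitig are placed by direct k-mer seeding; reads
    spanning unitig boundaries are mapped onto branching paths with a greedy
    seed-and-extend algorithm that anchors on unitig-boundary (k-1)-mers and
    accumulates substitutions against a Hamming mismatch budget. An exhaustive
    branch-and-bound mode provides a reference for the greedy heuristic. A
    simulation harness generates random genomes and error-bearing reads and
    evaluates recall and the distance-to-optimum of each mapping. Includes
    FASTA/FASTQ input, unitig FASTA and GFA1 output, a mapping TSV writer and
    a command-line style entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
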