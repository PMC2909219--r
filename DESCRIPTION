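Package: scafopt
Title: Genome Scaffolding from Mate-Pair Constraints by Statistical Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients de novo assembly contigs into scaffolds using
    mate-pair and paired-end constraints. Relative orientations are assigned by
    minimizing an Ising energy on the contig connectivity graph (exact layered
    dynamic programming on sparse components after articulation-vertex
    decomposition, simulated annealing elsewhere); relative positions are solved
    as the equilibrium of a weighted spring network, with iterative removal of
    contigs attached to stretched springs; wrongly fused scaffolds are detected
    through the contig density profile and segmented with a q-state Potts model.
    Includes robust dynamic-programming translation of SOLiD color-space contigs
    to base space, preprocessing filters (insert-size estimation, contig
    self-consistency, chimera splitting, coverage filtering), gap estimation, a
    synthetic assembly simulator with ground truth, and assembly-quality metrics
    (N50, chimeric/orientation/separation error rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
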