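Package: biocathodr
Title: Community Quantification for Electrode-Associated Microbial Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the composition of low-complexity microbial
    communities, such as aerobic biocathode biofilms, from paired shotgun
    metagenome and multi-region 16S rRNA gene amplicon sequencing. Implements
    consensus taxonomy assignment for paired reads from ranked tabular hits
    (e-value window plus lowest common ancestor), coverage-based relative
    abundance of metagenomic bin genomes with a reproducible split-bin merging
    heuristic, linking of per-region OTUs to full-length 16S references and
    bin genomes by semi-global alignment identity, cross-region averaging with
    per-region quality control, iterative integer 16S copy-number estimation
    reconciling amplicon and genome abundance, and correlation of taxon
    abundance with cathodic current. A ground-truthed synthetic community
    generator emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
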