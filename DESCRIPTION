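Package: igcleanr
Title: Cleaning and Indel-Artifact Screening for Immunoglobulin Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pre-processing of immunoglobulin (Ig) gene amplicon reads from
    pyrosequencing-style platforms, and screening of homopolymer-associated
    indel artifacts in clonally related Ig sequences. The cleaner
    demultiplexes reads by molecular identifier (MID) tag combinations,
    locates degenerate PCR primers by perfect IUPAC scan with an
    edit-bounded partial-match fallback, applies length and average-quality
    filters, and writes per-sample FASTA/QUAL output with a two-part run
    log. The indel identifier compares each clone member to its
    germline/consensus row in a multiple alignment, flags indels near
    homopolymer tracts that are not shared within the clone as sequencing
    artifacts, keeps uncertain singleton-clone indels separately, and
    screens low-quality point mutations while sparing AID hotspot motifs.
    A deletion-injection simulator and a synthetic read generator provide
    ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
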