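Package: softdisorder
Title: Soft-Disorder Annotation from Ensembles of Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates per-residue soft disorder in protein chains from
    crystallographic structure files: residues that are unresolved (missing
    electron density) or highly flexible (normalized Calpha B-factor above a
    threshold) in at least one member of a cluster of alternative structures
    of the same sequence. Builds identity/coverage clusters of chains, maps
    member positions onto cluster representatives, aggregates per-site
    soft-disorder and interface frequencies, detects protein-protein
    interfaces by Calpha contact distance and protein-nucleic interfaces by
    loss of solvent-accessible surface area, exports leakage-controlled
    machine-learning datasets, and provides a per-residue classifier
    evaluation metric suite (ROC AUC, PR AUC as average precision, MCC, F1,
    max-F1 threshold scan, Spearman profile correlation). A synthetic fixture
    generator emulates multi-chain crystals with planted missing segments,
    B-factor profiles and inter-chain contacts so the full pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
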