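Package: ligandgen
Title: Target-Conditioned SMILES Molecule Generation with Protein
    Sequence Encodings and Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates candidate ligands for a protein target as SMILES
    strings. A protein amino-acid sequence is encoded as a fixed 512-length
    numeric vector by fusing pseudo amino acid composition, Moreau-Broto
    autocorrelation descriptors and the conjoint triad descriptor; a small
    decoder-only transformer language model over SMILES tokens, conditioned
    on that vector and on a Bemis-Murcko scaffold, is pretrained on a
    generic lead-like corpus and fine-tuned by transfer learning on known
    actives. Includes the full evaluation battery (validity, novelty and
    uniqueness ratios, drug-likeness properties, Morgan/Tanimoto similarity
    to actives, Wasserstein-1 property shifts), a synthetic fixture corpus
    generator, and a file-level adapter for AutoDock-Vina-family docking
    runs. Standard cheminformatics operations are delegated to RDKit
    through a bundled Python helper.
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
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (configurable via option 'ligandgen.python').
Config/testthat/edition: 3
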