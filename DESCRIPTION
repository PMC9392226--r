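Package: ffp
Title: Alignment-Free Protein Phylogenetics from Amino-Acid Property Signals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free phylogenetic analysis of protein sequences.
    Amino-acid sequences are encoded as numeric curves using a
    physicochemical property scale (by default the alpha-carboxyl
    dissociation constant, pKa(COOH)), transformed with an iterated
    magnitude fast Fourier transform, and summarized by sliding-window
    Higuchi fractal dimension feature vectors. Pairwise cosine distances
    between feature vectors yield a distance matrix from which a
    single-linkage tree is built and exported as Newick. Includes
    correlation-coefficient agreement reports against reference distance
    matrices, a seeded synthetic protein-family generator for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
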