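Package: fragsite
Title: Fragment-Transformation Prediction of NAD- and FAD-Binding Residues
Version: 0.1.0
Authors@R: person("fragsite", "developers", role = c("aut", "cre"),
    email = "fragsite@example.org")
Description: Template-based prediction of nicotinamide adenine dinucleotide
    (NAD) and flavin adenine dinucleotide (FAD) binding residues in protein
    structures. Binding templates are built from ligand-bound structures by
    decomposing the cofactor into nicotinamide/flavin, adenosine and
    phosphate moieties; query structures are scanned with a fragment
    transformation alignment (rigid-body superposition of backbone
    N-CA-C triplets followed by single-linkage clustering of mutually
    consistent transforms) and each residue receives a composite
    sequence/structure binding score combining alignment size, C-alpha RMSD,
    BLOSUM62 and secondary-structure substitution terms. Includes
    leave-one-out evaluation with ROC/MCC operating points, balanced
    subsampling, and a deterministic synthetic-structure generator for
    download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
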