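Package: acylminer
Title: Iterative Profile-HMM Mining and Annotation of Acyltransferase Protein Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining protein superfamilies from proteome databases by
    iterative profile hidden Markov model (HMM) search to convergence, with
    duplicate removal, hallmark-motif scrutiny, entropy/gap/block alignment
    trimming, competitive clade classification by profile-HMM bit score,
    Kyte-Doolittle hydropathy and hydrophobic-region segmentation,
    sequence-logo information content, and desk-scale neighbor-joining
    phylogenies with bootstrap support. Includes a protein-superfamily
    simulator (WAG substitutions, indels, truncated gene models, redundant
    duplicates, background decoys) so every stage is testable against known
    clade labels. Motivated by the annotation of triglyceride-synthesis
    acyltransferases (DGAT1/DGAT2/DGAT3, PDAT/LCAT) in algal proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
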