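Package: hlarmsd
Title: Structure-Based Scoring of HLA Mismatches for Transplant Donor Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional structure discrepancy between
    HLA alleles by weighted root-mean-square deviation (RMSD) restricted to
    the functional recognition region of the class I and class II molecules
    (the "revised RMSD"), and applies it to allogeneic haematopoietic stem
    cell transplantation: classification of acceptable mismatched alleles,
    resolution of graft-versus-host-direction mismatches between recipient
    and donor genotypes, prediction of acute graft-versus-host disease
    (aGVHD) severity from single and total revised RMSD, and ranking of
    candidate donors by minimum total revised RMSD. Includes an HLA allele
    nomenclature parser, a pairwise RMSD matrix store with TSV persistence,
    packaged clinical mismatch records for validation, and a synthetic
    structure generator producing coordinate pairs with prescribed RMSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
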