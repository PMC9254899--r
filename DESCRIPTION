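Package: serialmerge
Title: Multi-Stage Clustering and Merging of Serial Crystallography Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assembling complete diffraction data sets from
    thousands of low-completeness wedges collected in serial
    crystallography.  Datasets are first clustered on unit-cell
    parameters, either with the classic PCA/Euclidean cell distance or
    with a Niggli-cone (G6) lattice distance, and merged until a target
    completeness is reached; the merged clusters are then re-clustered
    on a Pearson correlation-derived distance between reflection
    intensities (with a penalty for unmatched reflections) to separate
    near-isomorphous crystal forms that cell parameters alone cannot
    distinguish.  Includes SHELX HKL4 reflection I/O, Laue-group
    symmetry handling, Ward hierarchical clustering with LCV/aLCV and
    completeness annotation, a completeness-gated non-overlapping
    cluster selection, a synthetic serial-experiment generator with
    ground-truth labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
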