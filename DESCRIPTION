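Package: asdgraph
Title: Population-Graph Classification of Autism from Multimodal MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies subjects as autism spectrum disorder (ASD) or typical
    control (TC) by fusing structural and resting-state functional MRI. Voxelwise
    rs-fMRI summary derivatives (regional homogeneity, (fractional) amplitude of
    low-frequency fluctuations, degree and eigenvector centrality, local
    functional connectivity density, voxel-mirrored homotopic connectivity and
    dual regression) are stacked on a channel axis and encoded by a multichannel
    3D convolutional network into per-subject node features. Per-region radiomic
    features (first-order and grey-level co-occurrence statistics on all level-1
    wavelet sub-bands of the structural volume) are Fisher-ranked, compressed
    with a stacked autoencoder, and compared with an improved sqrt-cosine
    (Hellinger-style) similarity to define the edges of a population graph, on
    which a graph convolutional network performs semi-supervised node
    classification. Ships a synthetic-data module that generates every input the
    pipeline needs, so the whole method is testable without external imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    optparse,
    rlang
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
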