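Package: massembed
Title: Multiview Contrastive Embedding of Molecules and Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a joint embedding space over four views of a metabolite
    datum - its molecular graph, Morgan fingerprint, individual MS/MS
    spectrum, and consensus spectrum - with an all-pairs contrastive
    objective, and ranks candidate structures for query spectra by cosine
    similarity in that space. Includes subformula peak annotation at ppm
    tolerance, consensus-spectrum construction, a synthetic in-silico
    fragmentation data generator, rank aggregation, retrieval metrics
    (rank at k, exact maximum common edge subgraph distance), and MGF /
    candidate-JSON / CSV input-output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
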