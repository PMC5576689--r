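Package: lmcenm
Title: Elastic Network Models of Learned Maintained Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained anisotropic network models (ANM) of protein
    motion with contact-topology surgery. Labels contact transitions
    (maintained, breaking, forming) between two conformations from the
    relative strain of each contact, builds and stabilizes elastic networks
    under several spring schemes (uniform cutoff, HCA, edENM, secondary-
    structure scaled), predicts breaking contacts from a single
    conformation with a feature-based support vector machine, removes the
    predicted breaking contacts to form the network of learned maintained
    contacts (lmcENM), and evaluates predicted motion against observed
    functional transitions with mode overlap, cumulative overlap,
    collectivity, variance fractions, fluctuation correlations and
    subspace-similarity measures (RMSIP, RWSIP). Includes synthetic
    structure generators (compact globules, hinge and loop conformation
    pairs with known breaking contacts) so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
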