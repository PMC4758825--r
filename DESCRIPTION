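Package: commrobust
Title: Robustness of Social Network Community Assignment via Bootstrap
    Assortativity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies confidence in the assignment of individuals to
    social-network communities with the community-assortativity coefficient
    r_com. Builds weighted association networks from group-by-individual
    ("gambit of the group") observation streams using the simple ratio index,
    detects communities by fast-greedy modularity optimization, bootstraps the
    observation stream to accumulate community co-membership proportions, and
    measures their assortativity with respect to the empirical partition.
    Includes a data-stream permutation test for modularity, a generative
    simulator of fission-fusion populations with known community structure,
    and sample-size subsampling analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
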