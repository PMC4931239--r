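Package: socinherit
Title: Social Inheritance Models of Animal Social Network Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, analyses and fits a birth-death model of animal
    social network formation in which newborns inherit social bonds from
    their mothers (connecting to each maternal contact with probability
    p_n) and bond with strangers at random (probability p_r). Provides
    stationarity approximations for mean degree and mean local
    clustering, the mean-field stationary degree distribution, two-sex
    and varying-population-size variants, trait inheritance with
    heritability and assortativity experiments, alternative
    preference-based bonding models, and two parameter-estimation
    procedures (partial least squares regression on simulated ensembles,
    and analytical inversion of the stationarity approximations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
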