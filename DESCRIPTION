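Package: nanocapture
Title: Quantifying Nano- and Microplastic Capture on Nanocellulose Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative workflow for measuring nano- and microplastic
    particle capture at bio-based interfaces. Implements random sequential
    adsorption (RSA) kinetics (blocking functions, jamming-limit packing,
    forward ODE integration and trust-region least-squares fitting of
    QCM-D adsorption traces), Sauerbrey mass conversion with coupled-water
    estimation against image-analysis dry mass, SEM-style particle counting
    with single/cluster decomposition, Monte Carlo hard-disk deposition for
    the jamming limit, fluorescence-depletion particle quantification, and
    a synthetic-data generator that emulates all three instruments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
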