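Package: psse
Title: Statistical Features of Predicted Protein Secondary Structures for
    Structural Class Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts content-based and position-based statistical features
    from 3-state (helix/strand/coil) predicted protein secondary-structure
    sequences and predicts SCOP-style structural classes (all-alpha,
    all-beta, alpha/beta, alpha+beta) with a Gaussian-kernel support vector
    machine. Content-based features include element content, composition
    moment vectors, longest and average segment lengths with normalized
    forms, 3PATTERN window fractions, helix-strand alternation frequency,
    and the transition probability matrix of the coil-free segment
    sequence. Position-based features summarise the distribution of
    interval distances between successive occurrences of each element via
    truncated (semi-) moments and the reciprocal coefficient of variation.
    Includes SS-FASTA and PSIPRED ss2 input, a class-typed synthetic
    sequence generator, grid-searched model fitting, jackknife
    (leave-one-out) evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
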