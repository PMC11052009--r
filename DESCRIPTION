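Package: denitrait
Title: Digital Categorization of Microbial Genomes by Denitrification Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Categorizes archaeal and bacterial genomes by denitrification
    potential from the presence or absence of the twelve genes encoding
    the canonical denitrification reductases (narG, narH, narI, napA,
    napB, nirK, nirS, norB, norC, norV, norW, nosZ). Gene presence is
    encoded as a 12-digit binary Denitrifying Enzymes Pattern, reduced to
    a 4-digit Denitrification Pattern via enzyme-complex trait rules
    (narGHI or napAB; nirK or nirS; norBC or norVW; nosZ), and assigned
    one of sixteen named denitrification traits. Includes readers for
    IMG/M-style per-KO genome lists and metadata tables, assembly of a
    taxonomy- and ecosystem-annotated dataset with summaries, filters,
    replicate-strain detection and auxiliary-pathway annotation, a
    synthetic-cohort generator with planted trait distributions for
    end-to-end validation, and scholarly-search and portal link builders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
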