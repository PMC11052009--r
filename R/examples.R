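# Curated archaeal example records: the published denitrification-potential
# categorization of 866 archaeal genomes summarized to 9 trait categories
# with one exemplar genome each, plus the 21 archaeal genomes that encode
# both nitrite reductases (nirK and nirS). Used as ground-truth fixtures
# throughout the test suite.

#' Curated archaeal example records
#'
#' Reference records from the published archaeal categorization:
#' \describe{
#'   \item{trait_examples}{The nine denitrification-trait categories
#'     observed among 866 archaeal genomes, each with its 4-digit code,
#'     trait name, genome count, an exemplar genome and the exemplar's
#'     12-digit enzyme pattern.}
#'   \item{nirk_nirs_genomes}{The 21 archaeal genomes (7 Halobacteriota
#'     genera, 18 distinct strains) encoding both the copper-type (nirK)
#'     and cytochrome cd1-type (nirS) nitrite reductases, with genome ID,
#'     enzyme pattern and ecosystem category.}
#'   \item{worked_patterns}{Named enzyme-pattern strings for worked
#'     examples discussed in the text (oyster-associated and
#'     Arcobacteraceae genomes).}
#' }
#'
#' @return A list with elements `trait_examples` (tibble, 9 rows),
#'   `nirk_nirs_genomes` (tibble, 21 rows) and `worked_patterns` (named
#'   character vector).
#' @examples
#' ex <- archaeal_examples()
#' apply_trait_rules(ex$trait_examples$enzyme_pattern)
#' @export
archaeal_examples <- function() {
  trait_examples <- tibble::tribble(
    ~code, ~trait, ~n_genomes, ~example_genome, ~enzyme_pattern,
    "0000", "Incomplete Enzymes for Denitrification Steps", 278L,
    "Aeropyrum pernix K1", "110000000000",
    "0001", "Nitrous Oxide Reduction Only", 58L,
    "Haloarcula japonica DSM 6131", "110000010001",
    "0010", "Nitric Oxide Reduction Only", 1L,
    "Candidatus Hydrothermarchaeota archaeon JdFR-18", "110100011100",
    "0100", "Nitrite Reduction Only", 366L,
    "Haloferax volcanii DS2", "110001010000",
    "0101", "Nitrite and Nitrous Oxide Reduction Only", 119L,
    "Haloferax mediterranei R-4", "110001010001",
    "1000", "Nitrate Reduction Only", 39L,
    "Pyrobaculum aerophilum IM2", "111000010000",
    "1001", "Nitrate and Nitrous Oxide Reduction Only", 3L,
    "Pyrobaculum calidifontis JCM 11548", "111000010001",
    "1011", "Nitrate, Nitric Oxide and Nitrous Oxide Reduction Only", 1L,
    "Ferroglobus placidus AEDII12DO, DSM 10642", "111000011101",
    "1100", "Nitrate and Nitrite Reduction Only", 1L,
    "Candidatus Heimdallarchaeota archaeon LC_3", "111001000000"
  )

  nirk_nirs_genomes <- tibble::tribble(
    ~genome_name, ~genome_id, ~enzyme_pattern, ~ecosystem_category,
    "Halobiforma haloterrestris DSM 13078", "2693429869", "110001110001", "Terrestrial",
    "Halobiforma lacisalsi AJ5, JCM 12983", "2529293100", "110001110001", "Aquatic",
    "Halobiforma lacisalsi AJ5, JCM 12983", "2806310686", "110001110001", "Aquatic",
    "Halobiforma nitratireducens JCM 10879", "2554235466", "110001100001", "Aquatic",
    "Halorubrum amylolyticum ZC67", "2881047951", "110001110001", "Terrestrial",
    "Halorubrum salipaludis WN019", "2995789858", "000001110001", "Terrestrial",
    "Halosolutus halophilus LT55", "8055007790", "000001110001", "Terrestrial",
    "Haloterrigena longa ABH32", "8065811630", "000001110001", "Aquatic",
    "Haloterrigena sp. LL2A", "2639762614", "000001110001", "Aquatic",
    "Natrinema altunense AJ2", "2585427993", "110001110001", "Aquatic",
    "Natrinema altunense JCM 12890", "2554235488", "110001110001", "Aquatic",
    "Natrinema amylolyticum LT61", "8056733939", "110001110001", "Terrestrial",
    "Natrinema pallidum BOL6-1", "8058325716", "110001110000", "Terrestrial",
    "Natrinema pellirubrum 157", "2509601048", "110001110000", "Fish",
    "Natrinema pellirubrum 157", "2537562080", "110001110000", "Fish",
    "Natrinema sp. J7-2", "2517093029", "000001110000", "Terrestrial",
    "Natrinema thermotolerans A29", "2582580504", "110001110000", "Food production",
    "Natrinema thermotolerans A29", "2914868299", "110001110000", "Food production",
    "Natrinema thermotolerans DSM 11552", "2534681901", "110001110000", "Aquatic",
    "Natronomonas sp. LN261", "3001203943", "000001100001", "Terrestrial",
    "Salinilacihabitans rarus AD-4", "8054413294", "110001110001", "Aquatic"
  )

  worked_patterns <- c(
    "Marinobacter denitrificans JB02H27" = "111111111001",
    "Arcobacter sp. LA11" = "000110111001",
    "Pseudoalteromonas denitrificans DSM 6059" = "000110111001",
    "Psychrobacter maritimus Pi2-25" = "111001010010",
    "Aliarcobacter cryaerophilus AZT-1" = "000010111000",
    "Nisaea denitrificans DSM 18348" = "000111011001",
    "Shewanella denitrificans OS217" = "000111011001"
  )

  list(
    trait_examples = trait_examples,
    nirk_nirs_genomes = nirk_nirs_genomes,
    worked_patterns = worked_patterns
  )
}

#' Build a dataset from the curated nirK+nirS archaeal genomes
#'
#' Expands the 21 curated archaeal records into an annotated dataset
#' through the normal build path: enzyme digits decoded from each printed
#' pattern, trait rules applied, ecosystem category attached. Lineage and
#' sequencing fields not printed in the source records are `NA`.
#'
#' @return A `denit_dataset` with 21 rows.
#' @export
archaeal_examples_dataset <- function() {
  rows <- archaeal_examples()$nirk_nirs_genomes
  catalog <- denitrification_catalog()
  digits <- pattern_matrix(parse_pattern(rows$enzyme_pattern), 12)
  colnames(digits) <- enzyme_columns(catalog)
  annotated <- dplyr::bind_cols(
    tibble::tibble(
      genome_id = rows$genome_id,
      genome_name = rows$genome_name,
      domain = "Archaea",
      status = NA_character_,
      ecosystem_category = rows$ecosystem_category
    ),
    tibble::as_tibble(digits)
  )
  build_dataset(annotated)
}
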