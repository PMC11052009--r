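make_annotated <- function(patterns, names = NULL, ids = NULL, ...) {
  cat <- denitrification_catalog()
  n <- length(patterns)
  digits <- do.call(rbind, lapply(strsplit(patterns, ""), as.integer))
  colnames(digits) <- enzyme_columns(cat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(names)) names <- paste("Genus sp.", seq_len(n))
  dplyr::bind_cols(
    tibble::tibble(
      genome_id = ids,
      genome_name = names,
      domain = "Bacteria", status = "Finished", ...
    ),
    tibble::as_tibble(digits)
  )
}

test_that("build_dataset derives patterns, codes, traits and genus", {
  ds <- build_dataset(make_annotated("000000000001", names = "Thiobacillus denitrificans X"))
  expect_s3_class(ds, "denit_dataset")
  expect_equal(ds$denitrifying_enzymes_pattern, "000000000001")
  expect_equal(ds$denitrification_pattern, "0001")
  expect_equal(ds$denitrification_traits, "Nitrous Oxide Reduction Only")
  expect_equal(ds$genus, "Thiobacillus")
  expect_equal(ncol(ds), 36)
})

test_that("all-zero genomes are excluded at build time with a logged count", {
  ann <- make_annotated(c("000000000001", "000000000000", "000000000000"))
  expect_message(ds <- build_dataset(ann), "2 genome")
  expect_equal(nrow(ds), 1)
  expect_equal(attr(ds, "excluded"), 2L)
  expect_equal(glance(ds)$n_excluded, 2L)
})

test_that("stored potential columns are self-consistent with the rules", {
  ds <- archaeal_examples_dataset()
  expect_equal(
    ds$denitrification_pattern,
    apply_trait_rules(ds$denitrifying_enzymes_pattern)
  )
  expect_equal(ds$denitrification_traits, trait_name(ds$denitrification_pattern))
  cat <- denitrification_catalog()
  recon <- apply(as.matrix(ds[, enzyme_columns(cat)]), 1, paste, collapse = "")
  expect_equal(unname(recon), ds$denitrifying_enzymes_pattern)
  # rebuilt records carry the printed patterns
  expect_equal(
    ds$denitrifying_enzymes_pattern,
    archaeal_examples()$nirk_nirs_genomes$enzyme_pattern
  )
})

test_that("replicate strains are names with two or more genome records", {
  reps <- detect_replicate_strains(archaeal_examples_dataset())
  expect_equal(
    reps,
    tibble::tibble(
      genome_name = c(
        "Halobiforma lacisalsi AJ5, JCM 12983",
        "Natrinema pellirubrum 157",
        "Natrinema thermotolerans A29"
      ),
      n_genomes = c(2L, 2L, 2L)
    )
  )

  unique_ds <- build_dataset(make_annotated(rep("000000000001", 3)))
  expect_equal(nrow(detect_replicate_strains(unique_ds)), 0)

  five <- build_dataset(make_annotated(
    rep("000000000001", 5),
    names = rep("Brucella melitensis bv. 1 16 M", 5)
  ))
  expect_equal(detect_replicate_strains(five)$n_genomes, 5L)
})

test_that("grouped summaries tally genomes with Null for missing annotation", {
  ds <- archaeal_examples_dataset()
  by_eco <- summarize_dataset(ds, "ecosystem_category")
  expect_equal(
    by_eco$n_genomes[match(
      c("Aquatic", "Terrestrial", "Fish", "Food production"),
      by_eco$ecosystem_category
    )],
    c(9L, 8L, 2L, 2L)
  )
  expect_equal(sum(by_eco$n_genomes), nrow(ds))

  # the nine archaeal trait exemplars have nine distinct patterns
  ex <- archaeal_examples()$trait_examples
  ds5 <- build_dataset(make_annotated(ex$enzyme_pattern, names = ex$example_genome))
  by_code <- summarize_dataset(ds5, "denitrification_pattern")
  expect_equal(nrow(by_code), 9)
  expect_equal(by_code$n_genomes, rep(1L, 9))

  # missing annotation appears as "Null"
  by_type <- summarize_dataset(ds, "ecosystem_type")
  expect_equal(by_type$ecosystem_type, "Null")

  empty <- ds[0, ]
  expect_equal(nrow(summarize_dataset(empty, "genus")), 0)
  expect_error(summarize_dataset(ds, "no_such_column"), "no_such_column")
})

test_that("count_distinct reports distinct non-missing values", {
  ds <- archaeal_examples_dataset()
  expect_equal(count_distinct(ds, "genus"), 7)
  expect_equal(count_distinct(ds, "genome_name"), 18)
  expect_equal(count_distinct(ds[1, ], "denitrifying_enzymes_pattern"), 1)
  expect_equal(count_distinct(ds, "ecosystem_type"), 0)  # all NA
  expect_error(count_distinct(ds, "nope"), "nope")
})

test_that("filter_dataset takes conjunctions of column predicates", {
  ds <- archaeal_examples_dataset()
  expect_equal(nrow(filter_dataset(ds, genes_present = c("nirK", "nirS"))), 21)
  expect_equal(nrow(filter_dataset(ds)), 21)

  aq <- filter_dataset(ds, ecosystem_category = "Aquatic")
  expect_equal(nrow(aq), 9)
  # stable row order: same relative order as the input
  expect_equal(
    aq$genome_id,
    ds$genome_id[ds$ecosystem_category == "Aquatic"]
  )

  named <- build_dataset(make_annotated(
    c("000110111001", "000110111001", "111001010010"),
    names = c("Pseudoalteromonas denitrificans DSM 6059",
              "Arcobacter sp. LA11",
              "Psychrobacter maritimus Pi2-25")
  ))
  hit <- filter_dataset(named, name_contains = "DENITRIFICANS",
                        denitrification_pattern = "1111")
  expect_equal(hit$genome_name, "Pseudoalteromonas denitrificans DSM 6059")
  expect_error(filter_dataset(ds, not_a_column = "x"), "not_a_column")
})

test_that("auxiliary KO annotation flags carriers and counts per KO", {
  ds <- build_dataset(make_annotated(rep("000000000001", 6)))
  out <- annotate_auxiliary_kos(ds, list(
    glnA = c("1", "2", "3", "4", "5"),
    nifH = character(0)
  ))
  expect_equal(sum(out$aux_glnA), 5)
  expect_false(any(out$aux_nifH))
  s <- aux_ko_summary(out)
  expect_equal(s$genome_count, c(5L, 0L))
  expect_true(is.na(s$example_genome[2]))
  expect_message(
    annotate_auxiliary_kos(ds, list(glnA = c("1", "not-a-genome"))),
    "absent"
  )
})

test_that("exports re-import losslessly in CSV and TSV, keeping leading zeros", {
  ds <- archaeal_examples_dataset()
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_dataset(ds, csv, "csv")
  export_dataset(ds, tsv, "tsv")
  back_csv <- import_dataset(csv)
  back_tsv <- import_dataset(tsv)
  expect_equal(as.data.frame(back_csv), as.data.frame(ds))
  expect_equal(as.data.frame(back_tsv), as.data.frame(ds))
  expect_true(all(nchar(back_csv$denitrification_pattern) == 4))
  expect_true("0100" %in% back_csv$denitrification_pattern)
  # header uses the display schema
  header <- readLines(csv, n = 1)
  expect_match(header, "Genome ID")
  expect_match(header, "Denitrifying Enzymes Pattern")
})

test_that("trait categories partition the dataset and nosZ digits match codes", {
  spec <- cohort_spec(seed = 11, n_genomes = 300)
  truth <- generate_cohort(spec)$truth
  ds <- build_dataset(make_annotated(
    truth$enzyme_pattern, names = truth$genome_name, ids = truth$genome_id
  ))
  by_trait <- summarize_dataset(ds, "denitrification_traits")
  expect_equal(sum(by_trait$n_genomes), nrow(ds))

  nosz_codes <- c("0001", "0011", "0101", "0111", "1001", "1011", "1101", "1111")
  with_nosz <- ds$genome_id[substr(ds$denitrifying_enzymes_pattern, 12, 12) == "1"]
  by_code <- ds$genome_id[ds$denitrification_pattern %in% nosz_codes]
  expect_setequal(with_nosz, by_code)
})
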