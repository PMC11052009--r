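# Synthetic cohort generator: emits IMG/M-dialect per-KO genome lists and
# a metadata table with a planted trait distribution, taxonomy, ecosystem
# labels, replicate strains and auxiliary-KO carriers, plus the truth
# table the pipeline must recover.

default_taxonomy_pool <- function() {
  tibble::tribble(
    ~gtdb_domain, ~gtdb_phylum, ~gtdb_order, ~gtdb_family, ~genus,
    "Bacteria", "Pseudomonadota", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas",
    "Bacteria", "Pseudomonadota", "Rhodobacterales", "Paracoccaceae", "Paracoccus",
    "Bacteria", "Pseudomonadota", "Enterobacterales", "Shewanellaceae", "Shewanella",
    "Bacteria", "Pseudomonadota", "Hyphomicrobiales", "Xanthobacteraceae", "Bradyrhizobium",
    "Bacteria", "Campylobacterota", "Campylobacterales", "Arcobacteraceae", "Arcobacter",
    "Bacteria", "Pseudomonadota", "Pseudomonadales", "Moraxellaceae", "Psychrobacter",
    "Archaea", "Halobacteriota", "Halobacteriales", "Haloferacaceae", "Haloferax",
    "Archaea", "Halobacteriota", "Halobacteriales", "Natrialbaceae", "Natrinema"
  )
}

default_ecosystem_pool <- function() {
  tibble::tribble(
    ~ecosystem, ~ecosystem_category, ~ecosystem_type, ~ecosystem_subtype, ~specific_ecosystem,
    "Environmental", "Aquatic", "Marine", "Coastal", "Seawater",
    "Environmental", "Terrestrial", "Soil", "Loam", "Agricultural land",
    "Host-associated", "Mollusca", "Oyster", "Gills", "Unclassified",
    "Engineered", "Wastewater", "Activated Sludge", "Nutrient removal", "Unclassified"
  )
}

# Planted trait distribution: the published archaeal distribution over 866
# genomes (9 of the 16 codes). See the methods vignette.
default_trait_weights <- function() {
  c(
    "0000" = 278, "0001" = 58, "0010" = 1, "0100" = 366, "0101" = 119,
    "1000" = 39, "1001" = 3, "1011" = 1, "1100" = 1
  ) / 866
}

#' Specify a synthetic genome cohort
#'
#' Defines the planted structure of a synthetic cohort: how many genomes,
#' the distribution over the 16 denitrification trait codes (each genome's
#' 12-digit enzyme pattern is then drawn uniformly from its code's
#' preimage, excluding the all-zero pattern, so every genome meets the
#' at-least-one-gene inclusion criterion), taxonomy and ecosystem pools, a
#' replicate rate (probability that a genome is an additional sequencing
#' of an earlier strain: same name, taxonomy, ecosystem and pattern, new
#' genome ID) and per-KO carrier rates for auxiliary genes.
#'
#' @param seed Mandatory integer seed; identical specs generate
#'   byte-identical outputs.
#' @param n_genomes Number of genomes.
#' @param trait_weights Named probabilities over 4-digit codes (any
#'   subset of the 16; must sum to 1). Defaults to the archaeal
#'   distribution over 9 codes.
#' @param taxonomy_pool Tibble of `gtdb_domain`, `gtdb_phylum`,
#'   `gtdb_order`, `gtdb_family`, `genus` rows sampled uniformly.
#' @param ecosystem_pool Tibble of 5-level GOLD ecosystem tuples sampled
#'   uniformly among annotated genomes.
#' @param missing_ecosystem_rate Probability a genome carries no ecosystem
#'   annotation (all five fields `NA`).
#' @param replicate_rate Probability a genome replicates an earlier
#'   strain.
#' @param aux_ko_rates Named carrier probabilities per auxiliary gene
#'   label (e.g. `c(glnA = 0.9, nifH = 0.1)`), or `NULL`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed,
                        n_genomes = 500,
                        trait_weights = default_trait_weights(),
                        taxonomy_pool = default_taxonomy_pool(),
                        ecosystem_pool = default_ecosystem_pool(),
                        missing_ecosystem_rate = 0.4,
                        replicate_rate = 0.03,
                        aux_ko_rates = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    rlang::abort("a seed is mandatory")
  }
  codes <- names(trait_weights)
  parse_pattern(codes, width = 4)
  if (any(trait_weights < 0) || abs(sum(trait_weights) - 1) > 1e-8) {
    rlang::abort("trait_weights must be nonnegative and sum to 1")
  }
  probs <- c(missing_ecosystem_rate, replicate_rate, unlist(aux_ko_rates))
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("rates must be probabilities in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_genomes = as.integer(n_genomes),
      trait_weights = trait_weights,
      taxonomy_pool = taxonomy_pool,
      ecosystem_pool = ecosystem_pool,
      missing_ecosystem_rate = missing_ecosystem_rate,
      replicate_rate = replicate_rate,
      aux_ko_rates = aux_ko_rates
    ),
    class = "cohort_spec"
  )
}

species_epithets <- function() {
  c(
    "denitrificans", "marinus", "aquaticus", "terrae", "salinus",
    "profundi", "ostrearius", "sedimenti", "litoralis", "thermophilus"
  )
}

#' Generate a synthetic cohort
#'
#' Samples a cohort under a [cohort_spec()] and (optionally) writes the
#' IMG/M-dialect input files: one tab-separated genome list per catalog
#' gene (`01_narG.tsv` ... `12_nosZ.tsv`, containing exactly the genomes
#' whose pattern has '1' at that gene's position), one per auxiliary KO,
#' a metadata table and the truth table as CSV. Running the ingest and
#' build stages on the emitted files must reproduce the truth table
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory for the generated files, or `NULL` to
#'   sample the truth table only.
#' @return A list with `truth` (tibble of every planted attribute per
#'   genome), and — when `dir` is given — `ko_files` (named paths),
#'   `aux_files`, `metadata_file`, `truth_file`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  catalog <- denitrification_catalog()
  rules <- denitrification_ruleset(catalog)
  map <- enumerate_rule_map(rules)
  preimages <- split(map$enzyme_pattern, map$step_pattern)
  preimages <- purrr::map(preimages, setdiff, y = strrep("0", 12))
  stopifnot(all(lengths(preimages) > 0))

  n <- spec$n_genomes
  withr::with_seed(spec$seed, {
    code <- sample(names(spec$trait_weights), n, replace = TRUE,
                   prob = spec$trait_weights)
    pattern <- vapply(code, function(cd) {
      pre <- preimages[[cd]]
      pre[sample.int(length(pre), 1)]
    }, character(1), USE.NAMES = FALSE)

    tax_i <- sample.int(nrow(spec$taxonomy_pool), n, replace = TRUE)
    epithet <- sample(species_epithets(), n, replace = TRUE)
    eco_i <- sample.int(nrow(spec$ecosystem_pool), n, replace = TRUE)
    eco_missing <- stats::runif(n) < spec$missing_ecosystem_rate
    replicate_of <- rep(NA_integer_, n)
    if (n > 1) {
      dup <- setdiff(which(stats::runif(n) < spec$replicate_rate), 1L)
      for (i in dup) replicate_of[i] <- sample.int(i - 1, 1)
    }
    genome_size <- round(stats::rnorm(n, 3.8e6, 8e5))
    status <- sample(c("Finished", "Permanent Draft", "Draft"), n, replace = TRUE)
    aux <- purrr::map(spec$aux_ko_rates, function(p) stats::runif(n) < p)
  })

  genus <- spec$taxonomy_pool$genus[tax_i]
  genome_name <- sprintf("%s %s S%04d", genus, epithet, seq_len(n))
  # replicates: a later genome re-sequences an earlier strain
  for (i in which(!is.na(replicate_of))) {
    j <- replicate_of[i]
    genome_name[i] <- genome_name[j]
    genus[i] <- genus[j]
    tax_i[i] <- tax_i[j]
    eco_i[i] <- eco_i[j]
    eco_missing[i] <- eco_missing[j]
    pattern[i] <- pattern[j]
    code[i] <- code[j]
  }

  eco <- spec$ecosystem_pool[eco_i, ]
  eco[eco_missing, ] <- NA_character_
  tax <- spec$taxonomy_pool[tax_i, ]

  truth <- tibble::tibble(
    genome_id = sprintf("9%09d", seq_len(n)),
    genome_name = genome_name,
    domain = tax$gtdb_domain,
    status = status,
    genus = genus,
    gtdb_domain = tax$gtdb_domain,
    gtdb_phylum = tax$gtdb_phylum,
    gtdb_order = tax$gtdb_order,
    gtdb_family = tax$gtdb_family,
    gtdb_genus = tax$genus,
    gtdb_species = paste(genus, epithet),
    genome_size = genome_size,
    gene_count = round(genome_size / 1000),
    enzyme_pattern = pattern,
    code = code,
    trait = trait_name(code),
    is_replicate = !is.na(replicate_of)
  )
  truth <- dplyr::bind_cols(truth, eco)
  for (label in names(aux)) {
    truth[[paste0("aux_", label)]] <- aux[[label]]
  }

  out <- list(truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    digits <- pattern_matrix(truth$enzyme_pattern, 12)
    labels <- sprintf("%02d_%s", catalog$position, catalog$gene_symbol)
    img_cols <- function(rows) {
      tibble::tibble(
        Domain = truth$domain[rows],
        Status = truth$status[rows],
        `Genome ID` = truth$genome_id[rows],
        `Genome Name` = truth$genome_name[rows]
      )
    }
    ko_files <- character(length(labels))
    names(ko_files) <- labels
    for (k in seq_along(labels)) {
      ko_files[k] <- file.path(dir, paste0(labels[k], ".tsv"))
      readr::write_tsv(img_cols(digits[, k] == 1L), ko_files[k], progress = FALSE)
    }
    aux_files <- character(0)
    for (label in names(aux)) {
      p <- file.path(dir, paste0("aux_", label, ".tsv"))
      readr::write_tsv(img_cols(aux[[label]]), p, progress = FALSE)
      aux_files[label] <- p
    }
    metadata_file <- file.path(dir, "metadata.tsv")
    meta <- truth |>
      dplyr::select(
        "genome_id", "genome_name", "domain", "status",
        "gene_count", "genome_size",
        dplyr::starts_with("gtdb_"),
        "ecosystem", "ecosystem_category", "ecosystem_type",
        "ecosystem_subtype", "specific_ecosystem"
      )
    nm <- dataset_name_map()
    names(meta) <- ifelse(names(meta) %in% names(nm), nm[names(meta)], names(meta))
    readr::write_tsv(meta, metadata_file, progress = FALSE)
    truth_file <- file.path(dir, "truth.csv")
    readr::write_csv(truth, truth_file, progress = FALSE)
    out <- c(out, list(
      ko_files = ko_files, aux_files = aux_files,
      metadata_file = metadata_file, truth_file = truth_file, dir = dir
    ))
  }
  out
}

#' Ingest a generated cohort directory
#'
#' Convenience wrapper running the full ingest + build path on the files
#' emitted by [generate_cohort()]: reads the twelve labelled KO lists,
#' merges them, joins the metadata and builds the dataset.
#'
#' @param dir Directory written by [generate_cohort()].
#' @param rules Trait rule set; defaults to [denitrification_ruleset()].
#' @return A `denit_dataset`.
#' @export
ingest_cohort <- function(dir, rules = denitrification_ruleset()) {
  catalog <- rules$catalog
  labels <- sprintf("%02d_%s", catalog$position, catalog$gene_symbol)
  lists <- purrr::map(labels, function(lab) {
    read_ko_genome_list(file.path(dir, paste0(lab, ".tsv")), lab, catalog)
  })
  names(lists) <- labels
  presence <- merge_ko_lists(lists, catalog)
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  build_dataset(join_metadata(presence, metadata), rules)
}
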