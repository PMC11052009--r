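dataset_columns <- function(catalog = denitrification_catalog()) {
  c(
    # genome group
    "domain", "gene_count", "genome_id", "genome_name", "genome_size",
    "genus", "gold_sequencing_project_id", "sequencing_center",
    "sequencing_status", "status",
    # ecosystem group
    "ecosystem", "ecosystem_category", "ecosystem_type",
    "ecosystem_subtype", "specific_ecosystem",
    # lineage group
    "gtdb_domain", "gtdb_phylum", "gtdb_order", "gtdb_family",
    "gtdb_genus", "gtdb_species",
    # enzyme group
    enzyme_columns(catalog),
    # potential group
    "denitrification_pattern", "denitrification_traits",
    "denitrifying_enzymes_pattern"
  )
}

enzyme_columns <- function(catalog = denitrification_catalog()) {
  sprintf("E%02d_%s", catalog$position, catalog$gene_symbol)
}

new_denit_dataset <- function(x, excluded = 0L) {
  structure(
    x,
    excluded = excluded,
    class = c("denit_dataset", class(tibble::tibble()))
  )
}

#' Build the annotated denitrification-potential dataset
#'
#' Turns an annotated presence matrix (from [merge_ko_lists()] +
#' [join_metadata()]) into the full dataset: one row per genome with the
#' genome, ecosystem, lineage, enzyme and denitrification-potential column
#' groups. The 12-digit Denitrifying Enzymes Pattern is the concatenation
#' of the enzyme digits, the 4-digit Denitrification Pattern is derived
#' through the trait rules, and the trait name through [trait_name()].
#' The genus is derived from the genome name. Genomes with no present
#' enzyme gene are excluded (the inclusion criterion is at least one of
#' the twelve genes); the excluded count is reported and attached as
#' attribute `"excluded"`.
#'
#' @param annotated Annotated presence matrix.
#' @param rules Trait rule set; defaults to [denitrification_ruleset()].
#' @return A `denit_dataset` tibble with the 36 schema columns.
#' @export
build_dataset <- function(annotated, rules = denitrification_ruleset()) {
  catalog <- rules$catalog
  ecols <- enzyme_columns(catalog)
  missing <- setdiff(ecols, names(annotated))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "annotated matrix is missing enzyme column(s): ",
      paste(missing, collapse = ", ")
    ))
  }

  digits <- as.matrix(annotated[, ecols])
  storage.mode(digits) <- "integer"
  pattern <- apply(digits, 1, paste, collapse = "")
  zero <- rowSums(digits) == 0
  if (any(zero)) {
    rlang::inform(sprintf(
      "excluded %d genome(s) with no denitrifying enzyme gene", sum(zero)
    ))
  }

  out <- tibble::as_tibble(annotated[!zero, , drop = FALSE])
  out$denitrifying_enzymes_pattern <- pattern[!zero]
  out$denitrification_pattern <-
    apply_trait_rules(out$denitrifying_enzymes_pattern, rules)
  out$denitrification_traits <- trait_name(out$denitrification_pattern)
  out$genus <- derive_genus(out$genome_name)

  for (col in setdiff(dataset_columns(catalog), names(out))) {
    out[[col]] <- if (col %in% c("gene_count", "genome_size")) {
      NA_real_
    } else {
      NA_character_
    }
  }
  dup <- unique(out$genome_id[duplicated(out$genome_id)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate Genome ID(s) in dataset: ", paste(dup, collapse = ", ")
    ))
  }
  new_denit_dataset(
    out[, dataset_columns(catalog)],
    excluded = sum(zero)
  )
}

#' One-row summary of a denitrification dataset
#'
#' @param x A `denit_dataset`.
#' @param ... Unused.
#' @return A tibble with `n_genomes`, `n_enzyme_patterns` (distinct
#'   12-digit patterns), `n_traits`, `n_genera`, `n_complete`
#'   (genomes with pattern "1111") and `n_excluded` (all-zero genomes
#'   dropped at build time).
#' @method glance denit_dataset
#' @export
glance.denit_dataset <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x),
    n_enzyme_patterns = dplyr::n_distinct(x$denitrifying_enzymes_pattern),
    n_traits = dplyr::n_distinct(x$denitrification_traits),
    n_genera = dplyr::n_distinct(x$genus),
    n_complete = sum(x$denitrification_pattern == "1111"),
    n_excluded = attr(x, "excluded") %||% 0L
  )
}

#' Detect replicate strains
#'
#' A replicate strain is a (whitespace-normalized) genome name carried by
#' two or more Genome IDs — multiple sequenced genomes of one strain.
#'
#' @param dataset A `denit_dataset` (or any tibble with `genome_name`).
#' @return A tibble `genome_name`, `n_genomes` restricted to names with
#'   count >= 2, ordered by decreasing count then name.
#' @export
detect_replicate_strains <- function(dataset) {
  counts <- table(squish(dataset$genome_name))
  counts <- counts[counts >= 2]
  tibble::tibble(
    genome_name = names(counts),
    n_genomes = as.integer(counts)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_genomes), .data$genome_name)
}

#' Grouped genome counts
#'
#' Cross-tabulates the dataset by any subset of its columns, counting
#' genomes and distinct 12-digit enzyme patterns per group. Missing
#' annotation is rendered as the explicit label `"Null"`. Output is
#' ordered lexicographically by the grouping keys, so within any complete
#' partition the genome counts sum to the dataset size.
#'
#' @param dataset A `denit_dataset`.
#' @param by Character vector of dataset column names to group by.
#' @return A tibble of the keys plus `n_genomes` and `n_patterns`.
#' @export
summarize_dataset <- function(dataset, by) {
  unknown <- setdiff(by, names(dataset))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown grouping column(s): ", paste(unknown, collapse = ", ")
    ))
  }
  dataset |>
    tibble::as_tibble() |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(by),
      function(x) dplyr::coalesce(as.character(x), "Null")
    )) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      n_patterns = dplyr::n_distinct(.data$denitrifying_enzymes_pattern),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}

#' Count distinct non-missing values of a column
#'
#' @param dataset A `denit_dataset`.
#' @param column Column name.
#' @return Integer count of distinct non-`NA` values.
#' @export
count_distinct <- function(dataset, column) {
  if (!column %in% names(dataset)) {
    rlang::abort(paste0("unknown column: ", column))
  }
  dplyr::n_distinct(dataset[[column]], na.rm = TRUE)
}

#' Filter the dataset by column predicates
#'
#' Conjunction of simple predicates with stable row order:
#' named arguments in `...` are matched to dataset columns by set
#' membership (`column %in% values`); `name_contains` is a
#' case-insensitive substring match on the genome name; `genes_present` /
#' `genes_absent` require the named enzyme genes' digits to be 1 / 0.
#' With no predicates the dataset is returned unchanged.
#'
#' @param dataset A `denit_dataset`.
#' @param ... Named predicates, e.g. `ecosystem_category = "Aquatic"`,
#'   `denitrification_pattern = "1111"`.
#' @param name_contains Substring to require in `genome_name`
#'   (case-insensitive).
#' @param genes_present,genes_absent Character vectors of catalog gene
#'   symbols.
#' @param catalog Gene catalog used to resolve gene symbols.
#' @return The filtered `denit_dataset`.
#' @examples
#' \dontrun{
#' filter_dataset(ds, name_contains = "denitrificans",
#'                denitrification_pattern = "1111")
#' }
#' @export
filter_dataset <- function(dataset, ..., name_contains = NULL,
                           genes_present = NULL, genes_absent = NULL,
                           catalog = denitrification_catalog()) {
  preds <- list(...)
  if (length(preds) > 0 && (is.null(names(preds)) || any(!nzchar(names(preds))))) {
    rlang::abort("column predicates must be named")
  }
  unknown <- setdiff(names(preds), names(dataset))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown filter column(s): ", paste(unknown, collapse = ", ")
    ))
  }
  keep <- rep(TRUE, nrow(dataset))
  for (col in names(preds)) {
    keep <- keep & dataset[[col]] %in% preds[[col]]
  }
  if (!is.null(name_contains)) {
    keep <- keep & stringr::str_detect(
      dataset$genome_name,
      stringr::fixed(name_contains, ignore_case = TRUE)
    )
  }
  gene_digit <- function(genes, want) {
    bad <- setdiff(genes, catalog$gene_symbol)
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown gene symbol(s): ", paste(bad, collapse = ", ")))
    }
    cols <- enzyme_columns(catalog)[match(genes, catalog$gene_symbol)]
    Reduce(`&`, lapply(cols, function(cl) dataset[[cl]] == want), keep)
  }
  if (!is.null(genes_present)) keep <- gene_digit(genes_present, 1L)
  if (!is.null(genes_absent)) keep <- gene_digit(genes_absent, 0L)
  out <- dataset[keep, , drop = FALSE]
  new_denit_dataset(out, excluded = attr(dataset, "excluded") %||% 0L)
}

#' Annotate the dataset with auxiliary KO gene lists
#'
#' Adds one logical column per auxiliary KO (e.g. nitrogen-assimilation
#' genes nifH, nasA, narB, nirA, glnA, or carbon-fixation K01601): `TRUE`
#' iff the genome appears in that KO's genome list. Auxiliary genome IDs
#' absent from the dataset are ignored with a message. A per-KO summary
#' (gene label, KO identifier, genome count, example genome) is attached
#' as attribute `"aux_summary"` and retrieved with [aux_ko_summary()].
#'
#' @param dataset A `denit_dataset`.
#' @param aux_lists Named list; each element is either a tibble from
#'   [read_ko_genome_list()] or a character vector of genome IDs. Names
#'   are the gene labels (e.g. `"glnA"`).
#' @return The dataset with one `aux_<label>` logical column per entry.
#' @export
annotate_auxiliary_kos <- function(dataset, aux_lists) {
  if (is.null(names(aux_lists)) || any(!nzchar(names(aux_lists)))) {
    rlang::abort("aux_lists must be a named list")
  }
  out <- dataset
  rows <- vector("list", length(aux_lists))
  for (i in seq_along(aux_lists)) {
    label <- names(aux_lists)[i]
    x <- aux_lists[[i]]
    if (is.data.frame(x)) {
      ids <- x$genome_id
      ko <- if ("ko_id" %in% names(x) && nrow(x) > 0) x$ko_id[1] else NA_character_
    } else {
      ids <- as.character(x)
      ko <- NA_character_
    }
    unmatched <- sum(!ids %in% dataset$genome_id)
    if (unmatched > 0) {
      rlang::inform(sprintf(
        "%d %s genome ID(s) absent from the dataset; ignored", unmatched, label
      ))
    }
    flag <- dataset$genome_id %in% ids
    out[[paste0("aux_", label)]] <- flag
    rows[[i]] <- tibble::tibble(
      gene_symbol = label,
      ko_id = ko,
      genome_count = sum(flag),
      example_genome = if (any(flag)) dataset$genome_name[which(flag)[1]] else NA_character_
    )
  }
  out <- new_denit_dataset(out, excluded = attr(dataset, "excluded") %||% 0L)
  attr(out, "aux_summary") <- dplyr::bind_rows(rows)
  out
}

#' Per-KO summary of auxiliary annotation
#'
#' @param dataset Result of [annotate_auxiliary_kos()].
#' @return A tibble `gene_symbol`, `ko_id`, `genome_count`,
#'   `example_genome`.
#' @export
aux_ko_summary <- function(dataset) {
  s <- attr(dataset, "aux_summary")
  if (is.null(s)) {
    rlang::abort("dataset has no auxiliary annotation; run annotate_auxiliary_kos()")
  }
  s
}

#' Export the dataset to delimited text
#'
#' Writes the dataset with display-style column headers ("Genome ID",
#' "GTDB-Tk Genus", "Denitrifying Enzymes Pattern", ...) in the schema
#' group order. Pattern columns are text, and [import_dataset()] reads
#' them back as text, so leading zeros ("0100") survive the round trip.
#'
#' @param dataset A `denit_dataset`.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(dataset, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  out <- tibble::as_tibble(dataset)
  nm <- dataset_name_map()
  display <- names(out)
  hit <- match(display, names(nm))
  display[!is.na(hit)] <- nm[hit[!is.na(hit)]]
  display[display == "denitrification_pattern"] <- "Denitrification Pattern"
  display[display == "denitrification_traits"] <- "Denitrification Traits"
  display[display == "denitrifying_enzymes_pattern"] <- "Denitrifying Enzymes Pattern"
  names(out) <- display
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Re-import an exported dataset
#'
#' Inverse of [export_dataset()]: restores snake_case columns and column
#' types (pattern and enzyme columns as text/integer, counts as numeric),
#' so `import_dataset(export_dataset(x, p), ...)` reproduces `x`.
#'
#' @param path File written by [export_dataset()].
#' @param catalog Gene catalog; defaults to [denitrification_catalog()].
#' @return A `denit_dataset`.
#' @export
import_dataset <- function(path, catalog = denitrification_catalog()) {
  raw <- read_delim_chr(path)
  nm <- dataset_name_map()
  idx <- match(names(raw), nm)
  names(raw)[!is.na(idx)] <- names(nm)[idx[!is.na(idx)]]
  names(raw)[names(raw) == "Denitrification Pattern"] <- "denitrification_pattern"
  names(raw)[names(raw) == "Denitrification Traits"] <- "denitrification_traits"
  names(raw)[names(raw) == "Denitrifying Enzymes Pattern"] <- "denitrifying_enzymes_pattern"
  for (col in intersect(c("gene_count", "genome_size"), names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  for (col in intersect(enzyme_columns(catalog), names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  new_denit_dataset(raw)
}
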