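# Readers for IMG/M-style exports: per-KO genome lists and genome metadata.
# Both dialects are plain delimited text; tabs are the native delimiter but
# comma-separated copies of the same content must parse identically.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return("\t")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_chr <- function(path) {
  out <- readr::read_delim(
    path,
    delim = detect_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  out
}

squish <- function(x) stringr::str_squish(x)

#' Read a per-KO genome list export
#'
#' Reads one IMG/M-style genome list (the genomes annotated with one KEGG
#' Orthology term) and labels it with its dataset label, e.g. `"01_narG"`
#' or `"12_nosZ"`. The numeric prefix of the label must match the gene's
#' digit position in the catalog; labels whose gene symbol is not in the
#' catalog (auxiliary KOs) skip that check.
#'
#' @param path Delimited text file with a header containing at least
#'   `Domain`, `Status`, `Genome ID` and `Genome Name` (tab preferred,
#'   comma accepted).
#' @param dataset_label Label of the form `"NN_geneSymbol"`.
#' @param catalog Gene catalog used to validate the label and attach the
#'   KO identifier; defaults to [denitrification_catalog()].
#' @return A tibble with columns `dataset_label`, `ko_id`, `domain`,
#'   `status`, `genome_id`, `genome_name`, one row per genome (duplicate
#'   genome IDs within the list are collapsed with a warning: a genome
#'   carries a KO at most once in the presence model).
#' @export
read_ko_genome_list <- function(path, dataset_label,
                                catalog = denitrification_catalog()) {
  raw <- read_delim_chr(path)
  required <- c("Domain", "Status", "Genome ID", "Genome Name")
  hit <- match(tolower(required), tolower(names(raw)))
  if (anyNA(hit)) {
    rlang::abort(paste0(
      "genome list '", path, "' is missing column(s): ",
      paste(required[is.na(hit)], collapse = ", ")
    ))
  }

  gene <- sub("^\\d+_", "", dataset_label)
  prefix <- suppressWarnings(as.integer(sub("_.*$", "", dataset_label)))
  ko <- NA_character_
  if (gene %in% catalog$gene_symbol) {
    pos <- catalog$position[catalog$gene_symbol == gene]
    if (is.na(prefix) || prefix != pos) {
      rlang::abort(sprintf(
        "dataset label '%s' does not match catalog position %02d of %s",
        dataset_label, pos, gene
      ))
    }
    ko <- catalog$ko_id[catalog$gene_symbol == gene]
  }

  out <- tibble::tibble(
    dataset_label = dataset_label,
    ko_id = ko,
    domain = raw[[hit[1]]],
    status = raw[[hit[2]]],
    genome_id = raw[[hit[3]]],
    genome_name = squish(raw[[hit[4]]])
  )
  if (nrow(out) == 0) {
    rlang::warn(paste0("genome list '", path, "' is empty"))
    return(out)
  }
  if (any(!nzchar(out$genome_id) | is.na(out$genome_id))) {
    rlang::abort(paste0("genome list '", path, "' has empty Genome ID values"))
  }
  dup <- duplicated(out$genome_id)
  if (any(dup)) {
    rlang::warn(sprintf(
      "%d duplicate genome ID(s) collapsed in %s", sum(dup), dataset_label
    ))
    out <- out[!dup, ]
  }
  out
}

#' Merge twelve per-KO genome lists into a presence matrix
#'
#' Takes the twelve labelled genome lists (one per catalog gene) and
#' produces one row per distinct genome with a 0/1 presence column per
#' enzyme gene (`E01_narG` ... `E12_nosZ`). Genome identity is the Genome
#' ID; when lists disagree on a genome's name, domain or status, the
#' first-seen value (in list order) wins and the conflict is reported as a
#' warning.
#'
#' @param lists A list of tibbles from [read_ko_genome_list()], one per
#'   catalog gene, in any order.
#' @param catalog Gene catalog; defaults to [denitrification_catalog()].
#' @return A tibble with columns `genome_id`, `genome_name`, `domain`,
#'   `status` and one integer presence column per gene. Every row has at
#'   least one present gene by construction.
#' @export
merge_ko_lists <- function(lists, catalog = denitrification_catalog()) {
  validate_catalog(catalog)
  expected <- sprintf("%02d_%s", catalog$position, catalog$gene_symbol)
  labels <- vapply(
    lists,
    function(x) if (nrow(x) > 0) x$dataset_label[1] else NA_character_,
    character(1)
  )
  # an empty list is legitimate (no genome carries that KO); recover its
  # label from the names of `lists` if present
  if (!is.null(names(lists))) {
    labels[is.na(labels)] <- names(lists)[is.na(labels)]
  }
  if (anyNA(labels) || any(duplicated(labels)) ||
      !setequal(labels, expected)) {
    rlang::abort(paste0(
      "expected exactly one list per catalog label (",
      paste(expected, collapse = ", "), ")"
    ))
  }
  lists <- lists[match(expected, labels)]

  all_rows <- dplyr::bind_rows(lists)
  first_seen <- all_rows[!duplicated(all_rows$genome_id), ]

  conflicts <- all_rows |>
    dplyr::distinct(.data$genome_id, .data$genome_name) |>
    dplyr::count(.data$genome_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    rlang::warn(sprintf(
      "genome name conflict for %d genome ID(s); first-seen name kept (%s)",
      nrow(conflicts),
      paste(utils::head(conflicts$genome_id, 5), collapse = ", ")
    ))
  }

  presence <- purrr::map(lists, function(x) {
    as.integer(first_seen$genome_id %in% x$genome_id)
  })
  names(presence) <- paste0("E", expected)

  dplyr::bind_cols(
    first_seen[, c("genome_id", "genome_name", "domain", "status")],
    tibble::as_tibble(presence)
  )
}

# snake_case <-> display-name map for the dataset schema
dataset_name_map <- function() {
  c(
    domain = "Domain",
    gene_count = "Gene Count",
    genome_id = "Genome ID",
    genome_name = "Genome Name",
    genome_size = "Genome Size",
    genus = "Genus",
    gold_sequencing_project_id = "GOLD Sequencing Project ID",
    sequencing_center = "Sequencing Center",
    sequencing_status = "Sequencing Status",
    status = "Status",
    ecosystem = "Ecosystem",
    ecosystem_category = "Ecosystem Category",
    ecosystem_type = "Ecosystem Type",
    ecosystem_subtype = "Ecosystem Subtype",
    specific_ecosystem = "Specific Ecosystem",
    gtdb_domain = "GTDB-Tk Domain",
    gtdb_phylum = "GTDB-Tk Phylum",
    gtdb_order = "GTDB-Tk Order",
    gtdb_family = "GTDB-Tk Family",
    gtdb_genus = "GTDB-Tk Genus",
    gtdb_species = "GTDB-Tk Species"
  )
}

#' Read a genome metadata table
#'
#' Reads a delimited genome metadata export (GTDB-Tk lineage, GOLD 5-level
#' ecosystem, genome size and sequencing fields). Display-style column
#' headers ("Genome ID", "GTDB-Tk Genus", ...) are mapped to snake_case;
#' empty fields become explicit `NA`.
#'
#' @param path Delimited text file with at least a `Genome ID` column.
#' @return A tibble keyed by `genome_id` (duplicates are an error).
#' @export
read_metadata <- function(path) {
  raw <- read_delim_chr(path)
  nm <- dataset_name_map()
  idx <- match(tolower(names(raw)), tolower(nm))
  names(raw)[!is.na(idx)] <- names(nm)[idx[!is.na(idx)]]
  names(raw) <- gsub("[^A-Za-z0-9]+", "_", names(raw)) |> tolower()
  if (!"genome_id" %in% names(raw)) {
    rlang::abort(paste0("metadata '", path, "' is missing column: Genome ID"))
  }
  dup <- unique(raw$genome_id[duplicated(raw$genome_id)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate Genome ID(s) in metadata: ", paste(dup, collapse = ", ")
    ))
  }
  raw <- dplyr::mutate(
    raw,
    dplyr::across(dplyr::where(is.character), function(x) {
      dplyr::na_if(squish(x), "")
    })
  )
  for (col in intersect(c("gene_count", "genome_size"), names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
    if (any(raw[[col]] < 0, na.rm = TRUE)) {
      rlang::abort(paste0(col, " must be nonnegative"))
    }
  }
  raw
}

#' Derive the genus label from a genome name
#'
#' The text before the first whitespace run of the (whitespace-normalized)
#' genome name; the whole name when it has no space. Note this literal
#' rule assigns "Candidatus" as the genus of Candidatus-prefixed names.
#'
#' @param genome_name Character vector of genome names.
#' @return Character vector of genus labels ("" with a warning for empty
#'   names).
#' @examples
#' derive_genus("Pseudomonas aeruginosa PAO1")  # "Pseudomonas"
#' @export
derive_genus <- function(genome_name) {
  x <- squish(as.character(genome_name))
  x[is.na(x)] <- ""
  if (any(!nzchar(x))) {
    rlang::warn(sprintf("%d empty genome name(s); genus set to \"\"", sum(!nzchar(x))))
  }
  sub("\\s.*$", "", x)
}

#' Join genome metadata onto a presence matrix
#'
#' Left join on `genome_id`: every presence row is kept exactly once;
#' genomes without metadata keep `NA` lineage/ecosystem fields; metadata
#' rows for unknown genomes are ignored (count reported via a message).
#' The presence matrix's own `genome_name`, `domain` and `status` take
#' precedence over metadata copies.
#'
#' @param presence Presence matrix from [merge_ko_lists()].
#' @param metadata Metadata tibble from [read_metadata()].
#' @return The annotated matrix (same row count and order as `presence`).
#' @export
join_metadata <- function(presence, metadata) {
  keep <- setdiff(
    names(metadata),
    setdiff(intersect(names(metadata), names(presence)), "genome_id")
  )
  unmatched <- sum(!metadata$genome_id %in% presence$genome_id)
  if (unmatched > 0) {
    rlang::inform(sprintf(
      "%d metadata row(s) for genome IDs absent from the presence matrix; ignored",
      unmatched
    ))
  }
  dplyr::left_join(presence, metadata[, keep], by = "genome_id")
}
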