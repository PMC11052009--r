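#' Catalog of the twelve canonical denitrification enzyme genes
#'
#' The ordered gene catalog that fixes the digit positions of the 12-digit
#' Denitrifying Enzymes Pattern. Digits 1-12 correspond to
#' narG, narH, narI, napA, napB, nirK, nirS, norB, norC, norV, norW, nosZ,
#' grouped into the four reduction steps of the canonical pathway:
#' nitrate (positions 1-5), nitrite (6-7), nitric oxide (8-11) and
#' nitrous oxide (12). Each gene carries its KEGG Orthology identifier and
#' the enzyme complex it belongs to (narGHI, napAB, nirK, nirS, norBC,
#' norVW, nosZ).
#'
#' @return A tibble with one row per gene and columns `position`,
#'   `gene_symbol`, `ko_id`, `step`, `step_name` and `complex_label`.
#' @examples
#' denitrification_catalog()
#' @export
denitrification_catalog <- function() {
  tibble::tibble(
    position = 1:12,
    gene_symbol = c(
      "narG", "narH", "narI", "napA", "napB",
      "nirK", "nirS",
      "norB", "norC", "norV", "norW",
      "nosZ"
    ),
    ko_id = c(
      "K00370", "K00371", "K00374", "K02567", "K02568",
      "K00368", "K15864",
      "K04561", "K02305", "K12264", "K12265",
      "K00376"
    ),
    step = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 4L),
    step_name = c(
      rep("Nitrate", 5), rep("Nitrite", 2),
      rep("Nitric Oxide", 4), "Nitrous Oxide"
    ),
    complex_label = c(
      "narGHI", "narGHI", "narGHI", "napAB", "napAB",
      "nirK", "nirS",
      "norBC", "norBC", "norVW", "norVW",
      "nosZ"
    )
  )
}

#' Catalog of the six nitrogenase marker genes
#'
#' A companion gene catalog for nitrogen fixation: the structural
#' nitrogenase subunits (nifH, nifD, nifK) and the cofactor-biosynthesis
#' genes (nifE, nifN, nifB), forming the NifHDK and NifENB complexes. Used
#' with [nif_ruleset()] to show that the trait-rule machinery generalizes
#' beyond denitrification.
#'
#' @return A tibble with the same columns as [denitrification_catalog()]
#'   (KO identifiers for nifD/K/E/N/B are left `NA`; only nifH has a KO in
#'   the auxiliary-pathway table).
#' @export
nif_catalog <- function() {
  tibble::tibble(
    position = 1:6,
    gene_symbol = c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB"),
    ko_id = c("K02588", NA, NA, NA, NA, NA),
    step = c(1L, 1L, 1L, 2L, 2L, 2L),
    step_name = c(rep("Structural", 3), rep("Biosynthetic", 3)),
    complex_label = c(rep("nifHDK", 3), rep("nifENB", 3))
  )
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  req <- c("position", "gene_symbol", "ko_id", "step")
  missing <- setdiff(req, names(catalog))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "catalog is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!identical(as.integer(catalog$position), seq_len(nrow(catalog)))) {
    rlang::abort("catalog positions must be 1..n with no gaps")
  }
  if (anyDuplicated(catalog$gene_symbol) > 0) {
    rlang::abort("catalog gene symbols must be unique")
  }
  invisible(catalog)
}
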