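# Scholarly-search and genome-portal link construction. Queries and URLs
# are emitted as text only; no network access is performed.

#' Negation phrases accepted in scholarly searches
#'
#' The negation words usable with [build_scholar_query()] to retrieve
#' literature on incomplete denitrification (e.g. strains lacking nosZ).
#'
#' @return A character vector of eight phrases.
#' @export
scholar_negation_phrases <- function() {
  c("absence", "lack", "lacking", "missing", "no",
    "not possess", "not with", "without")
}

#' Build a Google Scholar search query for a denitrification gene
#'
#' Plain mode renders `denitrification <symbol>`; negation mode renders
#' `("<phrase> of <symbol>" denitrification)` to target literature on
#' incomplete denitrification (e.g. `("absence of nosZ" denitrification)`).
#'
#' @param gene_symbol One of the twelve catalog gene symbols.
#' @param mode `"plain"` or `"negation"`.
#' @param phrase Required in negation mode; one of
#'   [scholar_negation_phrases()].
#' @param catalog Gene catalog; defaults to [denitrification_catalog()].
#' @return A one-row tibble `gene_symbol`, `mode`, `phrase`, `query`.
#' @examples
#' build_scholar_query("nosZ", "negation", "absence")$query
#' @export
build_scholar_query <- function(gene_symbol, mode = c("plain", "negation"),
                                phrase = NULL,
                                catalog = denitrification_catalog()) {
  mode <- match.arg(mode)
  if (!gene_symbol %in% catalog$gene_symbol) {
    rlang::abort(paste0("unknown gene symbol: ", gene_symbol))
  }
  if (mode == "plain") {
    query <- paste("denitrification", gene_symbol)
    phrase <- NA_character_
  } else {
    if (is.null(phrase)) {
      rlang::abort("negation mode requires a phrase")
    }
    if (!phrase %in% scholar_negation_phrases()) {
      rlang::abort(paste0(
        "unknown negation phrase: '", phrase, "'; use one of ",
        paste(scholar_negation_phrases(), collapse = ", ")
      ))
    }
    query <- sprintf("(\"%s of %s\" denitrification)", phrase, gene_symbol)
  }
  tibble::tibble(
    gene_symbol = gene_symbol, mode = mode, phrase = phrase, query = query
  )
}

#' Build the IMG/M per-KO genome-list URL
#'
#' Substitutes a KEGG Orthology identifier into the documented IMG/M
#' FindFunctions URL template. Reference string only; nothing is fetched.
#'
#' @param ko_id KO identifier of the form `K#####` (e.g. `"K00376"`).
#' @return The URL as a string.
#' @examples
#' build_portal_url("K00376")
#' @export
build_portal_url <- function(ko_id) {
  if (length(ko_id) != 1 || !grepl("^K\\d{5}$", ko_id)) {
    rlang::abort(paste0("malformed KO identifier: '", ko_id, "'"))
  }
  paste0(
    "https://img.jgi.doe.gov/cgi-bin/m/main.cgi",
    "?section=FindFunctions&page=findkogenomelist&ko_id=KO:", ko_id,
    "&taxonChoice=allIsolates&data_type"
  )
}
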