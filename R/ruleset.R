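#' Construct a trait rule set
#'
#' A trait rule set maps gene presence to pathway-step completeness. Each
#' step is a disjunction of enzyme complexes; a complex is a set of subunit
#' genes that must all be present for the step digit to be '1'. The rule
#' set is evaluated against patterns encoded over `catalog`
#' (see [apply_trait_rules()]).
#'
#' @param name Short name for the rule set (e.g. `"denitrification"`).
#' @param steps Named list; each element is a list of character vectors,
#'   one vector per alternative complex. The element names are the step
#'   names, in pathway order.
#' @param catalog Gene catalog the rules refer to; every gene symbol in
#'   `steps` must appear in `catalog$gene_symbol`.
#' @return An object of class `trait_ruleset`.
#' @examples
#' trait_ruleset(
#'   "denitrification",
#'   steps = list(
#'     "Nitrate" = list(c("narG", "narH", "narI"), c("napA", "napB")),
#'     "Nitrite" = list("nirK", "nirS"),
#'     "Nitric Oxide" = list(c("norB", "norC"), c("norV", "norW")),
#'     "Nitrous Oxide" = list("nosZ")
#'   ),
#'   catalog = denitrification_catalog()
#' )
#' @export
trait_ruleset <- function(name, steps, catalog) {
  validate_catalog(catalog)
  if (is.null(names(steps)) || any(!nzchar(names(steps)))) {
    rlang::abort("every step must be named")
  }
  steps <- purrr::map(steps, function(alts) purrr::map(alts, as.character))
  referenced <- unique(unlist(steps))
  unknown <- setdiff(referenced, catalog$gene_symbol)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "rule set references gene symbol(s) not in catalog: ",
      paste(unknown, collapse = ", ")
    ))
  }
  structure(
    list(name = name, steps = steps, catalog = catalog),
    class = "trait_ruleset"
  )
}

#' The denitrification trait rule set
#'
#' The four reduction steps of canonical denitrification, each satisfied
#' by at least one complete enzyme complex:
#' \describe{
#'   \item{Nitrate}{narGHI (membrane-bound nitrate reductase) or napAB
#'     (periplasmic nitrate reductase).}
#'   \item{Nitrite}{nirK (copper-type) or nirS (cytochrome cd1-type)
#'     nitrite reductase.}
#'   \item{Nitric Oxide}{norBC (cytochrome c-dependent NO reductase) or
#'     norVW (flavorubredoxin NO reductase).}
#'   \item{Nitrous Oxide}{nosZ (nitrous-oxide reductase).}
#' }
#' Partial complexes never satisfy a step: napB without napA, or norB
#' without norC, contributes nothing.
#'
#' @param catalog Gene catalog; defaults to [denitrification_catalog()].
#' @return A `trait_ruleset` with four steps.
#' @examples
#' rules <- denitrification_ruleset()
#' apply_trait_rules("111001010010", rules)
#' @export
denitrification_ruleset <- function(catalog = denitrification_catalog()) {
  trait_ruleset(
    "denitrification",
    steps = list(
      "Nitrate" = list(c("narG", "narH", "narI"), c("napA", "napB")),
      "Nitrite" = list("nirK", "nirS"),
      "Nitric Oxide" = list(c("norB", "norC"), c("norV", "norW")),
      "Nitrous Oxide" = list("nosZ")
    ),
    catalog = catalog
  )
}

#' The nitrogen-fixation trait rule set
#'
#' Two-step rule set over the six nitrogenase marker genes: the structural
#' step requires the complete NifHDK complex, the biosynthetic step the
#' complete NifENB complex. Included to demonstrate that trait rule sets
#' are generic over gene catalogs.
#'
#' @param catalog Gene catalog; defaults to [nif_catalog()].
#' @return A `trait_ruleset` with two steps.
#' @examples
#' apply_trait_rules(encode_pattern(c("nifH", "nifD", "nifK"), nif_catalog()),
#'                   nif_ruleset())
#' @export
nif_ruleset <- function(catalog = nif_catalog()) {
  trait_ruleset(
    "nitrogen fixation",
    steps = list(
      "Structural" = list(c("nifH", "nifD", "nifK")),
      "Biosynthetic" = list(c("nifE", "nifN", "nifB"))
    ),
    catalog = catalog
  )
}

#' @export
print.trait_ruleset <- function(x, ...) {
  cat("<trait_ruleset:", x$name, ">\n")
  cat(" catalog:", nrow(x$catalog), "genes\n")
  for (i in seq_along(x$steps)) {
    alts <- vapply(
      x$steps[[i]],
      function(g) paste(g, collapse = "+"),
      character(1)
    )
    cat(sprintf(
      " step %d %-14s %s\n", i, names(x$steps)[i],
      paste(alts, collapse = " | ")
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trait rule set
#'
#' @param x A `trait_ruleset`.
#' @param ... Unused.
#' @return A tibble with one row per alternative complex: `step`,
#'   `step_name`, `alternative`, `complex` (genes joined with "+"),
#'   `n_genes`.
#' @method tidy trait_ruleset
#' @export
tidy.trait_ruleset <- function(x, ...) {
  purrr::imap_dfr(x$steps, function(alts, step_name) {
    tibble::tibble(
      step_name = step_name,
      alternative = seq_along(alts),
      complex = vapply(alts, function(g) paste(g, collapse = "+"), character(1)),
      n_genes = lengths(alts)
    )
  }) |>
    dplyr::mutate(
      step = match(.data$step_name, names(x$steps)),
      .before = 1
    )
}

#' Write a trait rule set to a YAML config file
#'
#' Serializes the step structure (step names and gene-symbol lists) so new
#' trait rules can be defined without code changes and read back with
#' [read_ruleset()].
#'
#' @param rules A `trait_ruleset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "trait_ruleset"))
  yaml::write_yaml(
    list(
      name = rules$name,
      steps = purrr::imap(rules$steps, function(alts, nm) {
        list(step_name = nm, alternatives = purrr::map(alts, as.list))
      }) |> unname()
    ),
    path
  )
  invisible(path)
}

#' Read a trait rule set from a YAML config file
#'
#' @param path File written by [write_ruleset()] (or hand-authored in the
#'   same layout).
#' @param catalog Gene catalog the rules refer to.
#' @return A `trait_ruleset`.
#' @export
read_ruleset <- function(path, catalog = denitrification_catalog()) {
  spec <- yaml::read_yaml(path)
  steps <- purrr::map(spec$steps, function(s) {
    purrr::map(s$alternatives, function(a) unlist(a, use.names = FALSE))
  })
  names(steps) <- vapply(spec$steps, `[[`, character(1), "step_name")
  trait_ruleset(spec$name, steps, catalog)
}
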