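#' Validate binary pattern strings
#'
#' Checks that each string is exactly `width` characters drawn from
#' \{'0','1'\} and returns it unchanged. Rejections name the position of
#' the first offending character.
#'
#' @param x Character vector of candidate patterns.
#' @param width Required pattern length (12 for enzyme patterns, 4 for
#'   step patterns).
#' @return `x`, validated.
#' @examples
#' parse_pattern("111000011101")
#' @export
parse_pattern <- function(x, width = 12) {
  x <- as.character(x)
  if (any(is.na(x))) {
    rlang::abort("pattern must not be NA")
  }
  bad_len <- nchar(x) != width
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    rlang::abort(sprintf(
      "pattern '%s' has length %d; expected %d", x[i], nchar(x[i]), width
    ))
  }
  bad_chr <- regexpr("[^01]", x)
  if (any(bad_chr > 0)) {
    i <- which(bad_chr > 0)[1]
    rlang::abort(sprintf(
      "pattern '%s' has invalid character '%s' at position %d",
      x[i], substr(x[i], bad_chr[i], bad_chr[i]), bad_chr[i]
    ))
  }
  x
}

#' Encode gene presence as a binary enzyme pattern
#'
#' Builds the presence/absence digit string over a gene catalog: digit i is
#' '1' exactly when the catalog's position-i gene is present. Genes not
#' mentioned are absent.
#'
#' @param presence Either a character vector of present gene symbols, or a
#'   named logical vector/list mapping gene symbol to presence.
#' @param catalog Gene catalog fixing digit order; defaults to
#'   [denitrification_catalog()].
#' @return A single pattern string of length `nrow(catalog)`.
#' @examples
#' encode_pattern(c("napA", "napB", "nirS", "norB", "norC", "nosZ"))
#' #> "000110111001"
#' @export
encode_pattern <- function(presence, catalog = denitrification_catalog()) {
  validate_catalog(catalog)
  if (is.list(presence)) presence <- unlist(presence)
  if (is.logical(presence)) {
    if (is.null(names(presence))) {
      rlang::abort("logical presence must be named by gene symbol")
    }
    present <- names(presence)[presence]
    keys <- names(presence)
  } else {
    present <- as.character(presence)
    keys <- present
  }
  unknown <- setdiff(keys, catalog$gene_symbol)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown gene symbol(s): ", paste(unknown, collapse = ", ")
    ))
  }
  paste(as.integer(catalog$gene_symbol %in% present), collapse = "")
}

# 0/1 digit matrix (patterns x genes) from pattern strings
pattern_matrix <- function(patterns, width) {
  m <- matrix(
    as.integer(unlist(strsplit(patterns, "", fixed = TRUE))),
    nrow = length(patterns), ncol = width, byrow = TRUE
  )
  m
}

#' Derive the step pattern from an enzyme pattern
#'
#' Applies a trait rule set to one or more enzyme patterns: step digit k is
#' '1' iff at least one of the step's enzyme complexes has every subunit
#' gene present. A pure, vectorized function of the pattern.
#'
#' @param pattern Character vector of enzyme patterns (length
#'   `nrow(rules$catalog)` each).
#' @param rules A `trait_ruleset`; defaults to [denitrification_ruleset()].
#' @return Character vector of step patterns, one digit per step.
#' @examples
#' apply_trait_rules("111000011101")  # -> "1011"
#' apply_trait_rules("110001010000")  # norB without norC: step 3 stays 0
#' @export
apply_trait_rules <- function(pattern, rules = denitrification_ruleset()) {
  stopifnot(inherits(rules, "trait_ruleset"))
  width <- nrow(rules$catalog)
  pattern <- parse_pattern(pattern, width = width)
  m <- pattern_matrix(pattern, width)
  digits <- vapply(rules$steps, function(alts) {
    hit <- rep(FALSE, length(pattern))
    for (genes in alts) {
      pos <- match(genes, rules$catalog$gene_symbol)
      hit <- hit | rowSums(m[, pos, drop = FALSE]) == length(pos)
    }
    as.integer(hit)
  }, integer(length(pattern)))
  if (length(pattern) == 1) {
    paste(digits, collapse = "")
  } else {
    apply(digits, 1, paste, collapse = "")
  }
}

#' Name a 4-digit denitrification pattern
#'
#' Maps each of the 16 possible step patterns to its trait name:
#' "0000" is "Incomplete Enzymes for Denitrification Steps", "1111" is
#' "Complete Denitrification", and any other code names its satisfied
#' steps, joined with commas and a final "and", suffixed "Reduction Only"
#' (e.g. "1011" is "Nitrate, Nitric Oxide and Nitrous Oxide Reduction
#' Only"). Name comparison is case-insensitive (see [trait_code()]).
#'
#' @param code Character vector of 4-digit step patterns.
#' @return Character vector of trait names.
#' @examples
#' trait_name(c("0001", "1011", "1111"))
#' @export
trait_name <- function(code) {
  code <- parse_pattern(code, width = 4)
  steps <- c("Nitrate", "Nitrite", "Nitric Oxide", "Nitrous Oxide")
  vapply(code, function(cd) {
    on <- strsplit(cd, "")[[1]] == "1"
    if (all(on)) return("Complete Denitrification")
    if (!any(on)) return("Incomplete Enzymes for Denitrification Steps")
    nm <- steps[on]
    joined <- if (length(nm) == 1) {
      nm
    } else {
      paste(
        paste(nm[-length(nm)], collapse = ", "),
        nm[length(nm)],
        sep = " and "
      )
    }
    paste(joined, "Reduction Only")
  }, character(1), USE.NAMES = FALSE)
}

#' Look up the 4-digit code for a trait name
#'
#' Inverse of [trait_name()] over the 16 canonical names; matching is
#' case-insensitive.
#'
#' @param name Character vector of trait names.
#' @return Character vector of 4-digit codes (`NA` where unmatched).
#' @export
trait_code <- function(name) {
  codes <- all_step_patterns()
  names(codes) <- tolower(trait_name(codes))
  unname(codes[tolower(trimws(name))])
}

all_step_patterns <- function() {
  sprintf(
    "%s%s%s%s",
    rep(0:1, each = 8), rep(0:1, each = 4), rep(0:1, each = 2), 0:1
  )
}

#' Enumerate the full enzyme-pattern space under a rule set
#'
#' Applies `rules` to every possible enzyme pattern (2^n for an n-gene
#' catalog; 4096 for denitrification) and tabulates the preimage of each
#' step pattern. All 16 step patterns are reachable for the
#' denitrification rules; the preimage sizes follow from per-step
#' inclusion-exclusion (e.g. "1111" has 11/32 * 3/4 * 7/16 * 1/2 * 4096 =
#' 231 preimages).
#'
#' @param rules A `trait_ruleset`; defaults to [denitrification_ruleset()].
#' @return A tibble with one row per enzyme pattern: `enzyme_pattern`,
#'   `step_pattern`, `trait` (named only for 4-step rule sets, else `NA`).
#'   The per-code preimage counts are attached as attribute `"preimages"`
#'   and returned by [preimage_counts()].
#' @examples
#' map <- enumerate_rule_map()
#' nrow(map)               # 4096
#' preimage_counts(map)
#' @export
enumerate_rule_map <- function(rules = denitrification_ruleset()) {
  n <- nrow(rules$catalog)
  ints <- 0:(2^n - 1)
  bits <- vapply(
    seq_len(n),
    function(i) bitwAnd(bitwShiftR(ints, n - i), 1L),
    integer(length(ints))
  )
  patterns <- apply(bits, 1, paste, collapse = "")
  codes <- apply_trait_rules(patterns, rules)
  map <- tibble::tibble(
    enzyme_pattern = patterns,
    step_pattern = codes,
    trait = if (length(rules$steps) == 4) trait_name(codes) else NA_character_
  )
  attr(map, "preimages") <- dplyr::count(
    map, .data$step_pattern,
    name = "n_patterns", sort = FALSE
  ) |>
    dplyr::arrange(.data$step_pattern)
  map
}

#' Preimage sizes of a rule map
#'
#' @param map Result of [enumerate_rule_map()].
#' @return A tibble `step_pattern`, `n_patterns`; counts sum to the size
#'   of the enumerated pattern space.
#' @export
preimage_counts <- function(map) {
  pre <- attr(map, "preimages")
  if (is.null(pre)) {
    pre <- dplyr::count(map, .data$step_pattern, name = "n_patterns") |>
      dplyr::arrange(.data$step_pattern)
  }
  pre
}
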