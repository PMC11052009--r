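#' Plot the distribution of denitrification traits
#'
#' Horizontal bar chart of genome counts per denitrification trait,
#' ordered by the 4-digit pattern; optionally filled by a second grouping
#' column (ecosystem category is the usual choice).
#'
#' @param dataset A `denit_dataset`.
#' @param fill Optional column name to fill bars by (missing annotation
#'   shown as "Null").
#' @return A ggplot object.
#' @export
plot_trait_distribution <- function(dataset, fill = NULL) {
  counts <- summarize_dataset(
    dataset,
    by = c("denitrification_pattern", "denitrification_traits", fill)
  )
  label <- paste(counts$denitrification_pattern, counts$denitrification_traits)
  counts$trait_label <- factor(label, levels = rev(sort(unique(label))))
  p <- ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$n_genomes, y = .data$trait_label)
  )
  p <- if (is.null(fill)) {
    p + ggplot2::geom_col()
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data[[fill]]))
  }
  p + ggplot2::labs(
    x = "Genomes", y = NULL,
    title = "Denitrification traits",
    fill = if (!is.null(fill)) dataset_name_map()[[fill]] else NULL
  )
}

#' Plot per-gene prevalence of the denitrifying enzymes
#'
#' Column chart of the fraction of genomes carrying each of the twelve
#' enzyme genes, in catalog (digit) order.
#'
#' @param dataset A `denit_dataset`.
#' @param catalog Gene catalog; defaults to [denitrification_catalog()].
#' @return A ggplot object.
#' @export
plot_enzyme_prevalence <- function(dataset, catalog = denitrification_catalog()) {
  cols <- enzyme_columns(catalog)
  prevalence <- tibble::tibble(
    gene = factor(catalog$gene_symbol, levels = catalog$gene_symbol),
    step = factor(catalog$step_name, levels = unique(catalog$step_name)),
    fraction = vapply(cols, function(cl) mean(dataset[[cl]] == 1L), numeric(1))
  )
  ggplot2::ggplot(
    prevalence,
    ggplot2::aes(x = .data$gene, y = .data$fraction, fill = .data$step)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "Fraction of genomes",
      title = "Denitrifying enzyme gene prevalence", fill = "Step"
    )
}

#' @rdname plot_trait_distribution
#' @param object A `denit_dataset`.
#' @param ... Unused.
#' @method autoplot denit_dataset
#' @export
autoplot.denit_dataset <- function(object, ...) {
  plot_trait_distribution(object)
}
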