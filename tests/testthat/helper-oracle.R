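# Independent oracles for the rule engine, written against the fixed digit
# order (narG narH narI napA napB nirK nirS norB norC norV norW nosZ) with
# direct digit indexing -- no shared code with apply_trait_rules().

oracle_step_pattern <- function(pattern) {
  vapply(pattern, function(p) {
    d <- as.integer(strsplit(p, "")[[1]]) == 1L
    s1 <- (d[1] && d[2] && d[3]) || (d[4] && d[5])
    s2 <- d[6] || d[7]
    s3 <- (d[8] && d[9]) || (d[10] && d[11])
    s4 <- d[12]
    paste(as.integer(c(s1, s2, s3, s4)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Preimage size of a 4-digit code by per-step counting: enumerate each
# step's own gene positions (<= 2^5 assignments) and multiply the
# per-step satisfying / non-satisfying assignment counts.
oracle_preimage_count <- function(code) {
  step_genes <- list(1:5, 6:7, 8:11, 12)
  step_sat <- function(d, step) {
    switch(step,
      (d[1] && d[2] && d[3]) || (d[4] && d[5]),
      d[1] || d[2],
      (d[1] && d[2]) || (d[3] && d[4]),
      d[1]
    )
  }
  want <- as.integer(strsplit(code, "")[[1]]) == 1L
  counts <- vapply(1:4, function(s) {
    k <- length(step_genes[[s]])
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    sat <- apply(grid, 1, function(row) step_sat(as.logical(row), s))
    sum(sat == want[s])
  }, numeric(1))
  prod(counts)
}

# Write a small IMG/M-style genome list
write_img_list <- function(df, path, delim = "\t") {
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  path
}

img_rows <- function(ids, names, domain = "Bacteria", status = "Finished") {
  tibble::tibble(
    Domain = domain, Status = status,
    `Genome ID` = ids, `Genome Name` = names
  )
}

# Twelve labelled list files realizing the given genome -> pattern map
write_cohort_lists <- function(dir, ids, names, patterns,
                               catalog = denitrification_catalog()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digits <- do.call(rbind, strsplit(patterns, ""))
  labels <- sprintf("%02d_%s", catalog$position, catalog$gene_symbol)
  paths <- vapply(seq_along(labels), function(k) {
    keep <- digits[, k] == "1"
    write_img_list(
      img_rows(ids[keep], names[keep]),
      file.path(dir, paste0(labels[k], ".tsv"))
    )
  }, character(1))
  names(paths) <- labels
  paths
}

read_cohort_lists <- function(paths, catalog = denitrification_catalog()) {
  lists <- lapply(names(paths), function(lab) {
    read_ko_genome_list(paths[[lab]], lab, catalog)
  })
  names(lists) <- names(paths)
  lists
}
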