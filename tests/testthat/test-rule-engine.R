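test_that("the enzyme catalog fixes the twelve digit positions and steps", {
  cat <- denitrification_catalog()
  expect_equal(nrow(cat), 12)
  expect_equal(cat$position, 1:12)
  expect_equal(
    cat$gene_symbol,
    c("narG", "narH", "narI", "napA", "napB", "nirK", "nirS",
      "norB", "norC", "norV", "norW", "nosZ")
  )
  expect_false(anyDuplicated(cat$ko_id) > 0)
  expect_equal(cat$ko_id[cat$gene_symbol == "nosZ"], "K00376")
  expect_equal(cat$step, c(rep(1L, 5), rep(2L, 2), rep(3L, 4), 4L))
})

test_that("the denitrification rule set encodes the four complex disjunctions", {
  rules <- denitrification_ruleset()
  expect_equal(lengths(rules$steps), c(
    "Nitrate" = 2L, "Nitrite" = 2L, "Nitric Oxide" = 2L, "Nitrous Oxide" = 1L
  ))
  expect_setequal(rules$steps[["Nitrate"]][[1]], c("narG", "narH", "narI"))
  expect_setequal(rules$steps[["Nitrate"]][[2]], c("napA", "napB"))
  expect_identical(rules$steps[["Nitrous Oxide"]][[1]], "nosZ")
  singletons <- unlist(purrr::map(
    rules$steps, function(alts) purrr::keep(alts, function(g) length(g) == 1)
  ))
  expect_setequal(singletons, c("nirK", "nirS", "nosZ"))
  expect_error(
    trait_ruleset("x", list(a = list("narX")), denitrification_catalog()),
    "narX"
  )
})

test_that("the nitrogen-fixation rule set evaluates NifHDK and NifENB", {
  rules <- nif_ruleset()
  cat6 <- nif_catalog()
  expect_equal(apply_trait_rules(encode_pattern(cat6$gene_symbol, cat6), rules), "11")
  expect_equal(apply_trait_rules(encode_pattern("nifH", cat6), rules), "00")
  expect_equal(
    apply_trait_rules(encode_pattern(c("nifH", "nifD", "nifK"), cat6), rules),
    "10"
  )
})

test_that("encode_pattern places presence digits by catalog position", {
  expect_equal(
    encode_pattern(c("napA", "napB", "nirS", "norB", "norC", "nosZ")),
    "000110111001"
  )
  expect_equal(
    encode_pattern(c("narG", "narH", "narI", "nirK", "norB", "norW")),
    "111001010010"
  )
  expect_equal(encode_pattern(character(0)), "000000000000")
  expect_equal(
    encode_pattern(c(narG = TRUE, nosZ = TRUE, nirK = FALSE)),
    "100000000001"
  )
  expect_error(encode_pattern(c("nosZ", "nirX")), "nirX")
})

test_that("encode then digit-indexing round-trips the presence set", {
  cat <- denitrification_catalog()
  set.seed(101)
  for (i in 1:25) {
    present <- sample(cat$gene_symbol, sample(0:12, 1))
    pat <- encode_pattern(present, cat)
    decoded <- cat$gene_symbol[strsplit(pat, "")[[1]] == "1"]
    expect_setequal(decoded, present)
  }
})

test_that("parse_pattern validates length and alphabet with positions", {
  expect_equal(parse_pattern("111000011101"), "111000011101")
  expect_error(parse_pattern("1111"), "length 4")
  expect_error(parse_pattern("11100001110X"), "position 12")
  expect_error(parse_pattern("2111000111010"), "length")
  expect_error(parse_pattern("0100"), "length")
  expect_equal(parse_pattern("0100", width = 4), "0100")
})

test_that("apply_trait_rules reproduces the published worked derivations", {
  cases <- c(
    "111001010010" = "1100",  # narGHI + nirK; norB and norW are orphans
    "111000011101" = "1011",  # norBC complete, no nitrite reductase
    "000010111000" = "0110",  # napB without napA fails the nitrate step
    "110001010000" = "0100",  # norB without norC fails the NO step
    "110100011100" = "0010",  # napA without napB; norBC complete
    "111111111001" = "1111",
    "000110111001" = "1111"
  )
  expect_equal(
    apply_trait_rules(names(cases)),
    unname(cases)
  )
  # vectorized call agrees with one-at-a-time calls
  expect_equal(
    vapply(names(cases), apply_trait_rules, character(1), USE.NAMES = FALSE),
    unname(cases)
  )
})

test_that("trait names follow the compositional scheme and are injective", {
  expect_equal(
    trait_name("1011"),
    "Nitrate, Nitric Oxide and Nitrous Oxide Reduction Only"
  )
  expect_equal(trait_name("1111"), "Complete Denitrification")
  expect_equal(trait_name("0001"), "Nitrous Oxide Reduction Only")
  expect_equal(trait_name("0000"), "Incomplete Enzymes for Denitrification Steps")
  codes <- apply(expand.grid(0:1, 0:1, 0:1, 0:1), 1, paste, collapse = "")
  expect_equal(length(unique(trait_name(codes))), 16)
  expect_error(trait_name("112X"), "invalid")
  # case-insensitive inverse lookup
  expect_equal(trait_code("complete denitrification"), "1111")
  expect_equal(trait_code("NITROUS OXIDE REDUCTION ONLY"), "0001")
})

test_that("enumeration covers all 4096 patterns and agrees with the oracle", {
  map <- enumerate_rule_map()
  expect_equal(nrow(map), 4096)
  expect_equal(length(unique(map$enzyme_pattern)), 4096)
  expect_equal(dplyr::n_distinct(map$step_pattern), 16)
  expect_equal(map$step_pattern, oracle_step_pattern(map$enzyme_pattern))

  pc <- preimage_counts(map)
  expect_equal(sum(pc$n_patterns), 4096)
  expect_equal(pc$n_patterns[pc$step_pattern == "1111"], 231)
  expect_equal(pc$n_patterns[pc$step_pattern == "0000"], 189)
  for (cd in pc$step_pattern) {
    expect_equal(
      pc$n_patterns[pc$step_pattern == cd],
      oracle_preimage_count(cd),
      info = cd
    )
  }
})

test_that("adding a gene never turns a step digit off (monotonicity)", {
  cat <- denitrification_catalog()
  set.seed(7)
  for (i in 1:50) {
    present <- sample(cat$gene_symbol, sample(0:11, 1))
    absent <- setdiff(cat$gene_symbol, present)
    added <- sample(absent, 1)
    before <- as.integer(strsplit(
      apply_trait_rules(encode_pattern(present, cat)), ""
    )[[1]])
    after <- as.integer(strsplit(
      apply_trait_rules(encode_pattern(c(present, added), cat)), ""
    )[[1]])
    expect_true(all(after >= before))
  }
})

test_that("each step digit can flip independently of the others", {
  # patterns differing only within one step's digit range flip only that
  # step's output digit
  flips <- list(
    list(off = "000001011001", on = "111001011001", digit = 1),
    list(off = "111000011001", on = "111001011001", digit = 2),
    list(off = "111001000001", on = "111001011001", digit = 3),
    list(off = "111001011000", on = "111001011001", digit = 4)
  )
  for (f in flips) {
    a <- strsplit(apply_trait_rules(f$off), "")[[1]]
    b <- strsplit(apply_trait_rules(f$on), "")[[1]]
    expect_equal(which(a != b), f$digit)
    expect_equal(a[f$digit], "0")
    expect_equal(b[f$digit], "1")
  }
})

test_that("rule sets serialize to YAML and read back equivalent", {
  rules <- denitrification_ruleset()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(rules, path)
  back <- read_ruleset(path)
  expect_equal(back$steps, rules$steps)
  map1 <- enumerate_rule_map(rules)
  map2 <- enumerate_rule_map(back)
  expect_equal(map2$step_pattern, map1$step_pattern)
})

test_that("tidy() lays out one row per alternative complex", {
  td <- tidy(denitrification_ruleset())
  expect_equal(nrow(td), 7)
  expect_equal(sum(td$n_genes), 12)
  expect_equal(td$complex[td$step == 4], "nosZ")
})
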