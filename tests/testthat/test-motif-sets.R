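test_that("hexamer sets canonicalise, deduplicate and validate", {
  s <- hexamer_set(c("gaagaa", "AAGAAG"), name = "x")
  expect_setequal(as.character(s), c("GAAGAA", "AAGAAG"))
  expect_equal(set_name(s), "x")
  expect_warning(hexamer_set(c("GAAGAA", "GAAGAA")), "duplicate")
  expect_error(hexamer_set("GAAGA"), "invalid")
  expect_error(hexamer_set("GAAGAN"), "invalid")
  expect_length(hexamer_set(character(0)), 0)
})

test_that("motif list round-trips through plain text with comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "gaagaa", "", "AAGAAG  "), path)
  s <- read_hexamer_set(path, name = "file")
  expect_setequal(as.character(s), c("GAAGAA", "AAGAAG"))
  write_hexamer_set(s, path)
  expect_identical(readLines(path), c("GAAGAA", "AAGAAG"))
})

test_that("octamer-derived hexamers follow occurrence counting", {
  expect_length(hexamers_from_octamers(character(0)), 0)
  # 3 copies of an A8 octamer contribute AAAAAA nine times
  expect_identical(as.character(hexamers_from_octamers(rep("AAAAAAAA", 3))),
                   "AAAAAA")
  # each constituent hexamer of 2 octamer copies occurs only twice
  expect_length(hexamers_from_octamers(rep("ACGTACGT", 2)), 0)
  expect_error(hexamers_from_octamers("ACGTACGX"), "ACGTACGX")
  # independent loop oracle on a random list with a permissive threshold
  set.seed(42)
  ocs <- replicate(40, paste(sample(c("A", "C"), 8, TRUE), collapse = ""))
  expect_identical(
    as.character(hexamers_from_octamers(ocs, min_occurrences = 3)),
    oracle_octamer_hexamers(ocs, 3))
})

test_that("intersect_at_least counts memberships and is monotone in k", {
  sets <- list(hexamer_set(c("AAAAAA", "CCCCCC")),
               hexamer_set("AAAAAA"),
               hexamer_set(c("AAAAAA", "GGGGGG")))
  expect_identical(as.character(intersect_at_least(sets, 2)), "AAAAAA")
  expect_setequal(as.character(intersect_at_least(sets, 1)),
                  c("AAAAAA", "CCCCCC", "GGGGGG"))
  expect_error(intersect_at_least(list(), 1))
  expect_error(intersect_at_least(sets, 4), "between 1")
  # monotonicity over random families
  set.seed(7)
  for (i in 1:5) {
    fam <- lapply(1:4, function(j) fix_pool(sample(20:80, 1), seed = i * 10 + j))
    prev <- intersect_at_least(fam, 1)
    for (k in 2:4) {
      cur <- intersect_at_least(fam, k)
      expect_true(all(as.character(cur) %in% as.character(prev)))
      prev <- cur
    }
  }
})

test_that("union_size matches inclusion-exclusion on explicit sets", {
  expect_identical(union_size(103, 198, 63), 238L)
  expect_identical(union_size(5, 0, 0), 5L)
  expect_identical(union_size(5, 7, 0), 12L)
  expect_error(union_size(5, 7, 6), "exceed")
  set.seed(11)
  for (i in 1:5) {
    a <- fix_pool(30, i)
    b <- fix_pool(40, i + 100)
    expect_identical(
      union_size(length(a), length(b), length(intersect(a, b))),
      length(union(as.character(a), as.character(b))))
  }
})

test_that("base composition sums to one and averages over disjoint unions", {
  expect_equal(base_composition(hexamer_set("AAAAAA"))$fractions[["A"]], 1)
  expect_equal(base_composition(hexamer_set("AAAAAA"))$AG, 1)
  expect_equal(base_composition(hexamer_set("AAAAAA"))$GC, 0)
  sym <- base_composition(hexamer_set(c("ACGTAC", "GTACGT")))
  expect_equal(unname(sym$fractions), rep(0.25, 4))
  expect_equal(sym$AG, 0.5)
  expect_error(base_composition(hexamer_set(character(0))), "empty")
  # size-weighted mean property
  a <- hexamer_set(c("AAAAAA", "AAAACC"))
  b <- hexamer_set(c("GGGGGG", "GGGTTT", "TTTTTT"))
  ab <- hexamer_set(c(as.character(a), as.character(b)))
  expect_equal(base_composition(ab)$fractions,
               (2 * base_composition(a)$fractions +
                  3 * base_composition(b)$fractions) / 5)
  # optional chi-square against a background
  cc <- suppressWarnings( # small-count chi-square approximation is fine here
    base_composition(a, background = c(A = .25, C = .25, G = .25, T = .25)))
  expect_true(cc$chisq_p >= 0 && cc$chisq_p <= 1)
})

test_that("positional information spans 0 to 2 bits and orders correctly", {
  expect_equal(positional_information(hexamer_set("GAAGAA")), rep(2, 6))
  expect_equal(positional_information(hexamer_set(all_hexamers())),
               rep(0, 6), tolerance = 1e-12)
  expect_equal(positional_information(hexamer_set(c("AAAAAA", "CAAAAA"))),
               c(1, 2, 2, 2, 2, 2))
  # invariant to motif order; strictly decreases when a maximally
  # dissimilar motif joins a singleton
  s1 <- hexamer_set(c("GAAGAA", "TTTCCC", "ACACAC"))
  s2 <- hexamer_set(rev(as.character(s1)))
  expect_equal(positional_information(s1), positional_information(s2))
  expect_true(all(positional_information(hexamer_set(c("AAAAAA", "TTTTTT")))
                  < positional_information(hexamer_set("AAAAAA"))))
})
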