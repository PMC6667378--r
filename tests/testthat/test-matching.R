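test_that("site comparison uses an inclusive margin and unknown-site rules", {
  expect_true(match_coordinate(8, 13, 5))    # boundary: |8-13| == margin
  expect_false(match_coordinate(7, 13, 5))
  expect_true(match_coordinate(18, 13, 5))
  expect_false(match_coordinate(19, 13, 5))
  expect_true(match_coordinate(17, 17, 0))
  expect_false(match_coordinate(16, 17, 0))
  # an unknown input site is less specific and matches anything; a known
  # input matches an unknown reference (NA or the legacy -1 sentinel)
  expect_true(match_coordinate(NA, 12, 3))
  expect_true(match_coordinate(12, NA, 3))
  expect_true(match_coordinate(12, -1, 3))
  expect_true(match_coordinate(NA, NA, 3))
  # zero/negative input coordinates are never valid, even in margin
  expect_false(match_coordinate(0, 2, 5))
  expect_false(match_coordinate(-1, 2, 5))
  expect_false(match_coordinate(-7, NA, 100))
})

test_that("PTM comparison honors types, the no-types mode and the wildcard", {
  ptm <- function(type, site) list(type = type, site = site)
  expect_true(match_ptm(ptm("00046", 15L), ptm("00046", 15L), 0, TRUE))
  expect_false(match_ptm(ptm("00046", 15L), ptm("00047", 15L), 0, TRUE))
  expect_true(match_ptm(ptm("00046", 15L), ptm("00047", 15L), 0, FALSE))
  expect_true(match_ptm(ptm("00000", 15L), ptm("00047", 15L), 0, TRUE))
  # the wildcard is an input-side query device only
  expect_false(match_ptm(ptm("00046", 15L), ptm("00000", 15L), 0, TRUE))
  expect_false(match_ptm(ptm("00046", 15L), ptm("00046", 18L), 2, TRUE))
  expect_true(match_ptm(ptm("00046", 15L), ptm("00046", 18L), 3, TRUE))
})

test_that("matching types implement their quantifier definitions", {
  ref <- parse_proteoform("P01308;00087:53,00798:31,00798:43")
  one_ptm <- parse_proteoform("P01308;00798:31")
  cfg <- function(type, margin = 0) matching_config(type, margin)

  expect_true(match_proteoform(ref, ref, cfg("STRICT")))
  expect_true(match_proteoform(one_ptm, ref, cfg("SUBSET")))
  expect_true(match_proteoform(one_ptm, ref, cfg("ONE")))
  expect_false(match_proteoform(one_ptm, ref, cfg("SUPERSET")))
  expect_false(match_proteoform(one_ptm, ref, cfg("STRICT")))
  expect_true(match_proteoform(ref, one_ptm, cfg("SUPERSET")))

  # identical accession and isoform are required for any match
  expect_false(match_proteoform(parse_proteoform("P31749-3;"),
                                parse_proteoform("P31749;"),
                                cfg("ACCESSION")))
  expect_false(match_proteoform(parse_proteoform("Q00001;"),
                                parse_proteoform("Q00002;"),
                                cfg("ACCESSION")))
  expect_true(match_proteoform(parse_proteoform("P31749-3;00046:1"),
                               parse_proteoform("P31749-3;"),
                               cfg("ACCESSION")))
})

test_that("empty PTM sets follow the vacuous-truth reading; ONE needs input", {
  unmod <- parse_proteoform("P1;")
  mod <- parse_proteoform("P1;00046:10")
  cfg <- function(type) matching_config(type, 0)
  expect_true(match_proteoform(unmod, mod, cfg("SUBSET")))
  expect_true(match_proteoform(mod, unmod, cfg("SUPERSET")))
  expect_true(match_proteoform(unmod, unmod, cfg("STRICT")))
  expect_false(match_proteoform(unmod, mod, cfg("ONE")))
  expect_false(match_proteoform(unmod, unmod, cfg("ONE")))
  expect_false(match_proteoform(unmod, mod, cfg("STRICT")))
})

test_that("STRICT requires a one-to-one assignment with exact sites", {
  cfg <- matching_config("STRICT", 5)  # margin must be ignored
  expect_false(match_proteoform(parse_proteoform("P1;00046:10"),
                                parse_proteoform("P1;00046:12"), cfg))
  # duplicate reference PTMs cannot be consumed twice by one input PTM
  expect_false(match_proteoform(parse_proteoform("P1;00046:10,00046:10"),
                                parse_proteoform("P1;00046:10,00046:11"),
                                cfg))
  expect_true(match_proteoform(parse_proteoform("P1;00046:10,00046:11"),
                               parse_proteoform("P1;00046:11,00046:10"),
                               cfg))
  # unknown pairs with unknown only
  expect_true(match_proteoform(parse_proteoform("P1;00046:?"),
                               parse_proteoform("P1;00046:?"), cfg))
  expect_false(match_proteoform(parse_proteoform("P1;00046:?"),
                                parse_proteoform("P1;00046:10"), cfg))
  # input wildcard type absorbs any reference type at the same site
  expect_true(match_proteoform(parse_proteoform("P1;00000:10"),
                               parse_proteoform("P1;00798:10"), cfg))
})

test_that("every matching type agrees with the brute-force oracle", {
  set.seed(101)
  types <- c("STRICT", "SUPERSET", "SUPERSET_NO_TYPES", "SUBSET",
             "SUBSET_NO_TYPES", "ONE", "ONE_NO_TYPES", "ACCESSION")
  for (i in 1:150) {
    a <- random_proteoform()
    b <- random_proteoform()
    margin <- sample(0:5, 1)
    for (ty in types) {
      expect_identical(match_proteoform(a, b, matching_config(ty, margin)),
                       oracle_match_proteoform(a, b, ty, margin),
                       label = paste(ty, format_proteoform(a), "vs",
                                     format_proteoform(b), "margin", margin))
    }
  }
})

test_that("subset/superset are dual on fully localized proteoforms", {
  set.seed(7)
  for (i in 1:200) {
    a <- random_proteoform(isoform_prob = 0)
    b <- random_proteoform(isoform_prob = 0)
    # duality needs type symmetry too: drop wildcards from both sides
    strip <- function(p) {
      keep <- vapply(p$ptms, function(m) m$type != "00000", logical(1))
      proteoform(p$accession, p$isoform,
                 vapply(p$ptms[keep], `[[`, character(1), "type"),
                 vapply(p$ptms[keep], `[[`, integer(1), "site"))
    }
    a <- strip(a)
    b <- strip(b)
    m <- sample(0:5, 1)
    expect_identical(
      match_proteoform(a, b, matching_config("SUBSET", m)),
      match_proteoform(b, a, matching_config("SUPERSET", m)))
  }
})

test_that("matching a collection yields deterministic, ordered results", {
  refs <- c("P1;", "P1;00046:10", "P1;00046:10,00047:20", "P2;", "P2;00048:5")
  input <- list(parse_proteoform("P1;00046:10"))
  strict <- match_against_kb(input, refs, matching_config("STRICT", 0))
  expect_equal(nrow(strict), 1)
  expect_equal(strict$reference, "P1;00046:10")

  one <- match_against_kb(input, refs, matching_config("ONE", 0))
  expect_equal(one$reference, sort(one$reference))

  acc <- match_against_kb(input, refs, matching_config("ACCESSION", 0))
  expect_true(all(strict$reference %in% acc$reference))
  expect_equal(nrow(acc), 3)

  none <- match_against_kb(list(parse_proteoform("ZZ;")), refs,
                           matching_config("ACCESSION", 0))
  expect_equal(nrow(none), 0)
})

test_that("matching-type and margin arguments are validated", {
  expect_error(matching_config("LOOSE", 0), class = "proteopath_config_error")
  expect_error(matching_config("SUBSET", -1),
               class = "proteopath_config_error")
  expect_error(matching_config("SUBSET", 2.5),
               class = "proteopath_config_error")
  expect_equal(matching_config("subset", 3)$matching_type, "SUBSET")
})
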