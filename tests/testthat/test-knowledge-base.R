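test_that("the fixture knowledge base loads with its authored counts", {
  kb <- fixture_kb()
  expect_s3_class(kb, "knowledge_base")
  expect_length(kb$proteoforms, 12)
  expect_length(unique(kb$participants$reaction_id), 6)
  expect_equal(nrow(kb$pathways), 4)
  expect_equal(sort(unique(kb$gene_map$accession)),
               c("A1", "A2", "A3", "A4", "A5"))
  expect_length(kb$sequences, 5)
  # hierarchy helpers
  expect_equal(proteopath:::pathway_ancestors(kb, "P3"), c("P2", "P1"))
  expect_equal(proteopath:::pathway_top_level(kb, "P3"), "P1")
  expect_equal(proteopath:::pathway_reaction_closure(kb, "P1"),
               c("R1", "R2", "R3", "R4"))
})

test_that("loading rejects missing files and dangling references", {
  dir <- withr::local_tempdir()
  write_fixture_kb(dir)
  file.remove(file.path(dir, "genes.tsv"))
  expect_error(load_kb(dir), "genes.tsv",
               class = "proteopath_config_error")

  dir2 <- withr::local_tempdir()
  write_fixture_kb(dir2)
  cat("P9\tR1\n", file = file.path(dir2, "pathway_reactions.tsv"),
      append = TRUE)
  expect_error(load_kb(dir2), "P9", class = "proteopath_integrity_error")

  dir3 <- withr::local_tempdir()
  write_fixture_kb(dir3)
  cat("R1\tPhosphorylation of A1\tA1;00046:0\tinput\tindividual\n",
      file = file.path(dir3, "reactions.tsv"), append = TRUE)
  expect_error(load_kb(dir3), "reactions.tsv")

  dir4 <- withr::local_tempdir()
  write_fixture_kb(dir4)
  pw <- readLines(file.path(dir4, "pathways.tsv"))
  pw[2] <- "P1\tTop signaling\tP3"  # P1 -> P3 -> P2 -> P1 cycle
  writeLines(pw, file.path(dir4, "pathways.tsv"))
  expect_error(load_kb(dir4), "cycle", class = "proteopath_integrity_error")
})

test_that("reference '-1' sites normalize to unknown at load time", {
  dir <- withr::local_tempdir()
  write_fixture_kb(dir)
  cat("A4;00046:-1\n", file = file.path(dir, "proteoforms.tsv"),
      append = TRUE)
  cat("R4\tA3 modification\tA4;00046:-1\tinput\tindividual\n",
      file = file.path(dir, "reactions.tsv"), append = TRUE)
  kb <- load_kb(dir)
  expect_true("A4;00046:?" %in% kb$proteoforms)
  expect_false(any(grepl("-1", kb$proteoforms, fixed = TRUE)))
})

test_that("save/load round-trips to byte-identical files", {
  kb <- fixture_kb()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_kb(kb, d1)
  save_kb(load_kb(d1), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  }
})

test_that("the synthetic generator is deterministic under a fixed seed", {
  kb1 <- generate_synthetic_kb(n_proteins = 200, ptm_fraction = 0.5,
                               n_reactions = 300, n_pathways = 40, seed = 7)
  kb2 <- generate_synthetic_kb(n_proteins = 200, ptm_fraction = 0.5,
                               n_reactions = 300, n_pathways = 40, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_kb(kb1, d1)
  save_kb(kb2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  }
  kb3 <- generate_synthetic_kb(n_proteins = 200, ptm_fraction = 0.5,
                               n_reactions = 300, n_pathways = 40, seed = 8)
  expect_false(identical(kb1$proteoforms, kb3$proteoforms))
})

test_that("generated structure respects its configuration", {
  kb0 <- generate_synthetic_kb(n_proteins = 50, ptm_fraction = 0,
                               n_reactions = 30, n_pathways = 8, seed = 3)
  counts <- vapply(proteopath:::kb_parsed_proteoforms(kb0),
                   proteopath:::ptm_count, integer(1))
  expect_true(all(counts == 0))
  # every proteoform participates in at least one reaction
  kb <- generate_synthetic_kb(n_proteins = 80, n_reactions = 40,
                              n_pathways = 10, seed = 11)
  expect_setequal(unique(kb$participants$proteoform), kb$proteoforms)
  expect_error(generate_synthetic_kb(n_proteins = 3,
                                     participants_per_reaction = c(2, 10),
                                     seed = 1),
               class = "proteopath_config_error")
})

test_that("PTM prevalence in pathways increases with ptm_fraction", {
  frac_with_ptm <- function(kb) {
    modified <- kb$proteoforms[vapply(proteopath:::kb_parsed_proteoforms(kb),
                                      function(p) {
                                        proteopath:::ptm_count(p) > 0
                                      }, logical(1))]
    has <- vapply(kb$pathways$pathway_id, function(pw) {
      rids <- proteopath:::pathway_reaction_closure(kb, pw)
      any(kb$participants$proteoform[kb$participants$reaction_id %in% rids]
          %in% modified)
    }, logical(1))
    mean(has)
  }
  # sparse pathways (few, small reactions) so the share is not saturated
  shares <- vapply(c(0, 0.15, 0.3, 0.6, 0.9), function(f) {
    mean(vapply(1:4, function(s) {
      frac_with_ptm(generate_synthetic_kb(
        n_proteins = 100, ptm_fraction = f, n_reactions = 60,
        n_pathways = 40, participants_per_reaction = c(2, 3), seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[1], 0)
})

test_that("the alteration rule rewrites the first PTM and shifts sites", {
  r1 <- alter_proteoform(parse_proteoform("X1;00046:15"))
  expect_equal(format_proteoform(r1$altered), "X1;00000:20")
  expect_equal(format_proteoform(r1$original), "X1;00046:15")

  r2 <- alter_proteoform(parse_proteoform("X1;00046:15,00047:30"))
  expect_equal(format_proteoform(r2$altered), "X1;00000:20,00047:35")

  # third and later PTMs are untouched
  r3 <- alter_proteoform(parse_proteoform("X1;00046:15,00047:30,00798:50"))
  expect_equal(format_proteoform(r3$altered), "X1;00000:20,00047:35,00798:50")

  expect_error(alter_proteoform(parse_proteoform("X1;")),
               class = "proteopath_config_error")
})

test_that("sensitivity experiment recovers originals per stringency", {
  kb <- generate_synthetic_kb(n_proteins = 60, ptm_fraction = 0.8,
                              n_reactions = 50, n_pathways = 10, seed = 5)
  res <- sensitivity_experiment(kb, n_samples = 2, sample_size = 25,
                                seed = 13)
  expect_equal(nrow(res), 2 * 8)
  avg <- vapply(split(res$original_pct, res$matching_type), mean, numeric(1))
  expect_equal(unname(avg[["ONE_NO_TYPES"]]), 100)
  expect_equal(unname(avg[["ACCESSION"]]), 100)
  expect_equal(unname(avg[["STRICT"]]), 0)
  # other same-accession proteoforms always exist for eligible proteins
  oth <- vapply(split(res$others_pct, res$matching_type), mean, numeric(1))
  expect_equal(unname(oth[["ACCESSION"]]), 100)
  # typed shares never exceed their no-types counterparts
  for (base in c("ONE", "SUBSET", "SUPERSET")) {
    expect_lte(avg[[base]], avg[[paste0(base, "_NO_TYPES")]])
    expect_lte(oth[[base]], oth[[paste0(base, "_NO_TYPES")]])
  }
  expect_error(sensitivity_experiment(kb, n_samples = 1, sample_size = 1e5),
               class = "proteopath_config_error")
})
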