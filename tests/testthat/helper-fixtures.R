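# Hand-authored fixture knowledge base: 12 proteoforms, 6 reactions,
# 4 pathways (P1 top <- P2 <- P3; P4 top), 5 proteins with sequences,
# gene and variant maps. Written as flat files so tests exercise the reader.
write_fixture_kb <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(lines, name) writeLines(lines, file.path(dir, name))
  w(c("proteoform",
      "A1;",
      "A1;00046:10",
      "A1;00046:10,00047:20",
      "A1-2;",
      "A2;",
      "A2;00048:5",
      "A2;00046:100",
      "A3;",
      "A3;00084:?",
      "A4;",
      "A5;",
      "A5;00046:15"), "proteoforms.tsv")
  w(c("gene_name\taccession",
      "GA1\tA1",
      "GA1ALT\tA1",
      "GA2\tA2",
      "GA3\tA3",
      "GA4\tA4",
      "GA5\tA5"), "genes.tsv")
  w(c("reaction_id\treaction_name\tproteoform\trole\tcontext",
      "R1\tPhosphorylation of A1\tA1;\tinput\tindividual",
      "R1\tPhosphorylation of A1\tA1;00046:10\toutput\tindividual",
      "R1\tPhosphorylation of A1\tA2;\tcatalyst\tcomplex:C1",
      "R2\tA1 complex assembly\tA1;00046:10,00047:20\tinput\tcomplex:C2",
      "R2\tA1 complex assembly\tA3;\tinput\tcomplex:C2",
      "R2\tA1 complex assembly\tA2;00048:5\tregulator\tindividual",
      "R3\tIsoform switch\tA1-2;\tinput\tindividual",
      "R3\tIsoform switch\tA4;\toutput\tindividual",
      "R4\tA3 modification\tA3;00084:?\toutput\tindividual",
      "R4\tA3 modification\tA3;\tinput\tindividual",
      "R5\tA5 signaling\tA5;00046:15\tcatalyst\tindividual",
      "R5\tA5 signaling\tA2;00046:100\tinput\tset:S1",
      "R5\tA5 signaling\tA4;\toutput\tindividual",
      "R6\tA5 turnover\tA5;\tinput\tindividual",
      "R6\tA5 turnover\tA5;00046:15\toutput\tindividual"), "reactions.tsv")
  w(c("pathway_id\tpathway_name\tparent_id",
      "P1\tTop signaling\t-",
      "P2\tMid cascade\tP1",
      "P3\tLeaf events\tP2",
      "P4\tOther top\t-"), "pathways.tsv")
  w(c("pathway_id\treaction_id",
      "P2\tR1",
      "P2\tR2",
      "P3\tR3",
      "P1\tR4",
      "P4\tR5",
      "P4\tR6"), "pathway_reactions.tsv")
  w(c("variant_id\taccession",
      "rs1\tA1",
      "rs2\tA2",
      "rs2\tA3",
      "1:1000\tA4"), "variants.tsv")
  # A1 contains PEPTIDE starting at 1-based position 10;
  # A2 and A3 share the substring SHAREDPEP
  w(c(">A1", paste0("AAAAAAAAA", "PEPTIDE", "KKKKKKKKKK"),
      ">A2", paste0("MSHAREDPEP", "WWWWYYYY"),
      ">A3", paste0("GGG", "SHAREDPEP", "HHHH"),
      ">A4", "MKLVTQRNDEFASTWY",
      ">A5", paste0(paste(rep("ACDEF", 10), collapse = ""), "STYSTY")),
    "sequences.fasta")
  invisible(dir)
}

fixture_kb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "proteopath-fixture-kb")
      write_fixture_kb(dir)
      cache <<- load_kb(dir)
    }
    cache
  }
})

# random proteoform generator over a small accession pool so pairs share
# accessions often; all sites are valid positive integers
random_proteoform <- function(accessions = c("Q1", "Q2"),
                              types = c("00000", "00046", "00047", "00798"),
                              max_ptms = 3, site_pool = 1:25,
                              isoform_prob = 0.2) {
  acc <- sample(accessions, 1)
  iso <- if (stats::runif(1) < isoform_prob) sample(1:2, 1) else NA
  n <- sample(0:max_ptms, 1)
  proteoform(acc, iso,
             if (n) sample(types, n, replace = TRUE) else character(),
             if (n) sample(site_pool, n, replace = TRUE) else integer())
}
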