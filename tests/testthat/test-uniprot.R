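test_that("UniProt FASTA headers map to records with the right reviewed flag", {
  path <- write_fasta_fixture(uniprot_fasta_lines)
  rec <- read_uniprot_fasta(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$accession, c("P02320", "Q9FAKE"))
  expect_equal(rec$reviewed, c(TRUE, FALSE))
  expect_equal(rec$organism, c("Bos taurus", "Sus scrofa"))
  expect_equal(rec$gene_names[[1]], "PRM1")
  expect_match(rec$description[2], "Protamine-like")
  # multi-line sequence is concatenated and uppercased
  expect_equal(nchar(rec$sequence[1]), 51)
})

test_that("an empty FASTA stream yields an empty record set", {
  path <- write_fasta_fixture(character())
  rec <- read_uniprot_fasta(path)
  expect_equal(nrow(rec), 0)
})

test_that("duplicate accessions are rejected", {
  path <- write_fasta_fixture(c(
    ">sp|P02320|A OS=Bos taurus GN=PRM1", "MARYR",
    ">tr|P02320|B OS=Sus scrofa GN=PRM1", "MARYK"))
  expect_error(read_uniprot_fasta(path), "Duplicate accession")
})

test_that("tabular exports parse gene synonyms and ordered lineages", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\treviewed\tgene_names\torganism\tlineage\tprotein_name\tsequence",
    "P02320\treviewed\tPRM1 HSP1\tBos taurus\tEukaryota, Metazoa, Eutheria\tSperm protamine P1\tMARYRCC",
    "Q9XYZ1\tunreviewed\tPrm1\tMus musculus\tEukaryota, Metazoa, Eutheria\tSperm protamine P1\tmaryrss"
  ), path)
  rec <- read_uniprot_tab(path)
  expect_equal(rec$reviewed, c(TRUE, FALSE))
  expect_equal(rec$gene_names[[1]], c("PRM1", "HSP1"))
  expect_equal(rec$lineage[[2]], c("Eukaryota", "Metazoa", "Eutheria"))
  expect_equal(rec$sequence[2], "MARYRSS")  # uppercased
})

test_that("group rules select by lineage, gene name and description", {
  recs <- mixed_records()
  rules <- protamine_rules()

  p1 <- filter_group(recs, rules$eutherian_p1)
  expect_setequal(p1$accession, c("P02320", "Q9MOUS"))

  p2 <- filter_group(recs, rules$eutherian_p2)
  expect_equal(p2$accession, "Q9PRM2")

  meta <- filter_group(recs, rules$metatherian_p1)
  expect_equal(meta$accession, "Q8KANG")

  # fish rule: Actinopterygii lineage, any gene, but "protamine-like" excluded
  fish <- filter_group(recs, rules$fish)
  expect_equal(fish$accession, "P69014")

  # a Metatheria record with gene PRM2 matches neither mammalian rule
  odd <- make_record("Q0ODD1", "Didelphis", metatherian_lineage, c("PRM2"))
  expect_equal(nrow(filter_group(odd, rules$metatherian_p1)), 0)
})

test_that("gene-name matching is exact and case-sensitive", {
  rule <- group_rule("g", "Eutheria", c("PRM1", "Prm1"))
  lower <- make_record("Q00001", "X", eutherian_lineage, c("prm1"))
  expect_equal(nrow(filter_group(lower, rule)), 0)
  synonym <- make_record("Q00002", "Y", eutherian_lineage, c("HSP1", "PRM1"))
  expect_equal(nrow(filter_group(synonym, rule)), 1)
})

test_that("filtering is idempotent and records provenance counts", {
  recs <- mixed_records()
  rule <- protamine_rules()$eutherian_p1
  once <- filter_group(recs, rule)
  twice <- filter_group(once, rule)
  expect_equal(twice$accession, once$accession)
  expect_equal(twice$sequence, once$sequence)
  prov <- attr(once, "provenance")
  expect_equal(prov$n_in, nrow(recs))
  expect_equal(prov$n_out, nrow(once))
  # reapplication removes nothing and appends a no-op provenance step
  prov2 <- attr(twice, "provenance")
  expect_equal(nrow(prov2), 2)
  expect_equal(prov2$n_in[2], prov2$n_out[2])
})

test_that("per-organism deduplication prefers reviewed, then lowest accession", {
  recs <- dplyr::bind_rows(
    make_record("Q9ZZZZ", "Bos taurus", eutherian_lineage, "PRM1"),
    make_record("P02320", "Bos taurus", eutherian_lineage, "PRM1",
                reviewed = TRUE),
    make_record("Q8BBBB", "Mus musculus", eutherian_lineage, "Prm1"),
    make_record("Q8AAAA", "Mus musculus", eutherian_lineage, "Prm1"),
    make_record("Q7SOLO", "Ovis aries", eutherian_lineage, "PRM1")
  )
  kept <- dedupe_per_organism(recs)
  expect_setequal(kept$accession, c("P02320", "Q8AAAA", "Q7SOLO"))
  expect_false(any(duplicated(kept$organism)))
})

test_that("deduplication is invariant under permutation of input order", {
  recs <- dplyr::bind_rows(
    make_record("Q9ZZZZ", "Bos taurus", eutherian_lineage, "PRM1"),
    make_record("P02320", "Bos taurus", eutherian_lineage, "PRM1",
                reviewed = TRUE),
    make_record("Q8BBBB", "Mus musculus", eutherian_lineage, "Prm1"),
    make_record("Q8AAAA", "Mus musculus", eutherian_lineage, "Prm1")
  )
  base <- dedupe_per_organism(recs)
  withr::with_seed(42, {
    for (i in 1:10) {
      perm <- recs[sample(nrow(recs)), ]
      shuffled <- dedupe_per_organism(perm)
      expect_setequal(shuffled$accession, base$accession)
    }
  })
})

test_that("listed members are removed with a warning for absent names", {
  recs <- dplyr::bind_rows(
    make_record("P1RAT0", "Rattus norvegicus", eutherian_lineage, "Prm2"),
    make_record("P1PIG0", "Sus scrofa", eutherian_lineage, "PRM2"),
    make_record("P1MOUS", "Mus musculus", eutherian_lineage, "Prm2")
  )
  trimmed <- remove_members(recs, c("Rattus norvegicus", "P1PIG0"),
                            reason = "aberrant sequences")
  expect_equal(trimmed$accession, "P1MOUS")
  expect_equal(remove_members(recs, character()), recs)
  expect_warning(remove_members(recs, "Cricetulus griseus"),
                 "matched no member")
})
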