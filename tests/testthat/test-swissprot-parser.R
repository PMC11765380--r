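# Swiss-Prot flat-file parsing and per-entry feature counting.

test_that("empty input yields an empty record collection", {
  expect_length(read_swissprot(text = ""), 0)
  expect_length(read_swissprot(text = character()), 0)
})

test_that("a hand-written entry parses to its visible line counts", {
  txt <- dat_entry(
    isoforms = c(event = "Alternative splicing", n = "3"),
    ft_lines = c(ft_feature("VARIANT", 10, note = "A -> V (in dbSNP:rs1)"),
                 ft_feature("VARIANT", 25, note = "R -> Q"),
                 ft_feature("MOD_RES", 40, note = "Phosphoserine")))
  recs <- read_swissprot(text = txt)
  expect_length(recs, 1)
  e <- recs[[1]]
  expect_equal(e$primary_accession, "P12345")
  expect_equal(e$entry_name, "TEST1_HUMAN")
  expect_equal(e$taxon_id, 9606)
  expect_equal(e$gene_name, "TP53")
  expect_equal(e$gene_name_source, "Name")
  expect_equal(e$declared_isoform_count, 3)
  expect_true(e$alternative_splicing_event)
  expect_equal(sum(e$features$key == "VARIANT"), 2)
  expect_equal(sum(e$features$key == "MOD_RES"), 1)
  expect_equal(e$sequence_length, 60)
  expect_equal(e$features$description[3], "Phosphoserine")
  expect_true(all(e$features$begin >= 1 & e$features$end <= e$sequence_length))
})

test_that("entries without an alternative-products block declare zero isoforms", {
  recs <- read_swissprot(text = dat_entry())
  expect_equal(recs[[1]]$declared_isoform_count, 0)
  expect_false(recs[[1]]$alternative_splicing_event)
  expect_equal(unname(entry_feature_counts(recs[[1]])), c(0L, 0L, 0L))
})

test_that("gene name precedence is Name > OrderedLocusNames > ORFNames, with accession fallback", {
  mk <- function(gn) read_swissprot(text = dat_entry(gn_line = gn))[[1]]
  e <- mk("GN   Name=Trp53; Synonyms=P53; OrderedLocusNames=b0001;")
  expect_equal(resolve_gene_key(e)$gene, "TRP53")
  e <- mk("GN   OrderedLocusNames=b0001;")
  expect_equal(resolve_gene_key(e)$gene, "B0001")
  expect_equal(e$gene_name_source, "OrderedLocusNames")
  e <- mk("GN   ORFNames=CG1234;")
  expect_equal(resolve_gene_key(e)$gene, "CG1234")
  # no GN line at all: singleton gene keyed by accession
  txt <- dat_entry(accession = "P99999", gn_line = "DR   PDB; 1ABC; X-ray.")
  e <- read_swissprot(text = txt)[[1]]
  expect_true(is.na(e$gene_name))
  k <- resolve_gene_key(e)
  expect_equal(k$gene, "P99999")
  expect_equal(k$source, "accession_fallback")
  # evidence tags are stripped from GN values
  e <- mk("GN   Name=Abc1 {ECO:0000312|MGI:MGI:88059};")
  expect_equal(resolve_gene_key(e)$gene, "ABC1")
})

test_that("isoform conventions and the splicing-event gate are honoured", {
  spliced <- read_swissprot(text = dat_entry(
    isoforms = c(event = "Alternative splicing", n = "4")))[[1]]
  expect_equal(entry_feature_counts(spliced)[["as_sequences"]], 4L)
  expect_equal(entry_feature_counts(spliced, isoform_convention = "non_canonical")[["as_sequences"]],
               3L)
  # named isoforms from a non-splicing event do not count
  init <- read_swissprot(text = dat_entry(
    isoforms = c(event = "Alternative initiation", n = "2")))[[1]]
  expect_equal(init$declared_isoform_count, 2)
  expect_equal(entry_feature_counts(init)[["as_sequences"]], 0L)
})

test_that("PTM key sets control which modification features count", {
  txt <- dat_entry(ft_lines = c(
    ft_feature("MOD_RES", 5, note = "Phosphoserine"),
    ft_feature("MOD_RES", 12, note = "N6-acetyllysine"),
    ft_feature("CARBOHYD", 20, note = "N-linked (GlcNAc...) asparagine"),
    ft_feature("DISULFID", 8, 30)))
  e <- read_swissprot(text = txt)[[1]]
  expect_equal(entry_feature_counts(e)[["ptm_sequences"]], 3L)  # DISULFID out by default
  expect_equal(entry_feature_counts(e, ptm_keys = c(default_ptm_keys(), "DISULFID"))[["ptm_sequences"]],
               4L)
  expect_equal(entry_feature_counts(e, ptm_keys = "MOD_RES")[["ptm_sequences"]], 2L)
  expect_error(entry_feature_counts(e, ptm_keys = "ACT_SITE"), "unknown PTM")
})

test_that("a malformed entry is skipped with a warning and parsing continues", {
  good <- dat_entry()
  bad <- sub("SQ   SEQUENCE.*CRC64;", "XX   broken", dat_entry(accession = "P00002"))
  good2 <- dat_entry(accession = "P00003", entry_name = "TEST3_HUMAN")
  expect_warning(recs <- read_swissprot(text = paste(good, bad, good2, sep = "\n")),
                 "missing SQ")
  expect_length(recs, 2)
  expect_equal(attr(recs, "n_malformed"), 1L)
  expect_equal(vapply(recs, `[[`, character(1), "primary_accession"),
               c("P12345", "P00003"))
})

test_that("binary input is rejected as a format error", {
  f <- tempfile()
  writeBin(as.raw(rep(c(1:8, 11, 12, 14:31), 10)), f)
  expect_error(suppressWarnings(read_swissprot(f)),
               "does not look like Swiss-Prot")
})

test_that("gzip-compressed flat files are read transparently", {
  sim <- simulate_proteome(n_genes = 4, seed = 5)
  f <- tempfile(fileext = ".dat.gz")
  con <- gzfile(f, "wt"); writeLines(sim$dat, con); close(con)
  recs <- read_swissprot(f)
  expect_length(recs, 4)
  expect_equal(recs[[2]]$primary_accession, "P00002")
})

test_that("parsing a generated flat file reproduces the planted per-entry truth", {
  for (seed in c(1, 17, 2024)) {
    sim <- simulate_proteome(n_genes = 25, seed = seed)
    recs <- read_swissprot(text = sim$dat)
    expect_length(recs, 25)
    got <- feature_count_table(recs)
    expect_equal(got$accession, sim$truth$accession)  # order-preserving
    expect_equal(got$as_sequences, sim$truth$as_sequences)
    expect_equal(got$sap_sequences, sim$truth$sap_sequences)
    expect_equal(got$ptm_sequences, sim$truth$ptm_sequences)
    # total SAP sequences equal the number of FT VARIANT lines in the file
    n_variant_lines <- sum(grepl("^FT   VARIANT",
                                 strsplit(sim$dat, "\n")[[1]]))
    expect_equal(sum(got$sap_sequences), n_variant_lines)
    # feature coordinates stay inside the sequence
    for (e in recs) {
      if (nrow(e$features)) {
        expect_true(all(e$features$begin >= 1))
        expect_true(all(e$features$end <= e$sequence_length))
      }
    }
  }
})

test_that("parse is idempotent on its own serialized output", {
  sim <- simulate_proteome(n_genes = 12, seed = 99)
  r1 <- read_swissprot(text = sim$dat)
  r2 <- read_swissprot(text = write_swissprot(r1))
  expect_identical(feature_count_table(r1), feature_count_table(r2))
  expect_identical(write_swissprot(r1), write_swissprot(r2))
})

test_that("the audit TSV matches the in-memory feature-count table", {
  sim <- simulate_proteome(n_genes = 6, seed = 3)
  recs <- read_swissprot(text = sim$dat)
  f <- tempfile(fileext = ".tsv")
  write_entry_audit(recs, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$accession, sim$truth$accession)
  expect_equal(back$sap_sequences, sim$truth$sap_sequences)
})
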