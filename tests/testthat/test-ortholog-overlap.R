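# Orthogroup tables, the overlap statistic, alignment scoring and RBH
# orthogroup inference.

test_that("orthogroup tables read, validate and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines("Orthogroup\thuman\tmouse", f)
  tab <- read_orthogroups(f)
  expect_length(tab$groups, 0)
  expect_equal(tab$species_order, c("human", "mouse"))

  writeLines(c("Orthogroup\thuman\tmouse",
               "OG1\th1\tm1",
               "OG2\th2\t"), f)
  tab <- read_orthogroups(f)
  expect_equal(lengths(lapply(tab$groups, function(g) unlist(g))),
               c(OG1 = 2L, OG2 = 1L))
  expect_equal(tab$groups$OG2$mouse, character())

  # canonicalized write/read is byte-identical
  canon <- write_orthogroups(tab)
  f2 <- tempfile(); writeLines(canon, f2)
  expect_identical(write_orthogroups(read_orthogroups(f2)), canon)

  writeLines(c("Orthogroup\thuman\tmouse", "OG1\th1\tm1\textra"), f)
  expect_error(read_orthogroups(f), "ragged row at line 2")
  writeLines(c("Orthogroup\thuman", "OG1\th1", "OG1\th2"), f)
  expect_error(read_orthogroups(f), "duplicate orthogroup")
  writeLines(c("Orthogroup\thuman", "OG1\th1, h1"), f)
  expect_error(read_orthogroups(f), "duplicate protein id")
})

test_that("aging-gene symbols map to accessions case-insensitively", {
  map <- data.frame(symbol = c("TP53", "EGFR", "FOXO3"),
                    accession = c("P04637", "P00533", "O43524"))
  expect_length(map_aging_genes(character(), map)$accessions, 0)
  got <- map_aging_genes(c("TP53", "egfr"), map)
  expect_setequal(got$accessions, c("P04637", "P00533"))
  got <- map_aging_genes(c("TP53", "NOSUCH"), map)
  expect_equal(got$unmapped, "NOSUCH")
  expect_equal(got$accessions, "P04637")
  expect_error(map_aging_genes("TP53", map[0, ]), "empty symbol-to-accession")
})

test_that("the overlap statistic counts groups with aging humans and target proteins", {
  f <- tempfile()
  writeLines(c("Orthogroup\thuman\tmouse",
               "OG1\th1\tm1",
               "OG2\th2\t",
               "OG3\th3\tm2"), f)
  tab <- read_orthogroups(f)
  expect_equal(count_orthogroup_overlap(tab, character(), "human", "mouse")$n_orthogroups, 0)
  oc <- count_orthogroup_overlap(tab, c("h1", "h2"), "human", "mouse")
  expect_equal(oc$n_orthogroups, 1)       # OG2 has no mouse protein
  expect_equal(oc$orthogroup_ids, "OG1")
  # one aging gene family split over two groups, both with mouse members
  writeLines(c("Orthogroup\thuman\tmouse",
               "OG1\th1\tm1",
               "OG2\th1b, h9\tm2"), f)
  tab2 <- read_orthogroups(f)
  expect_equal(count_orthogroup_overlap(tab2, c("h1", "h1b"), "human", "mouse")$n_orthogroups, 2)
  expect_error(count_orthogroup_overlap(tab, "h1", "human", "rat"), "unknown species")
  # the human column against itself counts all aging-containing groups
  expect_equal(count_orthogroup_overlap(tab, c("h1", "h2"), "human", "human")$n_orthogroups, 2)
})

test_that("overlap equals brute-force enumeration and is monotone", {
  set.seed(77)
  for (i in 1:60) {
    tab <- random_orthogroup_table(sample(1:12, 1))
    acc <- sprintf("human_p%d", sample.int(50, sample(0:8, 1)))
    for (target in c("mouse", "fly")) {
      expect_equal(count_orthogroup_overlap(tab, acc, "human", target)$n_orthogroups,
                   brute_force_overlap(tab, acc, "human", target))
    }
    # enlarging the aging set never decreases a count
    extra <- c(acc, sprintf("human_p%d", sample.int(50, 2)))
    expect_gte(count_orthogroup_overlap(tab, extra, "human", "mouse")$n_orthogroups,
               count_orthogroup_overlap(tab, acc, "human", "mouse")$n_orthogroups)
  }
})

test_that("alignment scores match hand-derived values and error on bad input", {
  expect_identical(nw_align_score("ACD", "ACD"), 19L)   # 4 + 9 + 6
  expect_identical(nw_align_score("", ""), 0L)
  expect_identical(nw_align_score("A", "D"), -2L)       # substitution beats two gaps
  expect_identical(nw_align_score("A", ""), -11L)       # open 10 + extend 1
  expect_identical(nw_align_score("", "ACD"), -13L)
  expect_error(nw_align_score("ACX", "ACD"), "position 3")
  expect_error(nw_align_score("ACD", "AB"), "position 2 of sequence b")
})

test_that("alignment scores agree with an independent aligner on random pairs", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(31)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  for (i in 1:25) {
    a <- paste(sample(aa, sample(3:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:40, 1), replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = BLOSUM62,
                                         gapOpening = 10, gapExtension = 1,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(nw_align_score(a, b), as.integer(ref))
  }
})

test_that("RBH inference recovers planted families and degenerate cases", {
  # single species: no cross-species edges, empty table
  one <- infer_orthogroups_rbh(list(human = c(p1 = "MKVLATTRSE")))
  expect_length(one$groups, 0)
  # two identical sequences: one orthogroup of size two
  two <- infer_orthogroups_rbh(list(human = c(h1 = "MKVLATTRSE"),
                                    mouse = c(m1 = "MKVLATTRSE")))
  expect_length(two$groups, 1)
  expect_equal(two$groups[[1]]$human, "h1")
  expect_equal(two$groups[[1]]$mouse, "m1")
  # planted families are recovered as the identical partition
  scn <- simulate_ortholog_families(n_species = 2, n_families = 3,
                                    aging_fraction = 1 / 3, seed = 9)
  inferred <- infer_orthogroups_rbh(scn$proteomes)
  expect_equal(length(inferred$groups), 3)
  part <- function(tab) unname(lapply(tab$groups, function(g) sort(unlist(g))))
  expect_setequal(part(inferred), part(scn$orthogroups))
  # duplicate protein ids are rejected
  expect_error(infer_orthogroups_rbh(list(a = c(x = "MKV", x = "MKL"),
                                          b = c(y = "MKV"))),
               "duplicate")
})

test_that("RBH inference is invariant to input sequence order", {
  scn <- simulate_ortholog_families(n_species = 2, n_families = 3,
                                    seq_length = 60, seed = 13)
  base <- infer_orthogroups_rbh(scn$proteomes)
  shuffled <- lapply(scn$proteomes, function(x) x[rev(seq_along(x))])
  again <- infer_orthogroups_rbh(shuffled)
  part <- function(tab) unname(lapply(tab$groups, function(g) sort(unlist(g))))
  expect_setequal(part(base), part(again))
})

test_that("planted aging families flow end-to-end through RBH to the expected counts", {
  scn <- simulate_ortholog_families(n_species = 3, n_families = 4,
                                    aging_fraction = 0.5, seq_length = 60,
                                    seed = 55)
  inferred <- infer_orthogroups_rbh(scn$proteomes)
  aging <- map_aging_genes(scn$aging_symbols, scn$mapping)
  for (target in setdiff(scn$species, "human")) {
    expected <- brute_force_overlap(scn$orthogroups, aging$accessions,
                                    "human", target)
    got <- count_orthogroup_overlap(inferred, aging, "human", target)
    expect_equal(got$n_orthogroups, expected)
  }
  # removing a species column leaves other counts unchanged
  reduced <- scn$orthogroups
  reduced$species_order <- setdiff(reduced$species_order, "species02")
  reduced$groups <- lapply(reduced$groups, function(g) g[reduced$species_order])
  expect_equal(count_orthogroup_overlap(reduced, aging, "human", "species01")$n_orthogroups,
               count_orthogroup_overlap(scn$orthogroups, aging, "human", "species01")$n_orthogroups)
})
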