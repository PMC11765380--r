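# Hand-written Swiss-Prot DAT fixtures, built in code so the expected
# feature counts can be read straight off the lines below.

# One complete entry; arguments splice optional blocks in and out.
dat_entry <- function(accession = "P12345",
                      entry_name = "TEST1_HUMAN",
                      taxon = 9606,
                      gn_line = "GN   Name=TP53;",
                      isoforms = NULL,     # e.g. c(event = "Alternative splicing", n = 3)
                      ft_lines = character(),
                      seq_len = 60,
                      sq_line = NULL) {
  seqc <- paste(rep("MKVLATTRSE", seq_len / 10), collapse = " ")
  lines <- c(
    sprintf("ID   %s                Reviewed;         %d AA.", entry_name, seq_len),
    sprintf("AC   %s;", accession),
    "DT   01-JAN-2020, integrated into UniProtKB/Swiss-Prot.",
    "DE   RecName: Full=Test protein;",
    gn_line,
    "OS   Homo sapiens (Human).",
    sprintf("OX   NCBI_TaxID=%d;", taxon))
  if (!is.null(isoforms)) {
    lines <- c(lines,
               "CC   -!- ALTERNATIVE PRODUCTS:",
               sprintf("CC       Event=%s; Named isoforms=%s;",
                       isoforms[["event"]], isoforms[["n"]]),
               "CC       Name=1;",
               sprintf("CC         IsoId=%s-1; Sequence=Displayed;", accession),
               "CC   -!- FUNCTION: A test protein.")
  }
  lines <- c(lines, ft_lines,
             sq_line %||%
               sprintf("SQ   SEQUENCE   %d AA;  6600 MW;  ABCDEF0123456789 CRC64;", seq_len),
             paste0("     ", seqc),
             "//")
  paste(lines, collapse = "\n")
}

ft_feature <- function(key, begin, end = begin, note = NULL) {
  pos <- if (begin == end) as.character(begin) else sprintf("%d..%d", begin, end)
  out <- sprintf("FT   %-15s %s", key, pos)
  if (!is.null(note)) {
    out <- c(out, sprintf("FT                   /note=\"%s\"", note))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force overlap count: double loop over groups x aging accessions.
# Independent of count_orthogroup_overlap's vectorised path.
brute_force_overlap <- function(table, accessions, human_label, target) {
  n <- 0L
  for (id in names(table$groups)) {
    g <- table$groups[[id]]
    has_aging <- FALSE
    for (acc in accessions) {
      if (acc %in% g[[human_label]]) has_aging <- TRUE
    }
    if (has_aging && length(g[[target]]) > 0) n <- n + 1L
  }
  n
}

# Random toy orthogroup table for property tests.
random_orthogroup_table <- function(n_groups, species = c("human", "mouse", "fly")) {
  groups <- lapply(seq_len(n_groups), function(i) {
    setNames(lapply(species, function(sp) {
      k <- sample(0:3, 1)
      if (k == 0) character() else sprintf("%s_p%d", sp, sample.int(50, k))
    }), species)
  })
  names(groups) <- sprintf("OG%04d", seq_len(n_groups))
  structure(list(species_order = species, groups = groups),
            class = "orthogroup_table")
}
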