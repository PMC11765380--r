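# Swiss-Prot flat-file (DAT) parsing.
#
# Only the line types that feed the width models are interpreted:
# ID, AC, OX (NCBI_TaxID), GN, CC -!- ALTERNATIVE PRODUCTS, FT, SQ and
# the "//" terminator. Everything else is carried past. Feature
# coordinates are 1-based inclusive, as in the flat file.

# Feature keys recognised by the pipeline; everything else in FT is ignored.
VARIANT_KEYS <- c("VARIANT", "VAR_SEQ")
PTM_FEATURE_KEYS <- c("MOD_RES", "CARBOHYD", "LIPID", "CROSSLNK", "DISULFID")

#' Default PTM feature keys
#'
#' Modification-site feature keys counted as post-translational
#' modifications by default: `MOD_RES`, `CARBOHYD`, `LIPID`, `CROSSLNK`.
#' `DISULFID` is recognised but excluded by default — disulfide bonds are
#' structural rather than chemical proteoform-generating events in most
#' treatments — and can be opted in via the `ptm_keys` argument of
#' [entry_feature_counts()] and [aggregate_gene_counts()].
#'
#' @return character vector of feature keys.
#' @export
default_ptm_keys <- function() c("MOD_RES", "CARBOHYD", "LIPID", "CROSSLNK")

#' Read UniProtKB/Swiss-Prot flat-file (DAT) records
#'
#' Parses reviewed Swiss-Prot entries from a flat file (optionally
#' gzip-compressed) or from in-memory text. One record is produced per
#' entry, in file order. Unknown line types are ignored. An entry missing
#' any of its mandatory ID, AC or SQ lines is skipped with a warning that
#' names the line where the entry starts; parsing continues and the
#' number of skipped entries is available as `attr(x, "n_malformed")`.
#'
#' @param file path to a DAT file; `.gz` input is decompressed
#'   transparently. Ignored when `text` is given.
#' @param text character vector of DAT lines (or a single string with
#'   embedded newlines), as produced by [simulate_proteome()] or
#'   [write_swissprot()].
#' @return an object of class `swissprot_records`: a list of
#'   `swissprot_entry` records. Each record holds `primary_accession`,
#'   `secondary_accessions`, `entry_name`, `taxon_id`, `gene_name` (`NA`
#'   if the entry has no GN line), `gene_name_source` (one of `"Name"`,
#'   `"OrderedLocusNames"`, `"ORFNames"`, `"accession_fallback"`),
#'   `declared_isoform_count` (from the ALTERNATIVE PRODUCTS block, 0 if
#'   absent), `alternative_splicing_event` (logical), `features` (a
#'   data.frame with columns `key`, `begin`, `end`, `description`),
#'   `sequence_length` and `sequence`.
#' @seealso [entry_feature_counts()], [aggregate_gene_counts()],
#'   [write_swissprot()]
#' @examples
#' sim <- simulate_proteome(n_genes = 3, seed = 1)
#' recs <- read_swissprot(text = sim$dat)
#' recs
#' @export
read_swissprot <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    con <- gzfile(file, open = "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines)) {
    probe <- paste(head(lines, 50), collapse = "")
    bad <- gregexpr("[\x01-\x08\x0B\x0C\x0E-\x1F]", probe, useBytes = TRUE)[[1]]
    n_bad <- if (bad[1] == -1L) 0L else length(bad)
    if (n_bad > nchar(probe, type = "bytes") / 20) {
      stop("input does not look like Swiss-Prot flat-file text")
    }
  }

  term <- which(lines == "//")
  starts <- c(1L, head(term, -1L) + 1L)
  entries <- vector("list", length(term))
  n_malformed <- 0L
  for (k in seq_along(term)) {
    block <- lines[seq.int(starts[k], term[k] - 1L)]
    rec <- tryCatch(parse_entry_block(block, starts[k]),
                    sp_malformed = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(rec)) n_malformed <- n_malformed + 1L
    entries[[k]] <- rec
  }
  entries <- entries[!vapply(entries, is.null, logical(1))]
  structure(entries, class = "swissprot_records", n_malformed = n_malformed)
}

malformed <- function(first_line, what) {
  cond <- structure(
    class = c("sp_malformed", "error", "condition"),
    list(message = sprintf("entry starting at line %d: %s; entry skipped",
                           first_line, what),
         call = NULL))
  stop(cond)
}

parse_entry_block <- function(block, first_line) {
  id_line <- block[startsWith(block, "ID   ")]
  if (!length(id_line)) malformed(first_line, "missing ID line")
  ac_lines <- block[startsWith(block, "AC   ")]
  if (!length(ac_lines)) malformed(first_line, "missing AC line")
  sq_line <- block[startsWith(block, "SQ   ")]
  if (!length(sq_line)) malformed(first_line, "missing SQ line")

  entry_name <- sub("^ID\\s+(\\S+).*", "\\1", id_line[1])
  acc <- unlist(strsplit(sub("^AC   ", "", paste(ac_lines, collapse = " ")),
                         ";\\s*"))
  acc <- acc[nzchar(acc)]

  m <- regmatches(sq_line[1],
                  regexec("^SQ\\s+SEQUENCE\\s+(\\d+)\\s+AA", sq_line[1]))[[1]]
  if (length(m) < 2) malformed(first_line, "unparseable SQ line")
  seq_len <- as.integer(m[2])

  sq_at <- which(startsWith(block, "SQ   "))[1]
  seq_lines <- if (sq_at < length(block)) block[(sq_at + 1L):length(block)] else character()
  sequence <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))

  ox_line <- block[startsWith(block, "OX   ")]
  taxon_id <- NA_integer_
  if (length(ox_line)) {
    mt <- regmatches(ox_line[1], regexec("NCBI_TaxID=(\\d+)", ox_line[1]))[[1]]
    if (length(mt) == 2) taxon_id <- as.integer(mt[2])
  }

  gn <- parse_gn(block[startsWith(block, "GN   ")])
  if (is.na(gn$name)) {
    gn$name <- NA_character_
    gn$source <- "accession_fallback"
  }

  alt <- parse_alternative_products(block)
  feats <- parse_features(block)

  structure(list(
    primary_accession = acc[1],
    secondary_accessions = if (length(acc) > 1) acc[-1] else character(),
    entry_name = entry_name,
    taxon_id = taxon_id,
    gene_name = gn$name,
    gene_name_source = gn$source,
    declared_isoform_count = alt$n_isoforms,
    alternative_splicing_event = alt$as_event,
    features = feats,
    sequence_length = seq_len,
    sequence = sequence
  ), class = "swissprot_entry")
}

# GN content, e.g. "Name=Trp53; Synonyms=P53; OrderedLocusNames=b0001;".
# Evidence tags {ECO:...} are stripped; precedence Name > OrderedLocusNames
# > ORFNames; the first name of a comma-separated list is taken.
parse_gn <- function(gn_lines) {
  if (!length(gn_lines)) {
    return(list(name = NA_character_, source = "accession_fallback"))
  }
  txt <- paste(sub("^GN   ", "", gn_lines), collapse = " ")
  txt <- gsub("\\{[^}]*\\}", "", txt)
  pick <- function(field) {
    m <- regmatches(txt, regexec(paste0(field, "=([^;]+);?"), txt))[[1]]
    if (length(m) < 2) return(NA_character_)
    val <- trimws(strsplit(m[2], ",")[[1]][1])
    if (nzchar(val)) val else NA_character_
  }
  for (field in c("Name", "OrderedLocusNames", "ORFNames")) {
    val <- pick(field)
    if (!is.na(val)) return(list(name = val, source = field))
  }
  list(name = NA_character_, source = "accession_fallback")
}

parse_alternative_products <- function(block) {
  start <- which(startsWith(block, "CC   -!- ALTERNATIVE PRODUCTS:"))
  if (!length(start)) return(list(n_isoforms = 0L, as_event = FALSE))
  start <- start[1]
  rest <- block[seq.int(start + 1L, length(block))]
  in_cc <- startsWith(rest, "CC       ")  # continuation lines of the block
  stop_at <- which(!in_cc)
  body <- if (length(stop_at)) rest[seq_len(stop_at[1] - 1L)] else rest
  txt <- paste(sub("^CC\\s+", "", body), collapse = " ")
  n <- 0L
  m <- regmatches(txt, regexec("Named isoforms=(\\d+)", txt))[[1]]
  if (length(m) == 2) n <- as.integer(m[2])
  ev <- regmatches(txt, regexec("Event=([^;]+);", txt))[[1]]
  as_event <- length(ev) == 2 && grepl("Alternative splicing", ev[2], fixed = TRUE)
  list(n_isoforms = n, as_event = as_event)
}

# FT lines, current UniProt layout: a key line has the feature key in
# column 6 ("FT   VARIANT         10" or "FT   MOD_RES   10..12");
# qualifier/continuation lines are indented past column 6.
parse_features <- function(block) {
  ft <- block[startsWith(block, "FT ")]
  empty <- data.frame(key = character(), begin = integer(), end = integer(),
                      description = character(), stringsAsFactors = FALSE)
  if (!length(ft)) return(empty)
  is_key <- substr(ft, 6, 6) != " " & nzchar(trimws(substr(ft, 6, 6)))
  idx <- which(is_key)
  if (!length(idx)) return(empty)
  keys <- character(length(idx)); begins <- integer(length(idx))
  ends <- integer(length(idx)); descs <- character(length(idx))
  bounds <- c(idx, length(ft) + 1L)
  for (i in seq_along(idx)) {
    line <- ft[idx[i]]
    keys[i] <- sub("^FT\\s+(\\S+).*", "\\1", line)
    pos <- sub("^FT\\s+\\S+\\s+(\\S+).*", "\\1", line)
    pos <- gsub("[<>?]", "", pos)
    parts <- strsplit(pos, "..", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    begins[i] <- if (length(parts)) suppressWarnings(as.integer(parts[1])) else NA_integer_
    ends[i] <- if (length(parts)) suppressWarnings(as.integer(parts[length(parts)])) else NA_integer_
    lo <- idx[i] + 1L
    hi <- bounds[i + 1L] - 1L
    descs[i] <- extract_note(if (lo <= hi) ft[lo:hi] else character())
  }
  keep <- keys %in% c(VARIANT_KEYS, PTM_FEATURE_KEYS)
  data.frame(key = keys[keep], begin = begins[keep], end = ends[keep],
             description = descs[keep], stringsAsFactors = FALSE)
}

extract_note <- function(cont_lines) {
  if (!length(cont_lines)) return("")
  txt <- paste(trimws(sub("^FT\\s+", "", cont_lines)), collapse = " ")
  m <- regmatches(txt, regexec("/note=\"([^\"]*)\"", txt))[[1]]
  if (length(m) == 2) m[2] else ""
}

#' Serialize records back to Swiss-Prot flat-file text
#'
#' Emits a minimal, syntactically valid DAT rendering of parsed records
#' (ID, AC, GN, OX, ALTERNATIVE PRODUCTS, FT, SQ, sequence, `//`), such
#' that `read_swissprot(text = write_swissprot(x))` reproduces `x`'s
#' annotation content. Used by the synthetic generator and for
#' audit round trips.
#'
#' @param x a `swissprot_records` object.
#' @param file optional path; when given the text is also written there.
#' @return invisibly for a file, otherwise a single string of DAT text.
#' @export
write_swissprot <- function(x, file = NULL) {
  stopifnot(inherits(x, "swissprot_records"))
  out <- vapply(x, format_entry_dat, character(1))
  txt <- paste0(paste(out, collapse = ""), collapse = "")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

format_entry_dat <- function(e) {
  lines <- c(
    sprintf("ID   %-24s Reviewed; %15d AA.", e$entry_name, e$sequence_length),
    sprintf("AC   %s;", paste(c(e$primary_accession, e$secondary_accessions),
                              collapse = "; ")))
  if (!is.na(e$gene_name)) {
    field <- if (e$gene_name_source %in% c("Name", "OrderedLocusNames", "ORFNames"))
      e$gene_name_source else "Name"
    lines <- c(lines, sprintf("GN   %s=%s;", field, e$gene_name))
  }
  lines <- c(lines, "OS   Synthetic organism.",
             sprintf("OX   NCBI_TaxID=%d;", e$taxon_id))
  if (e$declared_isoform_count > 0 || e$alternative_splicing_event) {
    ev <- if (e$alternative_splicing_event) "Alternative splicing" else "Alternative initiation"
    lines <- c(lines,
               "CC   -!- ALTERNATIVE PRODUCTS:",
               sprintf("CC       Event=%s; Named isoforms=%d;", ev,
                       e$declared_isoform_count),
               "CC       Name=1;",
               sprintf("CC         IsoId=%s-1; Sequence=Displayed;",
                       e$primary_accession))
  }
  f <- e$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      pos <- if (is.na(f$end[i]) || f$begin[i] == f$end[i]) as.character(f$begin[i])
             else sprintf("%d..%d", f$begin[i], f$end[i])
      lines <- c(lines, sprintf("FT   %-15s %s", f$key[i], pos))
      if (nzchar(f$description[i])) {
        lines <- c(lines, sprintf("FT                   /note=\"%s\"",
                                  f$description[i]))
      }
    }
  }
  lines <- c(lines,
             sprintf("SQ   SEQUENCE   %d AA;  %d MW;  0000000000000000 CRC64;",
                     e$sequence_length, e$sequence_length * 110L))
  seqc <- e$sequence
  if (nzchar(seqc)) {
    chunks <- substring(seqc, seq(1, nchar(seqc), 60), pmin(seq(60, nchar(seqc) + 59, 60), nchar(seqc)))
    grouped <- vapply(chunks, function(ch) {
      paste(substring(ch, seq(1, nchar(ch), 10), pmin(seq(10, nchar(ch) + 9, 10), nchar(ch))),
            collapse = " ")
    }, character(1))
    lines <- c(lines, paste0("     ", grouped))
  }
  paste0(paste(lines, collapse = "\n"), "\n//\n")
}

#' @export
print.swissprot_records <- function(x, ...) {
  cat(sprintf("Swiss-Prot records: %d entries", length(x)))
  nm <- attr(x, "n_malformed")
  if (!is.null(nm) && nm > 0) cat(sprintf(" (%d malformed entries skipped)", nm))
  cat("\n")
  if (length(x)) {
    taxa <- unique(vapply(x, `[[`, integer(1), "taxon_id"))
    cat(sprintf("  taxa: %s\n", paste(taxa, collapse = ", ")))
    cat(sprintf("  first entry: %s (%s)\n", x[[1]]$primary_accession,
                x[[1]]$entry_name))
  }
  invisible(x)
}

#' @export
print.swissprot_entry <- function(x, ...) {
  cat(sprintf("<%s> %s  taxon %s  gene %s [%s]\n", x$entry_name,
              x$primary_accession, x$taxon_id,
              ifelse(is.na(x$gene_name), "-", x$gene_name),
              x$gene_name_source))
  cat(sprintf("  length %d aa; %d named isoforms%s; %d features\n",
              x$sequence_length, x$declared_isoform_count,
              if (x$alternative_splicing_event) " (alternative splicing)" else "",
              nrow(x$features)))
  invisible(x)
}

#' Count proteoform-generating features of one entry
#'
#' Reduces a parsed entry to the three event counts the width models
#' consume: splice-variant sequences, single-amino-acid-polymorphism
#' (SAP) sequences, and PTM-bearing sequences. Splice variants come from
#' the declared named-isoform count and contribute only when the entry's
#' ALTERNATIVE PRODUCTS event is alternative splicing; SAPs are `VARIANT`
#' features; PTMs are modification features with one counted sequence
#' variant per annotated site.
#'
#' @param entry a `swissprot_entry`.
#' @param ptm_keys feature keys counted as PTMs; a subset of
#'   `MOD_RES`, `CARBOHYD`, `LIPID`, `CROSSLNK`, `DISULFID`. See
#'   [default_ptm_keys()].
#' @param isoform_convention `"all_named"` counts every named isoform as
#'   a splice-variant sequence (so a spliced gene contributes at least
#'   2); `"non_canonical"` counts named isoforms minus the canonical one.
#' @return named integer vector `c(as_sequences, sap_sequences,
#'   ptm_sequences)`.
#' @examples
#' sim <- simulate_proteome(n_genes = 2, seed = 7)
#' recs <- read_swissprot(text = sim$dat)
#' entry_feature_counts(recs[[1]])
#' @export
entry_feature_counts <- function(entry,
                                 ptm_keys = default_ptm_keys(),
                                 isoform_convention = c("all_named", "non_canonical")) {
  isoform_convention <- match.arg(isoform_convention)
  bad <- setdiff(ptm_keys, PTM_FEATURE_KEYS)
  if (length(bad)) {
    stop("unknown PTM feature key(s): ", paste(bad, collapse = ", "))
  }
  as_seq <- if (entry$alternative_splicing_event) {
    if (isoform_convention == "all_named") entry$declared_isoform_count
    else max(entry$declared_isoform_count - 1L, 0L)
  } else 0L
  sap_seq <- sum(entry$features$key == "VARIANT")
  ptm_seq <- sum(entry$features$key %in% ptm_keys)
  c(as_sequences = as.integer(as_seq), sap_sequences = as.integer(sap_seq),
    ptm_sequences = as.integer(ptm_seq))
}

#' Resolve the gene key of an entry
#'
#' Entries are grouped into genes by (NCBI taxon, gene label). The label
#' is the entry's gene name upper-cased; entries without any GN line are
#' keyed by their primary accession, so each becomes a singleton gene
#' rather than silently deflating the gene count.
#'
#' @param entry a `swissprot_entry`.
#' @return list with `taxon_id`, `gene` (upper-cased label) and `source`.
#' @export
resolve_gene_key <- function(entry) {
  if (is.na(entry$gene_name)) {
    list(taxon_id = entry$taxon_id, gene = entry$primary_accession,
         source = "accession_fallback")
  } else {
    list(taxon_id = entry$taxon_id, gene = toupper(entry$gene_name),
         source = entry$gene_name_source)
  }
}

#' Per-entry feature-count table
#'
#' One row per entry, in file order, with the resolved gene key and the
#' three event counts — the audit view behind [aggregate_gene_counts()].
#'
#' @inheritParams entry_feature_counts
#' @param records a `swissprot_records` object.
#' @return data.frame with columns `accession`, `entry_name`, `taxon_id`,
#'   `gene`, `gene_name_source`, `declared_isoforms`, `as_sequences`,
#'   `sap_sequences`, `ptm_sequences`, `sequence_length`.
#' @export
feature_count_table <- function(records,
                                ptm_keys = default_ptm_keys(),
                                isoform_convention = c("all_named", "non_canonical")) {
  isoform_convention <- match.arg(isoform_convention)
  rows <- lapply(records, function(e) {
    k <- resolve_gene_key(e)
    cnt <- entry_feature_counts(e, ptm_keys, isoform_convention)
    data.frame(accession = e$primary_accession, entry_name = e$entry_name,
               taxon_id = e$taxon_id, gene = k$gene,
               gene_name_source = k$source,
               declared_isoforms = e$declared_isoform_count,
               as_sequences = cnt[["as_sequences"]],
               sap_sequences = cnt[["sap_sequences"]],
               ptm_sequences = cnt[["ptm_sequences"]],
               sequence_length = e$sequence_length,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(accession = character(), entry_name = character(),
                      taxon_id = integer(), gene = character(),
                      gene_name_source = character(),
                      declared_isoforms = integer(), as_sequences = integer(),
                      sap_sequences = integer(), ptm_sequences = integer(),
                      sequence_length = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write the per-entry audit TSV
#'
#' @inheritParams feature_count_table
#' @param file output path.
#' @return the audit data.frame, invisibly.
#' @export
write_entry_audit <- function(records, file,
                              ptm_keys = default_ptm_keys(),
                              isoform_convention = c("all_named", "non_canonical")) {
  tab <- feature_count_table(records, ptm_keys, isoform_convention)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
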