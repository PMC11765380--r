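# Orthogroup tables, the aging-gene overlap statistic, and a
# reciprocal-best-hit (RBH) orthogroup inferrer.
#
# The overlap statistic counts, for a target species, the orthogroups
# that contain at least one mapped human aging protein AND at least one
# protein of the target species. Orthogroup tables use the OrthoFinder
# Orthogroups.tsv dialect: first column = orthogroup id, one column per
# species, cells are comma-separated protein identifiers.

#' Read an orthogroups table (OrthoFinder Orthogroups.tsv dialect)
#'
#' @param file path to a tab-separated file whose first column is the
#'   orthogroup id and whose remaining columns are species; cells hold
#'   comma-separated protein identifiers and may be empty.
#' @return object of class `orthogroup_table`: a list with
#'   `species_order` (character) and `groups` (named list: orthogroup id
#'   -> named list of per-species character vectors).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\thuman\tmouse",
#'              "OG1\th1, h2\tm1", "OG2\th3\t"), f)
#' read_orthogroups(f)
#' @export
read_orthogroups <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) stop("empty orthogroups file (no header)")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 1) stop("malformed header")
  species <- header[-1]
  ncol <- length(header)
  groups <- vector("list", length(cells) - 1L)
  ids <- character(length(groups))
  for (i in seq_along(groups)) {
    row <- cells[[i + 1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ncol) row <- c(row, rep("", ncol - length(row)))
    if (length(row) != ncol) {
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   i + 1L, length(row), ncol))
    }
    ids[i] <- row[1]
    members <- lapply(row[-1], split_protein_cell)
    names(members) <- species
    groups[[i]] <- members
  }
  if (anyDuplicated(ids)) {
    stop("duplicate orthogroup id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (i in seq_along(groups)) {
    for (sp in species) {
      v <- groups[[i]][[sp]]
      if (anyDuplicated(v)) {
        stop(sprintf("duplicate protein id within species '%s' in group %s",
                     sp, ids[i]))
      }
    }
  }
  names(groups) <- ids
  structure(list(species_order = species, groups = groups),
            class = "orthogroup_table")
}

split_protein_cell <- function(cell) {
  if (!nzchar(trimws(cell))) return(character())
  v <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

#' Write an orthogroups table in canonical form
#'
#' Cells are joined with `", "`; `write_orthogroups(read_orthogroups(f))`
#' is byte-identical to a canonicalized input file.
#'
#' @param x an `orthogroup_table`.
#' @param file output path; when `NULL` the lines are returned instead.
#' @return the output lines, invisibly when written to a file.
#' @export
write_orthogroups <- function(x, file = NULL) {
  stopifnot(inherits(x, "orthogroup_table"))
  header <- paste(c("Orthogroup", x$species_order), collapse = "\t")
  rows <- vapply(names(x$groups), function(id) {
    cells <- vapply(x$species_order, function(sp) {
      paste(x$groups[[id]][[sp]], collapse = ", ")
    }, character(1))
    paste(c(id, cells), collapse = "\t")
  }, character(1))
  out <- c(header, rows)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("Orthogroup table: %d groups x %d species (%s)\n",
              length(x$groups), length(x$species_order),
              paste(x$species_order, collapse = ", ")))
  invisible(x)
}

#' Map aging-gene symbols to protein accessions
#'
#' Orthogroup tables list protein identifiers, while aging-gene lists
#' carry gene symbols; this joins them through a symbol-to-accession
#' mapping. Matching is case-insensitive on the symbol; a symbol may map
#' to several accessions. Unmapped symbols are reported, not fatal.
#'
#' @param symbols character vector of gene symbols (one per gene).
#' @param mapping data.frame with columns `symbol` and `accession`, or a
#'   path to a two-column TSV with that header.
#' @return object of class `aging_gene_set`: list with `symbols`
#'   (upper-cased, unique), `accessions` (unique mapped identifiers) and
#'   `unmapped` (symbols absent from the mapping).
#' @examples
#' map <- data.frame(symbol = c("TP53", "EGFR"),
#'                   accession = c("P04637", "P00533"))
#' map_aging_genes(c("tp53", "EGFR", "NOPE"), map)
#' @export
map_aging_genes <- function(symbols, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- read.delim(mapping, stringsAsFactors = FALSE)
  }
  if (!all(c("symbol", "accession") %in% names(mapping))) {
    stop("mapping must have columns 'symbol' and 'accession'")
  }
  symbols <- unique(toupper(trimws(symbols)))
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) && !nrow(mapping)) {
    stop("empty symbol-to-accession mapping for a nonempty symbol list")
  }
  map_sym <- toupper(trimws(mapping$symbol))
  hit <- map_sym %in% symbols
  accessions <- sort(unique(trimws(mapping$accession[hit])))
  unmapped <- sort(setdiff(symbols, map_sym))
  structure(list(symbols = symbols, accessions = accessions,
                 unmapped = unmapped),
            class = "aging_gene_set")
}

#' @export
print.aging_gene_set <- function(x, ...) {
  cat(sprintf("Aging gene set: %d symbols -> %d accessions (%d unmapped)\n",
              length(x$symbols), length(x$accessions), length(x$unmapped)))
  invisible(x)
}

#' Count orthogroups shared between human aging genes and a species
#'
#' An orthogroup is counted when its human cell contains at least one
#' accession of the aging set and its target-species cell is nonempty.
#' Counting the human column against itself gives the number of
#' orthogroups containing any aging accession.
#'
#' @param table an `orthogroup_table`.
#' @param aging an `aging_gene_set` (or a character vector of
#'   accessions).
#' @param human_label column name of the human proteome in `table`.
#' @param target column name of the target species.
#' @return object of class `overlap_count`: list with `species`,
#'   `n_orthogroups` and the sorted `orthogroup_ids`.
#' @examples
#' f <- tempfile(); writeLines(c("Orthogroup\thuman\tmouse",
#'   "OG1\th1\tm1", "OG2\th2\t", "OG3\th3\tm2"), f)
#' tab <- read_orthogroups(f)
#' count_orthogroup_overlap(tab, c("h1", "h2"), "human", "mouse")
#' @export
count_orthogroup_overlap <- function(table, aging, human_label, target) {
  stopifnot(inherits(table, "orthogroup_table"))
  for (lab in c(human_label, target)) {
    if (!lab %in% table$species_order) {
      stop("unknown species label: ", lab)
    }
  }
  acc <- if (inherits(aging, "aging_gene_set")) aging$accessions else aging
  hit <- vapply(table$groups, function(g) {
    length(g[[target]]) > 0 && any(g[[human_label]] %in% acc)
  }, logical(1))
  ids <- sort(names(table$groups)[hit])
  structure(list(species = target, n_orthogroups = length(ids),
                 orthogroup_ids = ids),
            class = "overlap_count")
}

#' @export
print.overlap_count <- function(x, ...) {
  cat(sprintf("%s: %d orthogroup(s) contain human aging genes\n",
              x$species, x$n_orthogroups))
  invisible(x)
}

#' Overlap counts for every species of a table
#'
#' @inheritParams count_orthogroup_overlap
#' @param include_human whether to include the human column itself.
#' @return data.frame with columns `species` and `n_orthogroups`, sorted
#'   by decreasing count then species label.
#' @export
overlap_table <- function(table, aging, human_label, include_human = FALSE) {
  targets <- table$species_order
  if (!include_human) targets <- setdiff(targets, human_label)
  rows <- lapply(targets, function(sp) {
    oc <- count_orthogroup_overlap(table, aging, human_label, sp)
    data.frame(species = sp, n_orthogroups = oc$n_orthogroups,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), n_orthogroups = integer())
  out <- out[order(-out$n_orthogroups, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- alignment -------------------------------------------------------------

blosum_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global alignment score (Needleman-Wunsch, affine gaps)
#'
#' Scores the optimal global alignment of two protein sequences under a
#' substitution matrix and affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend` (the first gap residue costs
#' `gap_open + gap_extend`). This is the similarity measure behind the
#' reciprocal-best-hit orthogroup inferrer.
#'
#' @param a,b protein sequences over the 20 standard amino-acid letters.
#' @param matrix substitution matrix name from Biostrings (default
#'   `"BLOSUM62"`), or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend nonnegative gap penalties (defaults 10, 1).
#' @return integer alignment score.
#' @examples
#' nw_align_score("ACD", "ACD")  # 19
#' nw_align_score("A", "D")      # -2
#' @export
nw_align_score <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 1) {
  sm <- if (is.character(matrix)) blosum_matrix(matrix) else matrix
  ai <- encode_aa(a, "a")
  bi <- encode_aa(b, "b")
  n <- length(ai); m <- length(bi)
  ge <- gap_extend; go <- gap_open
  if (n == 0 && m == 0) return(0L)
  if (n == 0) return(as.integer(-(go + m * ge)))
  if (m == 0) return(as.integer(-(go + n * ge)))
  sub <- sm[AA_ALPHABET20, AA_ALPHABET20, drop = FALSE]
  NEG <- -1e9
  # Gotoh recursion, row by row. H = best, E = gap in `a` (consuming b),
  # F = gap in `b` (consuming a).
  Hprev <- c(0, -(go + (1:m) * ge))
  Fprev <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    srow <- sub[ai[i], bi]
    H <- numeric(m + 1)
    H[1] <- -(go + i * ge)
    Fcur <- numeric(m + 1)
    Fcur[1] <- NEG
    Fcur[-1] <- pmax(Hprev[-1] - go - ge, Fprev[-1] - ge)
    e <- NEG
    for (j in seq_len(m)) {
      e <- max(H[j] - go - ge, e - ge)
      H[j + 1] <- max(Hprev[j] + srow[j], e, Fcur[j + 1])
    }
    Hprev <- H
    Fprev <- Fcur
  }
  as.integer(Hprev[m + 1])
}

encode_aa <- function(s, label) {
  if (length(s) != 1 || !is.character(s)) stop("sequence must be one string")
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% AA_ALPHABET20))
  if (length(bad)) {
    stop(sprintf("illegal amino-acid character '%s' at position %d of sequence %s",
                 ch[bad[1]], bad[1], label))
  }
  ch
}

#' Infer orthogroups by reciprocal best hits
#'
#' A deliberately simple orthogroup builder for self-contained analyses:
#' for every ordered species pair, each query protein's best hit is the
#' target protein maximizing the global alignment score (ties broken by
#' the lexicographically smallest target identifier); pairs that are each
#' other's best hits form edges; orthogroups are the connected components
#' with at least two proteins. Singleton proteins are excluded. This is a
#' classical heuristic, far simpler than graph-clustering orthology
#' pipelines, and is intended for small planted scenarios, not
#' whole-proteome inference.
#'
#' @param proteomes named list: species label -> named character vector
#'   of protein sequences (names are protein identifiers), or a named
#'   character vector of FASTA file paths.
#' @param matrix,gap_open,gap_extend alignment scoring, as in
#'   [nw_align_score()].
#' @return an `orthogroup_table`; group ids are `OG000001, ...` assigned
#'   in order of each component's smallest protein id.
#' @examples
#' prot <- list(sp1 = c(a1 = "MKVLATTR"), sp2 = c(b1 = "MKVLATTR"))
#' infer_orthogroups_rbh(prot)
#' @export
infer_orthogroups_rbh <- function(proteomes, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 1) {
  proteomes <- load_proteomes(proteomes)
  species <- names(proteomes)
  if (is.null(species) || any(!nzchar(species))) {
    stop("proteomes must be a named list of species")
  }
  for (sp in species) {
    ids <- names(proteomes[[sp]])
    if (is.null(ids) || anyDuplicated(ids)) {
      stop("duplicate or missing protein ids within species ", sp)
    }
    if (any(!nzchar(proteomes[[sp]]))) stop("empty sequence in species ", sp)
  }
  empty <- structure(list(species_order = species,
                          groups = setNames(list(), character())),
                     class = "orthogroup_table")
  if (length(species) < 2) return(empty)

  sm <- if (is.character(matrix)) blosum_matrix(matrix) else matrix
  node <- function(sp, id) paste(sp, id, sep = "\r")
  # pairwise score cache (symmetric)
  edges_a <- character(); edges_b <- character()
  for (si in seq_along(species)) for (sj in seq_along(species)) {
    if (sj <= si) next
    A <- proteomes[[species[si]]]; B <- proteomes[[species[sj]]]
    scores <- matrix(NA_real_, length(A), length(B),
                     dimnames = list(names(A), names(B)))
    for (qi in seq_along(A)) for (ti in seq_along(B)) {
      scores[qi, ti] <- nw_align_score(A[[qi]], B[[ti]], matrix = sm,
                                       gap_open = gap_open,
                                       gap_extend = gap_extend)
    }
    best_hit <- function(v, ids) ids[order(-v, ids)][1]  # lexicographic tie-break
    best_ab <- vapply(seq_along(A), function(q)
      best_hit(scores[q, ], colnames(scores)), character(1))
    best_ba <- vapply(seq_along(B), function(t)
      best_hit(scores[, t], rownames(scores)), character(1))
    names(best_ab) <- rownames(scores)
    names(best_ba) <- colnames(scores)
    for (q in names(best_ab)) {
      t <- best_ab[[q]]
      if (identical(best_ba[[t]], q)) {
        edges_a <- c(edges_a, node(species[si], q))
        edges_b <- c(edges_b, node(species[sj], t))
      }
    }
  }
  if (!length(edges_a)) return(empty)

  # connected components via union-find over RBH edges
  nodes <- unique(c(edges_a, edges_b))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_along(edges_a)) {
    ra <- find(match(edges_a[k], nodes))
    rb <- find(match(edges_b[k], nodes))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comps <- split(nodes, roots)
  comps <- comps[order(vapply(comps, min, character(1)))]

  groups <- lapply(comps, function(members) {
    parts <- strsplit(members, "\r", fixed = TRUE)
    sp_of <- vapply(parts, `[[`, character(1), 1)
    id_of <- vapply(parts, `[[`, character(1), 2)
    setNames(lapply(species, function(sp) sort(id_of[sp_of == sp])), species)
  })
  names(groups) <- sprintf("OG%06d", seq_along(groups))
  structure(list(species_order = species, groups = groups),
            class = "orthogroup_table")
}

load_proteomes <- function(proteomes) {
  if (is.character(proteomes)) {
    out <- lapply(proteomes, function(path) {
      ss <- Biostrings::readAAStringSet(path)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    })
    names(out) <- names(proteomes)
    return(out)
  }
  proteomes
}
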