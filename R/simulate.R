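# Seeded generators of synthetic Swiss-Prot records and ortholog
# families, each emitting its own planted ground truth so that every
# pipeline stage can be validated exactly.
#
# Planting is deterministic: the number of genes affected by each event
# class is round(fraction * n_genes) and every affected gene receives
# exactly the stated number of events. Which genes are affected, feature
# positions and residues are drawn from the seeded RNG, so recovery
# tests are exact rather than statistical while files still vary with
# the seed.

#' Generate a synthetic Swiss-Prot proteome with planted truth
#'
#' Emits syntactically valid Swiss-Prot DAT text (one reviewed entry per
#' gene) in which `round(as_gene_fraction * n_genes)` genes declare
#' `as_per_gene` named isoforms under an alternative-splicing event,
#' `round(sap_gene_fraction * n_genes)` genes carry `sap_per_gene`
#' `VARIANT` features, and `round(ptm_gene_fraction * n_genes)` genes
#' carry `ptm_per_gene` modification features (cycled over the default
#' PTM keys). The same call returns the planted 13-parameter vector,
#' computed directly from the planting arithmetic, and a per-entry truth
#' table. Identical seeds give byte-identical output.
#'
#' Default fractions and per-gene event counts are of the order observed
#' in well-annotated mammalian proteomes (roughly half the genes spliced
#' or variant-bearing, a majority carrying modification sites, a few
#' events per affected gene).
#'
#' @param n_genes number of genes (one entry each); 0 gives an empty
#'   file and a `NULL` parameter vector (N undefined).
#' @param as_gene_fraction,sap_gene_fraction,ptm_gene_fraction fractions
#'   of genes affected by each event class, in \[0, 1\].
#' @param as_per_gene named isoforms declared per spliced gene (>= 1).
#' @param sap_per_gene,ptm_per_gene features per affected gene (>= 1).
#' @param taxon_id NCBI taxon id stamped on every entry.
#' @param seed integer seed; required, so all output is reproducible.
#' @return object of class `synthetic_proteome`: list with `dat` (one
#'   string of DAT text), `parameters` (planted `proteome_parameters`),
#'   `truth` (per-entry data.frame: `accession`, `gene`, `as_sequences`,
#'   `sap_sequences`, `ptm_sequences`), and `spec` (the arguments).
#' @examples
#' sim <- simulate_proteome(n_genes = 10, seed = 42)
#' sim$parameters
#' @export
simulate_proteome <- function(n_genes,
                              as_gene_fraction = 0.4,
                              sap_gene_fraction = 0.5,
                              ptm_gene_fraction = 0.6,
                              as_per_gene = 3,
                              sap_per_gene = 4,
                              ptm_per_gene = 5,
                              taxon_id = 9606,
                              seed) {
  fr <- c(as_gene_fraction, sap_gene_fraction, ptm_gene_fraction)
  if (any(fr < 0 | fr > 1)) stop("gene fractions must lie in [0, 1]")
  if (any(c(as_per_gene, sap_per_gene, ptm_per_gene) < 1)) {
    stop("per-gene event counts must be positive integers")
  }
  if (missing(seed)) stop("a seed is required")
  spec <- list(n_genes = n_genes, as_gene_fraction = as_gene_fraction,
               sap_gene_fraction = sap_gene_fraction,
               ptm_gene_fraction = ptm_gene_fraction,
               as_per_gene = as_per_gene, sap_per_gene = sap_per_gene,
               ptm_per_gene = ptm_per_gene, taxon_id = taxon_id, seed = seed)
  if (n_genes == 0) {
    return(structure(list(dat = "", parameters = NULL,
                          truth = data.frame(accession = character(),
                                             gene = character(),
                                             as_sequences = integer(),
                                             sap_sequences = integer(),
                                             ptm_sequences = integer()),
                          spec = spec),
                     class = "synthetic_proteome"))
  }

  n_as <- round(as_gene_fraction * n_genes)
  n_sap <- round(sap_gene_fraction * n_genes)
  n_ptm <- round(ptm_gene_fraction * n_genes)

  entries <- with_seed(seed, {
    as_genes <- sort(sample.int(n_genes, n_as))
    sap_genes <- sort(sample.int(n_genes, n_sap))
    ptm_genes <- sort(sample.int(n_genes, n_ptm))
    lapply(seq_len(n_genes), function(i) {
      len <- sample(80:200, 1)
      seqc <- paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
      is_as <- i %in% as_genes
      feats <- data.frame(key = character(), begin = integer(),
                          end = integer(), description = character(),
                          stringsAsFactors = FALSE)
      if (i %in% sap_genes) {
        pos <- sort(sample.int(len, sap_per_gene))
        feats <- rbind(feats, data.frame(
          key = "VARIANT", begin = pos, end = pos,
          description = sprintf("%s -> %s (in allele %d)",
                                sample(AA_ALPHABET20, sap_per_gene, TRUE),
                                sample(AA_ALPHABET20, sap_per_gene, TRUE),
                                seq_len(sap_per_gene)),
          stringsAsFactors = FALSE))
      }
      if (i %in% ptm_genes) {
        keys <- rep_len(default_ptm_keys(), ptm_per_gene)
        pos <- sort(sample.int(len, ptm_per_gene))
        feats <- rbind(feats, data.frame(
          key = keys, begin = pos, end = pos,
          description = "Synthetic modification site",
          stringsAsFactors = FALSE))
      }
      structure(list(
        primary_accession = sprintf("P%05d", i),
        secondary_accessions = character(),
        entry_name = sprintf("SYG%04d_SYNTH", i),
        taxon_id = as.integer(taxon_id),
        gene_name = sprintf("SYG%04d", i),
        gene_name_source = "Name",
        declared_isoform_count = if (is_as) as.integer(as_per_gene) else 0L,
        alternative_splicing_event = is_as,
        features = feats,
        sequence_length = len,
        sequence = seqc), class = "swissprot_entry")
    })
  })
  records <- structure(entries, class = "swissprot_records", n_malformed = 0L)

  # Planted truth from the planting arithmetic itself (independent of
  # the parser/aggregator under test).
  truth <- data.frame(
    accession = vapply(entries, `[[`, character(1), "primary_accession"),
    gene = vapply(entries, `[[`, character(1), "gene_name"),
    as_sequences = vapply(entries, function(e)
      if (e$alternative_splicing_event) e$declared_isoform_count else 0L,
      integer(1)),
    sap_sequences = vapply(entries, function(e)
      sum(e$features$key == "VARIANT"), integer(1)),
    ptm_sequences = vapply(entries, function(e)
      sum(e$features$key %in% default_ptm_keys()), integer(1)),
    stringsAsFactors = FALSE)
  planted <- parameter_vector(
    N = n_genes,
    ASg = n_as, AS = n_as * as_per_gene,
    SAPg = n_sap, SAP = n_sap * sap_per_gene,
    PTMg = n_ptm, PTM = n_ptm * ptm_per_gene)

  structure(list(dat = write_swissprot(records), parameters = planted,
                 truth = truth, spec = spec),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("Synthetic proteome: %d genes (seed %s)\n",
              x$spec$n_genes, x$spec$seed))
  if (!is.null(x$parameters)) print(x$parameters)
  invisible(x)
}

#' Generate multi-species ortholog families with planted truth
#'
#' Builds `n_families` protein families: each family descends from its
#' own random ancestor sequence, and every species carries
#' `family_size_per_species` members obtained by substituting a fraction
#' `1 - within_family_identity` of the ancestor's residues (so any two
#' family members share at least roughly `2 * within_family_identity - 1`
#' identity, while unrelated random sequences sit near background
#' identity, far below `between_family_identity`). The first species is
#' the human stand-in; a deterministic-size subset
#' (`round(aging_fraction * n_families)`) of families is marked as
#' aging-associated, with one gene symbol per family and a
#' symbol-to-accession mapping to the human members.
#'
#' @param n_species number of species (first one is human).
#' @param n_families number of planted families.
#' @param family_size_per_species members per species per family.
#' @param within_family_identity residue identity of each member to its
#'   family ancestor, in (0, 1\].
#' @param between_family_identity documented ceiling on cross-family
#'   identity; must be strictly below `within_family_identity`.
#' @param aging_fraction fraction of families whose human genes are
#'   aging-associated.
#' @param seq_length ancestor sequence length (amino acids).
#' @param seed integer seed; required.
#' @return list with `proteomes` (named list: species -> named sequence
#'   vector), `orthogroups` (planted `orthogroup_table`),
#'   `aging_symbols` (character), `mapping` (data.frame
#'   symbol/accession), `aging_families` (indices) and `species` labels.
#' @examples
#' scn <- simulate_ortholog_families(n_species = 2, n_families = 3,
#'                                   aging_fraction = 1/3, seed = 9)
#' scn$orthogroups
#' @export
simulate_ortholog_families <- function(n_species = 2,
                                       n_families = 4,
                                       family_size_per_species = 1,
                                       within_family_identity = 0.9,
                                       between_family_identity = 0.3,
                                       aging_fraction = 0.5,
                                       seq_length = 80,
                                       seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_species < 1 || n_families < 1) stop("need >= 1 species and family")
  if (within_family_identity <= between_family_identity) {
    stop("within_family_identity must exceed between_family_identity")
  }
  if (within_family_identity <= 0 || within_family_identity > 1) {
    stop("within_family_identity must lie in (0, 1]")
  }
  species <- c("human", if (n_species > 1) sprintf("species%02d", seq_len(n_species - 1)))
  n_mut <- round((1 - within_family_identity) * seq_length)

  out <- with_seed(seed, {
    ancestors <- replicate(n_families,
                           sample(AA_ALPHABET20, seq_length, replace = TRUE),
                           simplify = FALSE)
    proteomes <- setNames(vector("list", n_species), species)
    for (s in seq_len(n_species)) {
      seqs <- character(0)
      for (f in seq_len(n_families)) {
        for (m in seq_len(family_size_per_species)) {
          v <- ancestors[[f]]
          if (n_mut > 0) {
            at <- sample.int(seq_length, n_mut)
            v[at] <- vapply(v[at], function(orig)
              sample(setdiff(AA_ALPHABET20, orig), 1), character(1))
          }
          id <- sprintf("%s_F%02d_P%d", species[s], f, m)
          seqs[id] <- paste(v, collapse = "")
        }
      }
      proteomes[[s]] <- seqs
    }
    n_aging <- round(aging_fraction * n_families)
    aging_families <- sort(sample.int(n_families, n_aging))
    list(proteomes = proteomes, aging_families = aging_families)
  })

  groups <- lapply(seq_len(n_families), function(f) {
    setNames(lapply(species, function(sp) {
      sprintf("%s_F%02d_P%d", sp, f, seq_len(family_size_per_species))
    }), species)
  })
  names(groups) <- sprintf("OG%06d", seq_len(n_families))
  planted_table <- structure(
    list(species_order = species,
         groups = if (n_species > 1) groups else setNames(list(), character())),
    class = "orthogroup_table")

  aging_symbols <- sprintf("AGEF%02d", out$aging_families)
  mapping <- do.call(rbind, c(list(
    data.frame(symbol = character(), accession = character(),
               stringsAsFactors = FALSE)),
    lapply(seq_len(n_families), function(f) {
      data.frame(symbol = sprintf("AGEF%02d", f),
                 accession = sprintf("human_F%02d_P%d", f,
                                     seq_len(family_size_per_species)),
                 stringsAsFactors = FALSE)
    })))

  list(proteomes = out$proteomes, orthogroups = planted_table,
       aging_symbols = aging_symbols, mapping = mapping,
       aging_families = out$aging_families, species = species)
}

#' Write synthetic proteomes as FASTA files
#'
#' @param proteomes named list of named sequence vectors, as produced by
#'   [simulate_ortholog_families()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_proteome_fasta <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(proteomes), function(sp) {
    path <- file.path(dir, paste0(sp, ".fasta"))
    ss <- Biostrings::AAStringSet(proteomes[[sp]])
    Biostrings::writeXStringSet(ss, path, width = 60)
    path
  }, character(1))
  paths
}

#' Compare a recovered parameter vector with the planted one
#'
#' Field-by-field diff between two 13-parameter vectors on the same `N`
#' basis. The overall verdict passes only when every field matches
#' exactly.
#'
#' @param planted,recovered `proteome_parameters` objects.
#' @return object of class `recovery_report`: data.frame with columns
#'   `parameter`, `planted`, `recovered`, `delta`, `pass`, and attribute
#'   `pass` (logical overall verdict).
#' @examples
#' p <- parameter_vector(N = 10, ASg = 2, AS = 4)
#' recovery_report(p, p)
#' @export
recovery_report <- function(planted, recovered) {
  stopifnot(inherits(planted, "proteome_parameters"),
            inherits(recovered, "proteome_parameters"))
  if (planted$N != recovered$N) {
    warning("parameter vectors have different N bases")
  }
  fields <- names(unclass(planted))
  tab <- data.frame(
    parameter = fields,
    planted = unlist(unclass(planted))[fields],
    recovered = unlist(unclass(recovered))[fields],
    stringsAsFactors = FALSE)
  tab$delta <- tab$recovered - tab$planted
  tab$pass <- tab$delta == 0
  rownames(tab) <- NULL
  structure(tab, class = c("recovery_report", "data.frame"),
            pass = all(tab$pass))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s (%d/%d fields exact)\n",
              if (attr(x, "pass")) "PASS" else "FAIL",
              sum(x$pass), nrow(x)))
  if (!attr(x, "pass")) print.data.frame(x[!x$pass, ])
  invisible(x)
}
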