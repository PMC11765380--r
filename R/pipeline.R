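# End-to-end orchestration: parse per-species DAT files (or read a
# pre-extracted parameter table), compute annotation coverage, proteome
# widths and the aging-gene orthogroup overlap, and write the three
# reports plus a run log.

#' Read a pre-extracted proteome parameter table
#'
#' A TSV with one row per species and columns `species`, `taxon_id`,
#' `N`, `ASg`, `AS`, `SAPg`, `SAP`, `PTMg`, `PTM` — the alternative
#' input route when counts were extracted elsewhere.
#'
#' @param file path to the TSV.
#' @return data.frame with the columns above, checked for validity.
#' @export
read_parameter_table <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", "taxon_id", "N", "ASg", "AS", "SAPg", "SAP",
            "PTMg", "PTM")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("parameter table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Table of proteome widths for several species
#'
#' Evaluates the three width models for every row of a parameter table
#' and formats the comparative table: total width per model with the
#' per-gene ratio in parentheses.
#'
#' @param params data.frame as returned by [read_parameter_table()].
#' @param decimals decimal places of the per-gene ratios.
#' @return data.frame with columns `species`, `taxon_id`, `pcg`,
#'   `nps1`, `nps2`, `nps3`, `per_pcg_1..3` (rounded) and
#'   `nps1_printed..nps3_printed` (e.g. `"228,613 (11.2)"`).
#' @export
widths_table <- function(params, decimals = 1) {
  rows <- lapply(seq_len(nrow(params)), function(i) {
    r <- params[i, ]
    p <- parameter_vector(N = r$N, ASg = r$ASg, AS = r$AS, SAPg = r$SAPg,
                          SAP = r$SAP, PTMg = r$PTMg, PTM = r$PTM)
    w <- proteome_width(p)
    ratio <- per_pcg_ratio(w, decimals = decimals)
    printed <- sprintf("%s (%s)",
                       format(round_half_up(w$nps, 0), big.mark = ",",
                              scientific = FALSE, trim = TRUE),
                       formatC(ratio, format = "fg"))
    data.frame(species = r$species, taxon_id = r$taxon_id, pcg = r$N,
               nps1 = w$nps[["nps1"]], nps2 = w$nps[["nps2"]],
               nps3 = w$nps[["nps3"]],
               per_pcg_1 = ratio[["nps1"]], per_pcg_2 = ratio[["nps2"]],
               per_pcg_3 = ratio[["nps3"]],
               nps1_printed = printed[1], nps2_printed = printed[2],
               nps3_printed = printed[3],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), taxon_id = integer(), pcg = numeric(),
               nps1 = numeric(), nps2 = numeric(), nps3 = numeric(),
               per_pcg_1 = numeric(), per_pcg_2 = numeric(),
               per_pcg_3 = numeric(), nps1_printed = character(),
               nps2_printed = character(), nps3_printed = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates all stages and writes `coverage.tsv`, `widths.tsv`,
#' `overlap.tsv` and `run.log` to the output directory. Any stage error
#' aborts with a stage-tagged message and removes partial outputs.
#' Re-running with the same configuration and inputs yields
#' byte-identical reports.
#'
#' The configuration is a named list (or path to a YAML file) with:
#' \describe{
#'   \item{species}{list of per-species entries: `name`, `taxon_id`,
#'     `dat` (path to a Swiss-Prot DAT file), optional `n_override`.}
#'   \item{parameters}{alternatively, path of a pre-extracted parameter
#'     TSV (see [read_parameter_table()]); used when no `species` DATs
#'     are given.}
#'   \item{ensembl_counts}{path to a TSV with columns `species`,
#'     `taxon_id`, `genes_ensembl` for the coverage report (optional).}
#'   \item{aging_list}{path to a plain-text file, one gene symbol per
#'     line (optional; enables the overlap report).}
#'   \item{mapping}{path to a symbol→accession TSV (columns `symbol`,
#'     `accession`).}
#'   \item{orthogroups}{path to an Orthogroups.tsv; or}
#'   \item{proteome_dir}{directory of per-species FASTA files, from
#'     which orthogroups are inferred by reciprocal best hits.}
#'   \item{human_label}{species column holding the human proteins
#'     (default `"human"`).}
#'   \item{ptm_keys, isoform_convention}{counting conventions, see
#'     [entry_feature_counts()].}
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{integer recorded in the log (the pipeline itself is
#'     deterministic).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return invisibly, a list with elements `coverage`, `widths`,
#'   `overlap` (data.frames) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop_stage("config", "out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("coverage.tsv", "widths.tsv", "overlap.tsv", "run.log"))
  names(paths) <- c("coverage", "widths", "overlap", "log")
  for (p in c(config$parameters, config$ensembl_counts, config$aging_list,
              config$mapping, config$orthogroups,
              vapply(config$species %||% list(), `[[`, character(1), "dat"))) {
    if (!file.exists(p)) stop_stage("config", "input path missing: ", p)
  }
  on_error_cleanup <- function() suppressWarnings(file.remove(paths[file.exists(paths)]))
  log_lines <- c(sprintf("proteowidth pipeline"),
                 sprintf("seed: %s", config$seed %||% "none"))

  result <- tryCatch({
    ptm_keys <- config$ptm_keys %||% default_ptm_keys()
    convention <- config$isoform_convention %||% "all_named"

    ## ---- widths stage ----
    params <- if (!is.null(config$species) && length(config$species)) {
      rows <- lapply(config$species, function(sp) {
        recs <- read_swissprot(sp$dat)
        log_lines <<- c(log_lines,
                        sprintf("parsed %s: %d entries (%d malformed skipped)",
                                sp$name, length(recs),
                                attr(recs, "n_malformed") %||% 0L))
        genes <- aggregate_gene_counts(recs, ptm_keys = ptm_keys,
                                       isoform_convention = convention)
        p <- proteome_parameters(genes, n_override = sp$n_override)
        data.frame(species = sp$name, taxon_id = sp$taxon_id,
                   N = p$N, ASg = p$ASg, AS = p$AS, SAPg = p$SAPg,
                   SAP = p$SAP, PTMg = p$PTMg, PTM = p$PTM,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    } else if (!is.null(config$parameters)) {
      read_parameter_table(config$parameters)
    } else {
      data.frame(species = character(), taxon_id = integer(), N = numeric(),
                 ASg = numeric(), AS = numeric(), SAPg = numeric(),
                 SAP = numeric(), PTMg = numeric(), PTM = numeric(),
                 stringsAsFactors = FALSE)
    }
    widths <- tryCatch(widths_table(params),
                       error = function(e) stop_stage("widths", conditionMessage(e)))

    ## ---- coverage stage ----
    coverage <- if (!is.null(config$ensembl_counts)) {
      tryCatch({
        ens <- read.delim(config$ensembl_counts, stringsAsFactors = FALSE)
        idx <- match(ens$species, params$species)
        pcg <- if (!is.null(ens$pcg_swissprot)) ens$pcg_swissprot else params$N[idx]
        keep <- !is.na(pcg)
        annotation_coverage(pcg[keep], ens$genes_ensembl[keep],
                            species = ens$species[keep],
                            taxon_id = ens$taxon_id[keep])
      }, error = function(e) stop_stage("coverage", conditionMessage(e)))
    } else {
      annotation_coverage(numeric(), numeric(), character(), integer())
    }

    ## ---- overlap stage ----
    overlap <- if (!is.null(config$aging_list)) {
      tryCatch({
        og <- if (!is.null(config$orthogroups)) {
          read_orthogroups(config$orthogroups)
        } else if (!is.null(config$proteome_dir)) {
          fastas <- list.files(config$proteome_dir,
                               pattern = "\\.fa(sta)?$", full.names = TRUE)
          names(fastas) <- sub("\\.fa(sta)?$", "", basename(fastas))
          infer_orthogroups_rbh(fastas)
        } else {
          stop("aging_list given but neither orthogroups nor proteome_dir")
        }
        symbols <- readLines(config$aging_list, warn = FALSE)
        aging <- map_aging_genes(symbols, config$mapping)
        log_lines <<- c(log_lines,
                        sprintf("aging genes: %d symbols, %d accessions, %d unmapped",
                                length(aging$symbols), length(aging$accessions),
                                length(aging$unmapped)))
        human <- config$human_label %||% "human"
        overlap_table(og, aging, human_label = human)
      }, error = function(e) stop_stage("overlap", conditionMessage(e)))
    } else {
      data.frame(species = character(), n_orthogroups = integer(),
                 stringsAsFactors = FALSE)
    }

    write_report <- function(tab, path) {
      write.table(format(tab, trim = TRUE, scientific = FALSE,
                         justify = "none"),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_report(coverage, paths[["coverage"]])
    write_report(widths, paths[["widths"]])
    write_report(overlap, paths[["overlap"]])
    log_lines <- c(log_lines,
                   sprintf("species in width report: %d", nrow(widths)),
                   sprintf("species in overlap report: %d", nrow(overlap)))
    writeLines(log_lines, paths[["log"]])
    list(coverage = coverage, widths = widths, overlap = overlap,
         files = paths)
  }, error = function(e) {
    on_error_cleanup()
    stop(e)
  })
  invisible(result)
}
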