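# Gene-level aggregation, the 13-parameter proteome vector, the three
# nested proteoform-width models, and annotation coverage.
#
# The width models are evaluated on the raw integer counts (N, AS, SAP,
# PTM, ASg, SAPg, PTMg) rather than on pre-divided densities and
# averages: the densities are ratios of integers, and evaluating the
# products in that order keeps the model-1 identity
#   nps1 = N + AS + SAP + PTM
# exact, which floating division before multiplication would break.

#' Aggregate entry-level feature counts to genes
#'
#' Sums the per-entry splice-variant / SAP / PTM sequence counts over all
#' entries sharing a gene key (see [resolve_gene_key()]). Output rows are
#' sorted by taxon then gene label for determinism.
#'
#' @param x a `swissprot_records` object, or a data.frame shaped like
#'   [feature_count_table()] output (columns `taxon_id`, `gene`,
#'   `as_sequences`, `sap_sequences`, `ptm_sequences`).
#' @inheritParams entry_feature_counts
#' @return data.frame with one row per gene: `taxon_id`, `gene`,
#'   `n_entries`, `as_sequences`, `sap_sequences`, `ptm_sequences`.
#' @examples
#' sim <- simulate_proteome(n_genes = 5, seed = 3)
#' genes <- aggregate_gene_counts(read_swissprot(text = sim$dat))
#' head(genes)
#' @export
aggregate_gene_counts <- function(x,
                                  ptm_keys = default_ptm_keys(),
                                  isoform_convention = c("all_named", "non_canonical")) {
  isoform_convention <- match.arg(isoform_convention)
  tab <- if (inherits(x, "swissprot_records")) {
    feature_count_table(x, ptm_keys, isoform_convention)
  } else {
    as.data.frame(x)
  }
  need <- c("taxon_id", "gene", "as_sequences", "sap_sequences", "ptm_sequences")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(tab)) {
    return(data.frame(taxon_id = integer(), gene = character(),
                      n_entries = integer(), as_sequences = integer(),
                      sap_sequences = integer(), ptm_sequences = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(tab$taxon_id, tab$gene, sep = "\r")
  agg <- function(v) as.integer(rowsum(as.integer(v), key, reorder = TRUE))
  ord_keys <- sort(unique(key))
  parts <- strsplit(ord_keys, "\r", fixed = TRUE)
  out <- data.frame(
    taxon_id = as.integer(vapply(parts, `[[`, character(1), 1)),
    gene = vapply(parts, `[[`, character(1), 2),
    n_entries = as.integer(table(key)[ord_keys]),
    as_sequences = agg(tab$as_sequences),
    sap_sequences = agg(tab$sap_sequences),
    ptm_sequences = agg(tab$ptm_sequences),
    stringsAsFactors = FALSE)
  out <- out[order(out$taxon_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive the 13-parameter proteome vector
#'
#' From gene-level event counts, computes the parameter set the width
#' models consume: the number of protein-coding genes `N`; the counts of
#' genes bearing at least one splicing / SAP / PTM event (`ASg`, `SAPg`,
#' `PTMg`); the event-bearing sequence totals (`AS`, `SAP`, `PTM`); the
#' genome fractions (`ASd = ASg/N`, etc.); and the per-affected-gene
#' averages (`ASav = AS/ASg`, etc.). An average whose denominator is 0
#' is defined as 0, so species with no events of a class are valid.
#'
#' `N` defaults to the number of distinct genes observed in the reviewed
#' records; `n_override` substitutes an externally supplied
#' protein-coding-gene count when the reviewed set is known to differ
#' from the genome-wide figure.
#'
#' @param genes data.frame from [aggregate_gene_counts()] (or any frame
#'   with columns `as_sequences`, `sap_sequences`, `ptm_sequences`, one
#'   row per gene).
#' @param n_override optional positive count replacing `N`.
#' @return object of class `proteome_parameters`: a named list with
#'   elements `N`, `ASg`, `ASd`, `AS`, `ASav`, `SAPg`, `SAPd`, `SAP`,
#'   `SAPav`, `PTMg`, `PTMd`, `PTM`, `PTMav`.
#' @examples
#' genes <- data.frame(as_sequences = c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0),
#'                     sap_sequences = 0, ptm_sequences = 0)
#' proteome_parameters(genes)  # ASd = 0.2, ASav = 2
#' @export
proteome_parameters <- function(genes, n_override = NULL) {
  if ((is.null(genes) || !nrow(genes)) && is.null(n_override)) {
    stop("no gene records and no n_override: parameters undefined (N = 0)")
  }
  n <- if (!is.null(n_override)) as.numeric(n_override) else as.numeric(nrow(genes))
  if (n <= 0) stop("N must be positive; parameters undefined for N = 0")
  gcount <- function(v) as.numeric(sum(v > 0))
  gtotal <- function(v) as.numeric(sum(v))
  z <- function(num, den) if (den > 0) num / den else 0
  if (is.null(genes) || !nrow(genes)) {
    ASg <- SAPg <- PTMg <- AS <- SAP <- PTM <- 0
  } else {
    ASg <- gcount(genes$as_sequences);  AS <- gtotal(genes$as_sequences)
    SAPg <- gcount(genes$sap_sequences); SAP <- gtotal(genes$sap_sequences)
    PTMg <- gcount(genes$ptm_sequences); PTM <- gtotal(genes$ptm_sequences)
  }
  p <- list(N = n,
            ASg = ASg,  ASd = z(ASg, n),  AS = AS,  ASav = z(AS, ASg),
            SAPg = SAPg, SAPd = z(SAPg, n), SAP = SAP, SAPav = z(SAP, SAPg),
            PTMg = PTMg, PTMd = z(PTMg, n), PTM = PTM, PTMav = z(PTM, PTMg))
  structure(p, class = "proteome_parameters")
}

#' Assemble a parameter vector from raw counts
#'
#' Convenience constructor when the seven integer counts are already
#' known (for example from a published parameter table) rather than
#' derived from parsed records.
#'
#' @param N,ASg,AS,SAPg,SAP,PTMg,PTM nonnegative counts; `N > 0`,
#'   `ASg <= N`, `SAPg <= N`, `PTMg <= N`, and a zero gene count forces
#'   a zero sequence total.
#' @return a `proteome_parameters` object (see [proteome_parameters()]).
#' @examples
#' parameter_vector(N = 10, ASg = 2, AS = 4, SAPg = 5, SAP = 10,
#'                  PTMg = 10, PTM = 20)
#' @export
parameter_vector <- function(N, ASg = 0, AS = 0, SAPg = 0, SAP = 0,
                             PTMg = 0, PTM = 0) {
  v <- c(N = N, ASg = ASg, AS = AS, SAPg = SAPg, SAP = SAP,
         PTMg = PTMg, PTM = PTM)
  if (any(v < 0)) stop("counts must be nonnegative")
  if (N <= 0) stop("N must be positive")
  if (ASg > N || SAPg > N || PTMg > N) stop("gene counts cannot exceed N")
  if ((ASg == 0 && AS > 0) || (SAPg == 0 && SAP > 0) || (PTMg == 0 && PTM > 0)) {
    stop("a zero gene count requires a zero sequence total")
  }
  z <- function(num, den) if (den > 0) num / den else 0
  structure(list(N = as.numeric(N),
                 ASg = as.numeric(ASg), ASd = z(ASg, N),
                 AS = as.numeric(AS), ASav = z(AS, ASg),
                 SAPg = as.numeric(SAPg), SAPd = z(SAPg, N),
                 SAP = as.numeric(SAP), SAPav = z(SAP, SAPg),
                 PTMg = as.numeric(PTMg), PTMd = z(PTMg, N),
                 PTM = as.numeric(PTM), PTMav = z(PTM, PTMg)),
            class = "proteome_parameters")
}

#' @export
print.proteome_parameters <- function(x, ...) {
  cat("Proteome parameter vector (13 parameters)\n")
  cat(sprintf("  N    = %g protein-coding genes\n", x$N))
  fmt <- function(tag, g, d, tot, av) {
    cat(sprintf("  %-4s genes = %g (density %.4g), sequences = %g (avg/gene %.4g)\n",
                tag, g, d, tot, av))
  }
  fmt("AS", x$ASg, x$ASd, x$AS, x$ASav)
  fmt("SAP", x$SAPg, x$SAPd, x$SAP, x$SAPav)
  fmt("PTM", x$PTMg, x$PTMd, x$PTM, x$PTMav)
  invisible(x)
}

#' @export
as.data.frame.proteome_parameters <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Proteome width under the three information models
#'
#' The proteome width `Nps(H)` is the number of distinct proteoforms the
#' genome can encode under information model `H`:
#'
#' * **Model 1** — sequence changes (SAP) and modifications (PTM) occur
#'   only on the canonical sequence of each gene:
#'   `nps1 = N * (1 + ASd*ASav + SAPd*SAPav + PTMd*PTMav)`,
#'   which reduces exactly to `N + AS + SAP + PTM`.
#' * **Model 2** — SAPs and PTMs also occur on splice variants:
#'   `nps2 = nps1 + AS * (SAPav + PTMav)`.
#' * **Model 3** — SAPs and PTMs co-occur on any sequence:
#'   `nps3 = nps2 + N * SAPav * PTMav + AS * SAPav * PTMav`.
#'
#' `proteome_width()` is a generic: give it a parameter vector, parsed
#' Swiss-Prot records, a DAT file path, or a gene-count data.frame, and
#' it returns a classed result with [print()], [summary()], [coef()] and
#' [as.data.frame()] methods. `coef()` returns the 13-parameter vector.
#'
#' @param x a `proteome_parameters` object, `swissprot_records`, a path
#'   to a Swiss-Prot DAT file, or a gene-count data.frame as returned by
#'   [aggregate_gene_counts()].
#' @param ... passed on to the underlying aggregation
#'   ([aggregate_gene_counts()]: `ptm_keys`, `isoform_convention`) and to
#'   [proteome_parameters()] (`n_override`).
#' @return object of class `proteome_width` with elements `parameters`
#'   (the `proteome_parameters`), `nps` (named numeric `nps1`, `nps2`,
#'   `nps3`), and `per_pcg` (the three widths divided by `N`).
#' @examples
#' p <- parameter_vector(N = 10, ASg = 2, AS = 4, SAPg = 5, SAP = 10,
#'                       PTMg = 10, PTM = 20)
#' w <- proteome_width(p)
#' w$nps          # 44 60 116
#' per_pcg_ratio(w)
#' @export
proteome_width <- function(x, ...) UseMethod("proteome_width")

#' @rdname proteome_width
#' @export
proteome_width.proteome_parameters <- function(x, ...) {
  p <- x
  # Products of integer counts; exact in double precision for any
  # realistically sized proteome (well below 2^53).
  nps1 <- p$N + p$AS + p$SAP + p$PTM
  sap_term <- if (p$SAPg > 0) p$AS * p$SAP / p$SAPg else 0
  ptm_term <- if (p$PTMg > 0) p$AS * p$PTM / p$PTMg else 0
  nps2 <- nps1 + sap_term + ptm_term
  cross <- if (p$SAPg > 0 && p$PTMg > 0) {
    (p$N + p$AS) * p$SAP * p$PTM / (p$SAPg * p$PTMg)
  } else 0
  nps3 <- nps2 + cross
  nps <- c(nps1 = nps1, nps2 = nps2, nps3 = nps3)
  structure(list(parameters = p, nps = nps, per_pcg = nps / p$N),
            class = "proteome_width")
}

#' @rdname proteome_width
#' @param n_override optional protein-coding-gene count replacing the
#'   observed distinct-gene count as `N`.
#' @export
proteome_width.swissprot_records <- function(x, n_override = NULL, ...) {
  genes <- aggregate_gene_counts(x, ...)
  proteome_width(proteome_parameters(genes, n_override = n_override))
}

#' @rdname proteome_width
#' @export
proteome_width.character <- function(x, n_override = NULL, ...) {
  proteome_width(read_swissprot(x), n_override = n_override, ...)
}

#' @rdname proteome_width
#' @export
proteome_width.data.frame <- function(x, n_override = NULL, ...) {
  proteome_width(proteome_parameters(x, n_override = n_override))
}

#' @export
print.proteome_width <- function(x, ...) {
  cat("Proteome width (number of proteoforms)\n")
  cat(sprintf("  N = %g protein-coding genes\n", x$parameters$N))
  for (k in 1:3) {
    cat(sprintf("  model %d: %s proteoforms (%s per gene)\n", k,
                format(x$nps[[k]], big.mark = ",", scientific = FALSE),
                format(round_half_up(x$per_pcg[[k]], 1), nsmall = 1)))
  }
  invisible(x)
}

#' @export
summary.proteome_width <- function(object, ...) {
  print(object$parameters)
  print(object)
  invisible(object)
}

#' @export
coef.proteome_width <- function(object, ...) {
  unlist(unclass(object$parameters))
}

#' @export
as.data.frame.proteome_width <- function(x, ...) {
  data.frame(N = x$parameters$N,
             nps1 = x$nps[["nps1"]], nps2 = x$nps[["nps2"]],
             nps3 = x$nps[["nps3"]],
             per_pcg_1 = x$per_pcg[["nps1"]], per_pcg_2 = x$per_pcg[["nps2"]],
             per_pcg_3 = x$per_pcg[["nps3"]])
}

#' Per-gene proteoform ratios
#'
#' The average number of proteoforms encoded by one protein-coding gene
#' under each model, `nps_k / N`, rounded half-up.
#'
#' @param w a `proteome_width` object, or a numeric vector of widths
#'   (then `N` must be given).
#' @param N protein-coding-gene count (taken from `w` when omitted).
#' @param decimals decimal places to round to (default 1, the precision
#'   comparative tables in this field usually print).
#' @return named numeric vector of rounded ratios.
#' @examples
#' per_pcg_ratio(c(nps1 = 228613), N = 20429)  # 11.2
#' @export
per_pcg_ratio <- function(w, N = NULL, decimals = 1) {
  if (inherits(w, "proteome_width")) {
    N <- N %||% w$parameters$N
    w <- w$nps
  }
  if (is.null(N) || N <= 0) stop("N must be a positive count")
  round_half_up(w / N, decimals)
}

#' Genome annotation coverage
#'
#' The fraction of a species' genes with expert-reviewed (Swiss-Prot)
#' annotation: 100 times the reviewed protein-coding-gene count divided
#' by the Ensembl gene count. Values above 100 are possible when the
#' reviewed set is annotated redundantly relative to Ensembl's gene
#' models (several reviewed entries per predicted gene, or genes absent
#' from the Ensembl build).
#'
#' The printed form follows the precision tiers used by comparative
#' annotation tables: integer above 10 percent, one decimal between 1
#' and 10, one significant figure below 1 — all rounded half-up. (Some
#' published tables truncate rather than round a minority of rows; the
#' raw percentage is always returned so either convention can be
#' checked.)
#'
#' @param pcg_swissprot reviewed gene count(s).
#' @param genes_ensembl Ensembl gene count(s); must be positive.
#' @param species optional species label(s) carried into the result.
#' @param taxon_id optional NCBI taxon id(s) carried into the result.
#' @return data.frame with columns `species`, `taxon_id`,
#'   `pcg_swissprot`, `genes_ensembl`, `percent_annotated` (raw) and
#'   `percent_printed` (tiered precision).
#' @examples
#' annotation_coverage(3343, 30153, species = "Danio rerio")
#' @export
annotation_coverage <- function(pcg_swissprot, genes_ensembl,
                                species = NA_character_,
                                taxon_id = NA_integer_) {
  if (any(genes_ensembl <= 0)) stop("genes_ensembl must be positive")
  if (any(pcg_swissprot < 0)) stop("pcg_swissprot must be nonnegative")
  pct <- 100 * pcg_swissprot / genes_ensembl
  data.frame(species = species, taxon_id = taxon_id,
             pcg_swissprot = pcg_swissprot, genes_ensembl = genes_ensembl,
             percent_annotated = pct,
             percent_printed = format_coverage_percent(pct),
             stringsAsFactors = FALSE)
}

#' Tiered rounding of a coverage percentage
#'
#' @param pct numeric percentage(s).
#' @return numeric vector: integer for values >= 10, one decimal for
#'   values in \[1, 10), one significant figure below 1; half rounds up.
#' @export
format_coverage_percent <- function(pct) {
  vapply(pct, function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 10) round_half_up(p, 0)
    else if (p >= 1) round_half_up(p, 1)
    else signif(p, 1)
  }, numeric(1))
}
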