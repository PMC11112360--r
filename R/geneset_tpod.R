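#' Aggregate probeset BMDs to gene BMDs
#'
#' When two or more probesets map to a single gene their BMD values are
#' averaged (arithmetic mean on the linear scale) to obtain one BMD per gene.
#' Probesets mapped to more than one gene are excluded entirely, as are
#' probesets with no gene mapping.
#'
#' @param records data frame of per-probeset BMD records as returned by
#'   [run_bmd_analysis()] (columns `probeset_id`, `bmd` required).
#' @param structure a [gene_set_structure()] supplying the probe map.
#' @return data frame with columns `gene_id`, `bmd`, `n_probesets`, plus a
#'   list-column-free `provenance` string of contributing probeset ids
#'   (';'-separated).
#' @export
aggregate_to_genes <- function(records, structure) {
  pm <- structure$probe_to_gene
  pm <- pm[!(pm$probeset_id %in% structure$multi_gene_probesets), ,
           drop = FALSE]
  m <- merge(records[, c("probeset_id", "bmd")], pm, by = "probeset_id")
  if (nrow(m) == 0)
    return(data.frame(gene_id = character(0), bmd = numeric(0),
                      n_probesets = integer(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  sp <- split(m, m$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    bmd = vapply(sp, function(x) mean(x$bmd), numeric(1)),
    n_probesets = vapply(sp, nrow, integer(1)),
    provenance = vapply(sp, function(x)
      paste(sort(x$probeset_id), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Minimum-enrichment filter
#'
#' A gene set contributes to the tPOD only if it holds at least
#' `min_genes_with_bmd` genes with a BMD and those genes make up at least
#' `min_pct_with_bmd` percent of the set's platform genes.
#'
#' @param name filter label (e.g. `"F3"`).
#' @param min_genes_with_bmd minimum count of genes with a BMD.
#' @param min_pct_with_bmd minimum percentage (0-100) of the set's
#'   platform-restricted genes that have a BMD.
#' @return a list of class `enrichment_filter`.
#' @export
enrichment_filter <- function(name, min_genes_with_bmd, min_pct_with_bmd) {
  stopifnot(min_genes_with_bmd >= 1,
            min_pct_with_bmd >= 0, min_pct_with_bmd <= 100)
  structure(list(name = name,
                 min_genes_with_bmd = as.integer(min_genes_with_bmd),
                 min_pct_with_bmd = min_pct_with_bmd),
            class = "enrichment_filter")
}

#' The default stringency ladder of enrichment filters
#'
#' Eleven filters of non-decreasing stringency in both fields. F3 is the
#' recommended minimum-enrichment criterion (at least 3 genes and at least 5
#' percent of the set's platform genes with a BMD); the other rungs are
#' package defaults chosen to sweep from very permissive to very strict and
#' are user-overridable.
#'
#' @return named list of [enrichment_filter()] objects `F1` to `F11`.
#' @export
default_filter_ladder <- function() {
  spec <- list(F1 = c(2, 1), F2 = c(3, 3), F3 = c(3, 5), F4 = c(4, 7.5),
               F5 = c(5, 10), F6 = c(6, 15), F7 = c(8, 20), F8 = c(10, 30),
               F9 = c(12, 40), F10 = c(15, 50), F11 = c(20, 60))
  stats::setNames(
    lapply(names(spec), function(nm)
      enrichment_filter(nm, spec[[nm]][1], spec[[nm]][2])),
    names(spec))
}

#' Summarize gene sets against a gene BMD table
#'
#' For every set with at least one platform gene, counts the genes with a
#' BMD, computes the percentage relative to the set's platform-restricted
#' size (the denominator is the number of the set's genes represented on the
#' platform), the median and mean of the contributing gene BMDs, and whether
#' the set passes the enrichment filter.
#'
#' @param gene_table output of [aggregate_to_genes()].
#' @param structure a [gene_set_structure()].
#' @param platform_probesets probeset ids defining the platform.
#' @param filter an [enrichment_filter()].
#' @return data frame with columns `set_id`, `n_genes_platform`,
#'   `n_genes_with_bmd`, `pct_with_bmd`, `median_bmd`, `mean_bmd`,
#'   `passes_filter`.
#' @export
summarize_gene_sets <- function(gene_table, structure, platform_probesets,
                                filter) {
  stopifnot(inherits(filter, "enrichment_filter"))
  pm <- structure$probe_to_gene
  platform_genes <- unique(pm$gene_id[pm$probeset_id %in% platform_probesets])
  bmd_by_gene <- stats::setNames(gene_table$bmd, gene_table$gene_id)
  rows <- lapply(names(structure$set_members), function(sid) {
    genes <- intersect(structure$set_members[[sid]], platform_genes)
    if (length(genes) == 0) return(NULL)
    with_bmd <- genes[genes %in% names(bmd_by_gene)]
    pct <- 100 * length(with_bmd) / length(genes)
    bmds <- unname(bmd_by_gene[with_bmd])
    data.frame(
      set_id = sid,
      n_genes_platform = length(genes),
      n_genes_with_bmd = length(with_bmd),
      pct_with_bmd = pct,
      median_bmd = if (length(bmds)) stats::median(bmds) else NA_real_,
      mean_bmd = if (length(bmds)) mean(bmds) else NA_real_,
      passes_filter = length(with_bmd) >= filter$min_genes_with_bmd &&
        pct >= filter$min_pct_with_bmd,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(set_id = character(0), n_genes_platform = integer(0),
                      n_genes_with_bmd = integer(0), pct_with_bmd = numeric(0),
                      median_bmd = numeric(0), mean_bmd = numeric(0),
                      passes_filter = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene set-based tPOD
#'
#' The tPOD is the lowest summary statistic (median by default, mean
#' optionally) of gene BMDs among the gene sets passing the enrichment
#' filter; if no set passes, no tPOD is generated.
#'
#' @param summaries output of [summarize_gene_sets()] under one filter.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param molecule_id,method labels recorded in the result.
#' @param n_probesets_with_bmd probeset count recorded for provenance.
#' @return a one-row data frame (a tPOD result): `molecule_id`, `method`,
#'   `tpod` (NA when no set passes), `n_probesets_with_bmd`, `driver` (set id
#'   of the minimizing set, NA when none).
#' @export
geneset_tpod <- function(summaries, statistic = c("median", "mean"),
                         molecule_id = "molecule", method = "geneset",
                         n_probesets_with_bmd = NA_integer_) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "median") "median_bmd" else "mean_bmd"
  pass <- summaries[summaries$passes_filter & !is.na(summaries[[col]]), ,
                    drop = FALSE]
  if (nrow(pass) == 0)
    return(tpod_result(molecule_id, method, NA_real_, n_probesets_with_bmd,
                       NA_character_))
  i <- which.min(pass[[col]])
  tpod_result(molecule_id, method, pass[[col]][i], n_probesets_with_bmd,
              pass$set_id[i])
}

# Canonical one-row tPOD result record.
tpod_result <- function(molecule_id, method, tpod, n_probesets_with_bmd,
                        driver = NA_character_) {
  data.frame(molecule_id = molecule_id, method = method,
             tpod = as.numeric(tpod),
             n_probesets_with_bmd = as.integer(n_probesets_with_bmd),
             driver = driver, stringsAsFactors = FALSE)
}
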