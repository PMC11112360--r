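#' End-to-end tPOD derivation for one molecule
#'
#' Runs the full pipeline on one study: prefilter (trend test + fold
#' change), per-probeset BMD modeling with the sanity filters, then one gene
#' set-based tPOD per supplied structure and the five distribution-based
#' tPODs. Stage failures for one method are recorded as a missing tPOD; the
#' remaining methods still run.
#'
#' @param study a [dose_response_study()].
#' @param structures named list of [gene_set_structure()] objects (the names
#'   become method labels, e.g. `geneset_GOBP`); may be empty.
#' @param prefilter_par a [prefilter_params()].
#' @param bmd_filters a [bmd_filter_params()].
#' @param filter an [enrichment_filter()] for the gene-set methods.
#' @param statistic per-set statistic for the gene-set tPOD.
#' @param dist_params a [distribution_params()].
#' @param records optional precomputed BMD records; when supplied, the
#'   prefilter and BMD stages are skipped.
#' @param out_dir optional directory; when given, the per-stage outputs are
#'   written there as TSVs (`bmd_records.tsv`, `tpod_results.tsv`) along
#'   with a plain-text run log recording every parameter.
#' @return list with `results` (data frame of tPOD results, one row per
#'   method), `records` (the per-probeset BMD records) and
#'   `n_probesets_with_bmd`.
#' @export
run_molecule <- function(study, structures = list(),
                         prefilter_par = prefilter_params(),
                         bmd_filters = bmd_filter_params(max(study$doses)),
                         filter = default_filter_ladder()$F3,
                         statistic = "median",
                         dist_params = distribution_params(),
                         records = NULL, out_dir = NULL) {
  if (is.null(records)) {
    passing <- prefilter(study, prefilter_par)
    records <- run_bmd_analysis(study, passing, bmd_filters)
  }
  nb <- nrow(records)
  res <- list()
  for (nm in names(structures)) {
    st <- structures[[nm]]
    r <- tryCatch({
      gt <- aggregate_to_genes(records, st)
      geneset_tpod(
        summarize_gene_sets(gt, st, study$probeset_ids, filter),
        statistic, study$molecule_id, paste0("geneset_", nm), nb)
    }, error = function(e) {
      warning("gene-set method '", nm, "' failed for ", study$molecule_id,
              ": ", conditionMessage(e))
      tpod_result(study$molecule_id, paste0("geneset_", nm), NA_real_, nb)
    })
    res[[length(res) + 1]] <- r
  }
  dt <- if (nb > 0)
    distribution_tpods(records$bmd, dist_params, study$molecule_id)
  else do.call(rbind, lapply(c("PODAcc", "FirstMode", "Perc05", "Perc10",
                               "Rank25"),
                             function(m) tpod_result(study$molecule_id, m,
                                                     NA_real_, 0L)))
  res[[length(res) + 1]] <- dt
  results <- do.call(rbind, res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(records, file.path(out_dir, "bmd_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(results, file.path(out_dir, "tpod_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(
      paste("molecule_id:", study$molecule_id),
      paste("n_probesets:", length(study$probeset_ids)),
      paste("dose_levels:", paste(sort(unique(study$doses)), collapse = ",")),
      paste("prefilter: p <", prefilter_par$p_threshold,
            "; fold change >", prefilter_par$fc_threshold,
            "; permutations =", prefilter_par$n_permutations,
            "; seed =", if (is.null(prefilter_par$seed)) "NULL"
                        else prefilter_par$seed),
      paste("bmd filters: max_bmd =", bmd_filters$max_bmd,
            "; max BMDU/BMDL =", bmd_filters$max_bmdu_bmdl_ratio),
      paste("enrichment filter:", filter$name, "=",
            filter$min_genes_with_bmd, "genes,",
            filter$min_pct_with_bmd, "%; statistic =", statistic),
      paste("distribution: min_probesets =", dist_params$min_probesets,
            "; kde_min_bw =", dist_params$kde_min_bandwidth,
            "; mode_min_density =", dist_params$mode_min_density,
            paste0("(", dist_params$mode_density_scale, ")"),
            "; kneedle sensitivity =", dist_params$kneedle_sensitivity),
      paste("structures:", paste(names(structures), collapse = ", ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(results = results, records = records, n_probesets_with_bmd = nb)
}

#' Cross-molecule benchmark of tPOD methods
#'
#' Given per-molecule tPOD results for several methods, computes the pairwise
#' concordance matrix (overall and within bins of the number of probesets
#' with a BMD) and a sensitivity table.
#'
#' @param results data frame of tPOD results across molecules and methods
#'   (columns `molecule_id`, `method`, `tpod`, `n_probesets_with_bmd`).
#' @param bins cut points for grouping molecules by their BMD probeset count;
#'   the default bins are fewer than 150, 150 to fewer than 300, and 300 or
#'   more.
#' @param k fold thresholds for the within-k proportions.
#' @return list of class `tpod_benchmark` with `pairwise` (data frame of all
#'   ordered method pairs with `n_common`, `median_abs_fc`, `prop_within_k*`,
#'   `rmsd_log10`, one row per pair and bin including `"all"`), and
#'   `sensitivity` (per-method counts and fractions).
#' @export
run_benchmark <- function(results, bins = c(150, 300), k = c(2, 4, 10)) {
  stopifnot(all(c("molecule_id", "method", "tpod",
                  "n_probesets_with_bmd") %in% names(results)))
  methods <- unique(results$method)
  nb <- tapply(results$n_probesets_with_bmd, results$molecule_id, max)
  lab <- c(paste0("<", bins[1]),
           paste0(bins[-length(bins)], "-", bins[-1]),
           paste0(">=", bins[length(bins)]))
  bin_of <- lab[findInterval(nb, c(bins), left.open = FALSE) + 1]
  names(bin_of) <- names(nb)
  groups <- c(list(all = names(nb)),
              split(names(nb), factor(bin_of, levels = lab)))
  rows <- list()
  for (g in names(groups)) {
    mols <- groups[[g]]
    sub <- results[results$molecule_id %in% mols, , drop = FALSE]
    for (a in methods) for (b in methods) {
      ra <- sub[sub$method == a, ]
      rb <- sub[sub$method == b, ]
      cr <- concordance_report(ra, rb, k)
      row <- data.frame(bin = g, method_a = a, method_b = b,
                        n_common = cr$n_common,
                        median_abs_fc = cr$median_abs_fc,
                        rmsd_log10 = cr$rmsd_log10,
                        stringsAsFactors = FALSE)
      for (kk in names(cr$prop_within))
        row[[paste0("prop_within_", kk)]] <- cr$prop_within[[kk]]
      rows[[length(rows) + 1]] <- row
    }
  }
  sens <- do.call(rbind, lapply(methods, function(m) {
    s <- sensitivity(results[results$method == m, ])
    data.frame(method = m, n_molecules = s$n_molecules,
               n_with_tpod = s$n_with_tpod, fraction = s$fraction,
               stringsAsFactors = FALSE)
  }))
  structure(list(pairwise = do.call(rbind, rows), sensitivity = sens,
                 bins = lab),
            class = "tpod_benchmark")
}

#' @export
print.tpod_benchmark <- function(x, ...) {
  cat("tPOD method benchmark\n")
  cat("Sensitivity:\n")
  print(x$sensitivity, row.names = FALSE, digits = 3)
  all_pairs <- x$pairwise[x$pairwise$bin == "all" &
                          x$pairwise$method_a != x$pairwise$method_b, ]
  cat("\nPairwise concordance (all molecules):\n")
  print(utils::head(all_pairs[order(all_pairs$rmsd_log10), ], 10),
        row.names = FALSE, digits = 3)
  invisible(x)
}
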