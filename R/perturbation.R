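#' Structure-preserving gene-set randomization
#'
#' Replicates the original structure exactly — same set ids and the same
#' number of genes per set — but with random gene membership. In `"overlap"`
#' mode each set is sampled independently from the gene universe (assigning a
#' gene to one set does not reduce its chance of joining another); in
#' `"no_overlap"` mode each gene occurs in at most one randomized set, for
#' structures whose original sets are non-overlapping.
#'
#' @param structure a [gene_set_structure()].
#' @param mode `"overlap"` or `"no_overlap"`.
#' @param seed integer seed.
#' @param universe `"structure"` (default: the union of genes in the original
#'   sets) or `"platform"` (all genes in the probe map), or a character
#'   vector of gene ids.
#' @return a [gene_set_structure()] with identical set-size multiset and the
#'   original probe map.
#' @export
randomize_structure <- function(structure, mode = c("overlap", "no_overlap"),
                                seed = 1L, universe = "structure") {
  mode <- match.arg(mode)
  set.seed(seed)
  pool <- if (identical(universe, "structure"))
    unique(unlist(structure$set_members, use.names = FALSE))
  else if (identical(universe, "platform"))
    unique(structure$probe_to_gene$gene_id)
  else as.character(universe)
  sizes <- lengths(structure$set_members)
  if (mode == "no_overlap") {
    if (sum(sizes) > length(pool))
      stop("no_overlap randomization infeasible: total set size ",
           sum(sizes), " exceeds the gene universe (", length(pool), ")")
    drawn <- sample(pool, sum(sizes))
    members <- split(drawn, rep(seq_along(sizes), sizes))
    names(members) <- names(structure$set_members)
  } else {
    members <- lapply(sizes, function(s) sample(pool, s))
  }
  gene_set_structure(structure$probe_to_gene, members, structure$set_names)
}

#' Transcriptome-reduction scenario
#'
#' @param name scenario label (`"S1"`, `"S2"`, `"S3"`, ...).
#' @param mode `"random_fraction"` (randomly retain a fraction of the
#'   platform probesets) or `"keep_list"` (retain a fixed probeset list, e.g.
#'   sentinel-gene probesets).
#' @param fraction fraction retained when `mode = "random_fraction"`
#'   (0.60 and 0.113 are the study's two random scenarios).
#' @param keep_list probeset ids retained when `mode = "keep_list"`.
#' @return a list of class `reduction_scenario`.
#' @export
reduction_scenario <- function(name, mode = c("random_fraction", "keep_list"),
                               fraction = NULL, keep_list = NULL) {
  mode <- match.arg(mode)
  if (mode == "random_fraction") {
    stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  } else {
    if (is.null(keep_list) || length(keep_list) == 0)
      stop("keep_list must be non-empty")
  }
  structure(list(name = name, mode = mode, fraction = fraction,
                 keep_list = as.character(keep_list)),
            class = "reduction_scenario")
}

#' Down-sample a probeset platform
#'
#' `random_fraction` scenarios take a uniform sample without replacement of
#' `round(fraction * N)` probesets; `keep_list` scenarios intersect the list
#' with the platform (deterministic).
#'
#' @param platform character vector of probeset ids.
#' @param scenario a [reduction_scenario()].
#' @param seed integer seed (ignored for keep-list scenarios).
#' @return character vector of retained probeset ids.
#' @export
downsample_probesets <- function(platform, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "reduction_scenario"))
  platform <- as.character(platform)
  out <- if (scenario$mode == "random_fraction") {
    set.seed(seed)
    sample(platform, round(scenario$fraction * length(platform)))
  } else {
    intersect(scenario$keep_list, platform)
  }
  if (length(out) == 0) stop("down-sampling produced an empty platform")
  out
}

# Aggregation rule shared by the two simulation studies: a summary is
# reported only when at least half of the simulations produced a tPOD, and
# the reported value is the median across the successful simulations.
summarize_sims <- function(molecule_id, method, tpods, n_sims) {
  ok <- tpods[!is.na(tpods)]
  data.frame(molecule_id = molecule_id, method = method, n_sims = n_sims,
             n_success = length(ok),
             median_tpod = if (length(ok)) stats::median(ok) else NA_real_,
             reported = length(ok) >= n_sims / 2,
             stringsAsFactors = FALSE)
}

#' Randomized gene-set study for one molecule
#'
#' Compares the gene set-based tPOD under the original structure with tPODs
#' from randomized versions of the same structure. The randomization is
#' repeated `n_sims` times; the summary follows the at-least-half rule
#' (reported only when half or more of the simulations return a tPOD, as the
#' median over successful simulations) and the fold change is original tPOD /
#' median randomized tPOD.
#'
#' @param records per-probeset BMD records ([run_bmd_analysis()] output).
#' @param structure the original [gene_set_structure()].
#' @param platform_probesets platform probeset ids.
#' @param filter an [enrichment_filter()] (the recommended F3 by default).
#' @param statistic per-set statistic, `"median"` or `"mean"`.
#' @param mode randomization mode, see [randomize_structure()].
#' @param n_sims number of randomizations (1000 for full runs).
#' @param seed master seed; per-simulation child seeds are derived
#'   deterministically.
#' @param molecule_id label for the outputs.
#' @return list with `summary` (one-row data frame: the simulation summary
#'   plus `original_tpod` and `fold_change`) and `sim_tpods` (numeric vector
#'   of per-simulation tPODs, NA when a simulation produced none).
#' @export
run_randomization_study <- function(records, structure, platform_probesets,
                                    filter = default_filter_ladder()$F3,
                                    statistic = "median",
                                    mode = "overlap",
                                    n_sims = 1000, seed = 1L,
                                    molecule_id = "molecule") {
  gene_table <- aggregate_to_genes(records, structure)
  orig <- geneset_tpod(
    summarize_gene_sets(gene_table, structure, platform_probesets, filter),
    statistic, molecule_id, "geneset", nrow(records))
  sim_tpods <- vapply(seq_len(n_sims), function(i) {
    rs <- randomize_structure(structure, mode, seed = seed + i)
    geneset_tpod(
      summarize_gene_sets(gene_table, rs, platform_probesets, filter),
      statistic, molecule_id, "geneset_random", nrow(records))$tpod
  }, numeric(1))
  sm <- summarize_sims(molecule_id, "geneset_random", sim_tpods, n_sims)
  sm$original_tpod <- orig$tpod
  sm$fold_change <- if (!is.na(orig$tpod) && sm$reported &&
                        !is.na(sm$median_tpod))
    orig$tpod / sm$median_tpod else NA_real_
  list(summary = sm, sim_tpods = sim_tpods)
}

#' Transcriptome-reduction study for one molecule
#'
#' Re-derives tPODs after down-sampling the probeset platform. The retained
#' probesets restrict the existing per-probeset BMD records (per-probeset
#' statistics are independent across probesets, so restriction is equivalent
#' to rerunning the upstream stages on the reduced matrix); the gene-set
#' pipeline also shrinks the platform denominator to the retained probesets.
#' Random scenarios are repeated `n_sims` times and aggregated by the
#' at-least-half / median rule; keep-list scenarios run once
#' (deterministic).
#'
#' @inheritParams run_randomization_study
#' @param scenario a [reduction_scenario()].
#' @param pipeline `"geneset"`, `"distribution"`, or both.
#' @param dist_params a [distribution_params()].
#' @return list with `summary` (one row per method: simulation summary plus
#'   `original_tpod` and `fold_change` = original / median reduced) and
#'   `sim_tpods` (matrix, simulations x methods).
#' @export
run_reduction_study <- function(records, structure, platform_probesets,
                                scenario,
                                pipeline = c("geneset", "distribution"),
                                filter = default_filter_ladder()$F3,
                                statistic = "median",
                                dist_params = distribution_params(),
                                n_sims = 1000, seed = 1L,
                                molecule_id = "molecule") {
  pipeline <- match.arg(pipeline, several.ok = TRUE)
  if (scenario$mode == "keep_list") n_sims <- 1L
  methods <- c(if ("geneset" %in% pipeline) "geneset",
               if ("distribution" %in% pipeline)
                 c("PODAcc", "FirstMode", "Perc05", "Perc10", "Rank25"))
  one_run <- function(keep) {
    recs <- records[records$probeset_id %in% keep, , drop = FALSE]
    out <- numeric(0)
    if ("geneset" %in% pipeline) {
      gt <- aggregate_to_genes(recs, structure)
      gs <- geneset_tpod(
        summarize_gene_sets(gt, structure, keep, filter),
        statistic, molecule_id, "geneset", nrow(recs))
      out <- c(out, geneset = gs$tpod)
    }
    if ("distribution" %in% pipeline) {
      dt <- if (nrow(recs) > 0)
        distribution_tpods(recs$bmd, dist_params, molecule_id)
      else NULL
      v <- stats::setNames(rep(NA_real_, 5),
                           c("PODAcc", "FirstMode", "Perc05", "Perc10",
                             "Rank25"))
      if (!is.null(dt)) v[dt$method] <- dt$tpod
      out <- c(out, v)
    }
    out
  }
  full <- one_run(platform_probesets)
  raw <- vapply(seq_len(n_sims), function(i)
    one_run(downsample_probesets(platform_probesets, scenario,
                                 seed = seed + i)),
    numeric(length(methods)))
  sims <- if (length(methods) == 1) matrix(raw, ncol = 1) else t(raw)
  colnames(sims) <- methods
  summary <- do.call(rbind, lapply(methods, function(m) {
    sm <- summarize_sims(molecule_id, m, sims[, m], n_sims)
    sm$original_tpod <- full[[m]]
    sm$fold_change <- if (!is.na(full[[m]]) && sm$reported &&
                          !is.na(sm$median_tpod))
      full[[m]] / sm$median_tpod else NA_real_
    sm
  }))
  list(summary = summary, sim_tpods = sims)
}
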