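#' Configuration for a synthetic dose-response study
#'
#' The defaults emulate a 29-day rat liver toxicogenomics design: a control
#' group plus three treated dose levels spanning two orders of magnitude,
#' five replicates per group, and log2-scale residual noise of 0.1. Responsive
#' probesets follow one of the eight continuous dose-response model families
#' with the mean curve calibrated so that it crosses the one-standard-deviation
#' benchmark response (the configured residual SD) exactly at the probeset's
#' true BMD; the remaining probesets are flat baseline plus noise.
#'
#' @details The default dose grid is a seven-level half-log series (0, 3,
#'   10, 30, 100, 300, 1000 mg/kg/d). A grid of this density is needed for
#'   the benchmark-dose crossing to be statistically identifiable at a 1-SD
#'   benchmark response; with only two or three treated dose levels the
#'   crossing falls between widely spaced doses and no estimator can locate
#'   it to better than about two-fold, regardless of implementation.
#'
#' @param n_probesets total number of probesets.
#' @param n_responsive number of dose-responsive probesets
#'   (`<= n_probesets`).
#' @param dose_levels numeric dose levels in mg/kg/d, including 0.
#' @param n_replicates samples per dose group.
#' @param noise_sd residual SD in log2 units (also the BMR used for
#'   calibration).
#' @param model_family_weights named numeric sampling weights over the eight
#'   model shapes (`hill`, `power`, `linear`, `poly2`, `exp2`..`exp5`);
#'   infeasible families for a drawn (BMD, effect size) pair are excluded and
#'   the remaining weights renormalized.
#' @param true_bmd_range length-2 numeric; true BMDs are sampled
#'   log-uniformly within this range, which must lie in (0, max dose].
#' @param effect_size_range length-2 numeric; target maximum absolute log2
#'   change at the top dose. The drawn effect is clamped to the family's
#'   feasible interval for the drawn BMD.
#' @param baseline_range length-2 numeric range of baseline log2 intensities.
#' @param seed integer seed; two calls with equal seeds give identical output.
#' @return a list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_probesets = 500,
                                   n_responsive = 300,
                                   dose_levels = c(0, 3, 10, 30, 100, 300,
                                                   1000),
                                   n_replicates = 5,
                                   noise_sd = 0.1,
                                   model_family_weights = NULL,
                                   true_bmd_range = c(1, 1000),
                                   effect_size_range = c(1, 2.5),
                                   baseline_range = c(6, 12),
                                   seed = 1L) {
  if (is.null(model_family_weights))
    model_family_weights <- stats::setNames(rep(1, 8), bmd_model_names())
  stopifnot(n_responsive <= n_probesets, noise_sd > 0,
            n_replicates >= 2, length(true_bmd_range) == 2,
            length(effect_size_range) == 2)
  dose_levels <- sort(unique(as.numeric(dose_levels)))
  if (!any(dose_levels == 0) || sum(dose_levels > 0) < 2)
    stop("dose_levels must contain 0 and at least 2 positive values")
  if (true_bmd_range[1] <= 0 || true_bmd_range[2] > max(dose_levels))
    stop("true_bmd_range must lie within (0, max dose]")
  if (min(effect_size_range) <= noise_sd)
    stop("infeasible calibration: effect size must exceed noise_sd ",
         "for the curve to cross the benchmark response before the max dose")
  structure(list(n_probesets = as.integer(n_probesets),
                 n_responsive = as.integer(n_responsive),
                 dose_levels = dose_levels,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd,
                 model_family_weights = model_family_weights,
                 true_bmd_range = true_bmd_range,
                 effect_size_range = effect_size_range,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

# Unit dose-response shapes f(d) with f(0) = 0 and f(dmax) = 1 for the six
# families whose amplitude is free of the baseline (hill, power, linear,
# poly2, exp4, exp5). Calibration solves the family's auxiliary shape
# parameter so that f(bmd) = r, where r = noise_sd / effect; the mean curve
# is then mu(d) = baseline + direction * effect * f(d), which stays inside
# the fitted model family and crosses the 1-SD BMR exactly at the true BMD.
unit_shape <- function(family, aux, dmax) {
  switch(family,
    linear = function(d) d / dmax,
    poly2 = function(d) (d + aux * d^2) / (dmax + aux * dmax^2),
    power = function(d) (d / dmax)^aux,
    hill = {
      n <- aux[["n"]]; k <- aux[["k"]]
      function(d) (d^n / (k^n + d^n)) / (dmax^n / (k^n + dmax^n))
    },
    exp4 = function(d) (1 - exp(-aux * d)) / (1 - exp(-aux * dmax)),
    exp5 = {
      b <- aux[["b"]]; p <- aux[["p"]]
      function(d) (1 - exp(-(b * d)^p)) / (1 - exp(-(b * dmax)^p))
    },
    stop("unknown model family: ", family))
}

# Solve the auxiliary shape parameter so unit_shape(bmd) == r, or return NULL
# when the family cannot place its BMR crossing at bmd for this r.
calibrate_shape <- function(family, bmd, r, dmax) {
  stopifnot(bmd > 0, bmd <= dmax, r > 0, r < 1)
  frac <- bmd / dmax
  ratio_at <- function(aux) unit_shape(family, aux, dmax)(bmd)
  solve_monotone <- function(lo, hi, make_aux) {
    f <- function(u) ratio_at(make_aux(u)) - r
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
    make_aux(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  switch(family,
    linear = if (abs(frac - r) < 1e-9) numeric(0) else NULL,
    power = {
      delta <- log(r) / log(frac)
      if (is.finite(delta) && delta >= 1 && delta <= 8) delta else NULL
    },
    poly2 = {
      if (r > frac || r < frac^2) return(NULL)
      solve_monotone(0, 1e6 / dmax, identity)
    },
    exp4 = {
      if (r < frac) return(NULL)
      solve_monotone(1e-9 / dmax, 1e4 / dmax, identity)
    },
    exp5 = {
      p <- if (r >= frac) stats::runif(1, 1, 3) else {
        p_min <- log(r) / log(frac)  # need (frac)^p <= r
        if (p_min > 3) return(NULL)
        stats::runif(1, p_min, 3)
      }
      solve_monotone(1e-9 / dmax, 1e4 / dmax,
                     function(b) c(b = b, p = p))
    },
    hill = {
      # ratio(k) decreases from 1 (k -> 0) to frac^n (k -> Inf)
      n <- if (r > frac) stats::runif(1, 1, 4) else {
        n_min <- log(r) / log(frac)
        if (n_min > 12) return(NULL)
        stats::runif(1, n_min + 0.2, min(n_min + 2, 14))
      }
      solve_monotone(dmax * 1e-6, dmax * 1e6,
                     function(k) c(n = n, k = k))
    })
}

# Calibrate one responsive mean curve within the requested model family so
# that |mu(bmd) - mu(0)| equals sigma exactly. The exp2 and exp3 families
# couple amplitude to baseline (mu = a exp(s (b d)^p) with mu(0) = a), so
# their calibration conditions on the baseline: exp2 has no spare parameter
# and implies the effect size; exp3 solves its exponent p for the requested
# effect. Returns list(mu = mean function, eff = realized top-dose effect)
# or NULL when the family cannot realize the (bmd, effect) pair.
calibrate_curve <- function(family, bmd, eff, sigma, dmax, baseline, dir,
                            eff_range) {
  if (family %in% c("exp2", "exp3")) {
    a <- baseline
    lg_bmr <- if (dir > 0) log1p(sigma / a) else -log1p(-sigma / a)
    lg_eff <- function(E) if (dir > 0) log1p(E / a) else -log1p(-E / a)
    if (family == "exp2") {
      b <- lg_bmr / bmd
      eff_impl <- abs(a * expm1(dir * b * dmax))
      if (eff_impl < eff_range[1] || eff_impl > eff_range[2]) return(NULL)
      return(list(mu = function(d) a * exp(dir * b * d), eff = eff_impl))
    }
    if (bmd >= dmax) return(NULL)
    p <- log(lg_eff(eff) / lg_bmr) / log(dmax / bmd)
    if (!is.finite(p) || p < 1 || p > 3) return(NULL)
    b <- lg_bmr^(1 / p) / bmd
    return(list(mu = function(d) a * exp(dir * (b * d)^p), eff = eff))
  }
  if (family == "linear") {
    eff_lin <- sigma * dmax / bmd
    if (eff_lin < eff_range[1] || eff_lin > eff_range[2]) return(NULL)
    f <- unit_shape("linear", numeric(0), dmax)
    return(list(mu = function(d) baseline + dir * eff_lin * f(d),
                eff = eff_lin))
  }
  aux <- calibrate_shape(family, bmd, sigma / eff, dmax)
  if (is.null(aux)) return(NULL)
  f <- unit_shape(family, aux, dmax)
  list(mu = function(d) baseline + dir * eff * f(d), eff = eff)
}

#' Generate a synthetic dose-response study with known truth
#'
#' Responsive probesets follow their assigned model family with the mean
#' curve crossing the 1-SD benchmark response exactly at the recorded true
#' BMD; non-responsive probesets are flat baseline plus Gaussian noise.
#' Up/down direction is sampled 50/50.
#'
#' @param config a [synthetic_study_config()].
#' @return list with `study` (a [dose_response_study()]) and `truth`, a data
#'   frame with columns `probeset_id`, `true_bmd`, `true_model`,
#'   `true_direction` ("up"/"down") and `effect_size` (realized top-dose
#'   absolute log2 change) for the responsive probesets.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(config$seed)
  dl <- config$dose_levels
  dmax <- max(dl)
  doses <- rep(dl, each = config$n_replicates)
  n <- length(doses)
  ids <- sprintf("probe_%04d", seq_len(config$n_probesets))
  resp <- seq_len(config$n_responsive)
  fam_w <- config$model_family_weights[bmd_model_names()]
  fam_w[is.na(fam_w)] <- 0

  mat <- matrix(NA_real_, config$n_probesets, n,
                dimnames = list(ids, sprintf("d%s_r%d", doses,
                                             sequence(rep(config$n_replicates,
                                                          length(dl))))))
  truth <- data.frame(probeset_id = character(0), true_bmd = numeric(0),
                      true_model = character(0), true_direction = character(0),
                      effect_size = numeric(0), stringsAsFactors = FALSE)
  baselines <- stats::runif(config$n_probesets, config$baseline_range[1],
                            config$baseline_range[2])
  for (i in seq_len(config$n_probesets)) {
    mu <- rep(baselines[i], n)
    if (i %in% resp) {
      # The occasional draw admits no family (a true BMD within a fraction
      # of a percent of the top dose demands an unrepresentably sharp
      # curve); such draws are rejected and redrawn, trimming a vanishing
      # sliver off the log-uniform BMD distribution.
      pick <- NULL
      dir <- if (stats::runif(1) < 0.5) 1 else -1
      for (attempt in 1:50) {
        bmd <- exp(stats::runif(1, log(config$true_bmd_range[1]),
                                log(config$true_bmd_range[2])))
        eff <- stats::runif(1, config$effect_size_range[1],
                            config$effect_size_range[2])
        fams <- sample(names(fam_w)[fam_w > 0],
                       prob = fam_w[fam_w > 0] / sum(fam_w))
        for (fam in fams) {
          cal <- calibrate_curve(fam, bmd, eff, config$noise_sd, dmax,
                                 baselines[i], dir,
                                 config$effect_size_range)
          if (!is.null(cal)) {
            pick <- list(fam = fam, cal = cal)
            break
          }
        }
        if (!is.null(pick)) break
      }
      if (is.null(pick))
        stop("infeasible calibration: no model family can cross the ",
             "benchmark response at the sampled true BMDs; widen ",
             "effect_size_range or true_bmd_range")
      mu <- pick$cal$mu(doses)
      truth <- rbind(truth, data.frame(
        probeset_id = ids[i], true_bmd = bmd, true_model = pick$fam,
        true_direction = if (dir > 0) "up" else "down",
        effect_size = pick$cal$eff, stringsAsFactors = FALSE))
    }
    mat[i, ] <- mu + stats::rnorm(n, sd = config$noise_sd)
  }
  study <- dose_response_study(mat, doses,
                               sprintf("synthetic_seed%d", config$seed))
  list(study = study, truth = truth)
}

#' Generate a random gene set structure
#'
#' Samples `n_sets` gene sets from a gene universe. In `overlap = "allowed"`
#' mode each set is sampled independently (a gene may belong to several
#' sets); in `overlap = "disjoint"` mode sets are pairwise disjoint, so each
#' gene occurs in at most one set.
#'
#' @param n_sets number of gene sets.
#' @param set_sizes either a single integer (all sets that size), an integer
#'   vector of length `n_sets`, or a function `f(n)` returning `n` sizes.
#' @param gene_universe character vector of gene ids to sample from.
#' @param overlap `"allowed"` or `"disjoint"`.
#' @param seed integer seed.
#' @param probe_to_gene optional probe map data frame to attach; defaults to
#'   an identity map (one probeset per universe gene, id `probe_<gene>`).
#' @param set_prefix prefix for generated set ids.
#' @return a [gene_set_structure()].
#' @export
simulate_structure <- function(n_sets, set_sizes, gene_universe,
                               overlap = c("allowed", "disjoint"),
                               seed = 1L, probe_to_gene = NULL,
                               set_prefix = "set") {
  overlap <- match.arg(overlap)
  set.seed(seed)
  gene_universe <- as.character(gene_universe)
  sizes <- if (is.function(set_sizes)) as.integer(set_sizes(n_sets))
           else if (length(set_sizes) == 1) rep(as.integer(set_sizes), n_sets)
           else as.integer(set_sizes)
  if (length(sizes) != n_sets) stop("need one size per set")
  if (any(sizes < 1)) stop("set sizes must be >= 1")
  if (any(sizes > length(gene_universe)))
    stop("a set size exceeds the gene universe")
  ids <- sprintf("%s_%03d", set_prefix, seq_len(n_sets))
  if (overlap == "disjoint") {
    if (sum(sizes) > length(gene_universe))
      stop("disjoint sets infeasible: total size exceeds the gene universe")
    pool <- sample(gene_universe, sum(sizes))
    members <- split(pool, rep(seq_len(n_sets), sizes))
    names(members) <- ids
  } else {
    members <- stats::setNames(
      lapply(sizes, function(s) sample(gene_universe, s)), ids)
  }
  if (is.null(probe_to_gene))
    probe_to_gene <- data.frame(
      probeset_id = paste0("probe_", gene_universe),
      gene_id = gene_universe, stringsAsFactors = FALSE)
  gene_set_structure(probe_to_gene, members)
}

#' Generate a synthetic probeset-to-gene map
#'
#' Assigns each probeset a primary gene drawn from `n_genes` gene ids (so
#' genes may be measured by several probesets when `n_genes <
#' length(probesets)`), and maps a small fraction of probesets to a second
#' gene to emulate ambiguous probes, which downstream aggregation excludes.
#'
#' @param probesets character vector of probeset ids.
#' @param n_genes number of distinct genes.
#' @param multi_gene_fraction fraction of probesets mapped to two genes.
#' @param seed integer seed.
#' @param gene_prefix prefix for generated gene ids.
#' @return data frame with columns `probeset_id`, `gene_id`.
#' @export
simulate_probe_map <- function(probesets, n_genes,
                               multi_gene_fraction = 0.02, seed = 1L,
                               gene_prefix = "gene") {
  set.seed(seed)
  genes <- sprintf("%s_%04d", gene_prefix, seq_len(n_genes))
  primary <- sample(genes, length(probesets), replace = TRUE)
  pm <- data.frame(probeset_id = as.character(probesets), gene_id = primary,
                   stringsAsFactors = FALSE)
  n_multi <- round(multi_gene_fraction * length(probesets))
  if (n_multi > 0) {
    which_multi <- sample(seq_along(probesets), n_multi)
    second <- vapply(which_multi, function(i)
      sample(setdiff(genes, primary[i]), 1), character(1))
    pm <- rbind(pm, data.frame(probeset_id = probesets[which_multi],
                               gene_id = second, stringsAsFactors = FALSE))
  }
  pm[order(pm$probeset_id), , drop = FALSE]
}
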