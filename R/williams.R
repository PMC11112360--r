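#' Prefilter parameters
#'
#' Settings for the dose-responsiveness screen applied before any BMD
#' modeling: a Williams trend test p-value threshold and an absolute
#' linear-scale fold-change threshold, applied conjunctively.
#'
#' @param p_threshold significance level for the trend test (default 0.05).
#' @param fc_threshold linear-scale absolute fold change that must be
#'   exceeded (default 1.5).
#' @param n_permutations Monte-Carlo permutations for the p-value
#'   (default 1000, minimum 100).
#' @param seed integer seed for the permutation draw, or `NULL`.
#' @return a list of class `prefilter_params`.
#' @export
prefilter_params <- function(p_threshold = 0.05, fc_threshold = 1.5,
                             n_permutations = 1000, seed = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1, fc_threshold >= 1,
            n_permutations >= 100)
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "prefilter_params")
}

# Williams-type trend statistic for rows of a value matrix sharing one
# column-to-group assignment. The amalgamated mean of the highest dose group
# under the monotone-increasing constraint equals the maximum over suffix
# weighted means of the treated groups (pool-adjacent-violators identity for
# the last element); mirrored with a minimum for the decreasing direction.
# The two-sided statistic is the larger of the directional t ratios.
williams_stat_rows <- function(V, gi) {
  G <- length(gi$n)
  N <- sum(gi$n)
  means <- matrix(NA_real_, nrow(V), G)
  for (g in seq_len(G)) {
    cols <- gi$idx[[g]]
    means[, g] <- if (length(cols) == 1) V[, cols]
                  else rowMeans(V[, cols, drop = FALSE])
  }
  ssw <- rowSums(V^2) - drop(means^2 %*% gi$n)
  s2 <- pmax(ssw / (N - G), 0)
  se <- sqrt(s2 * (1 / gi$n[G] + 1 / gi$n[1]))
  # suffix weighted means over treated groups (columns 2..G)
  cs <- rep(0, nrow(V)); cw <- 0
  up <- rep(-Inf, nrow(V)); dn <- rep(Inf, nrow(V))
  for (g in G:2) {
    cs <- cs + gi$n[g] * means[, g]
    cw <- cw + gi$n[g]
    sm <- cs / cw
    up <- pmax(up, sm)
    dn <- pmin(dn, sm)
  }
  t_up <- (up - means[, 1]) / se
  t_dn <- (means[, 1] - dn) / se
  list(stat = pmax(t_up, t_dn), s2 = s2, means = means)
}

#' Williams trend test with a permutation p-value
#'
#' Computes a Williams-type trend statistic (isotonic amalgamated mean of the
#' highest dose group versus control, maximized over both monotone
#' directions) and returns a Monte-Carlo permutation p-value with the +1
#' correction: p = (1 + #\{T_perm >= T_obs\}) / (n_permutations + 1).
#'
#' @param values numeric per-sample responses for one probeset.
#' @param doses numeric per-sample doses; at least 3 dose groups with at
#'   least 2 samples each, control (dose 0) present.
#' @param params a [prefilter_params()].
#' @return the permutation p-value, with the observed statistic attached as
#'   attribute `"statistic"`. Rows with zero pooled within-group variance
#'   raise a condition of class `tpod_degenerate_error`.
#' @export
williams_trend_pvalue <- function(values, doses, params = prefilter_params()) {
  gi <- group_index(doses)
  if (length(gi$levels) < 3) stop("need at least 3 dose groups")
  if (any(gi$n < 2)) stop("need at least 2 samples per group")
  if (gi$levels[1] != 0) stop("control group (dose 0) required")
  obs <- williams_stat_rows(matrix(values, nrow = 1), gi)
  if (obs$s2 <= .Machine$double.eps * mean(values^2)) {
    cond <- structure(
      class = c("tpod_degenerate_error", "error", "condition"),
      list(message = "zero pooled within-group variance",
           call = sys.call(),
           means_differ = diff(range(obs$means)) > 0))
    stop(cond)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- length(values)
  B <- params$n_permutations
  perm <- matrix(values[vapply(seq_len(B), function(i) sample.int(n),
                               integer(n))], nrow = B, byrow = TRUE)
  tp <- williams_stat_rows(perm, gi)$stat
  p <- (1 + sum(tp >= obs$stat - 1e-12)) / (B + 1)
  attr(p, "statistic") <- as.numeric(obs$stat)
  p
}

#' Maximum absolute fold change versus control
#'
#' Values are log2 intensities; the fold change of each treated group is
#' `2^|mean_g - mean_control|` and the maximum over treated groups is
#' returned (always on the linear scale, >= 1).
#'
#' @inheritParams williams_trend_pvalue
#' @return linear-scale fold change.
#' @export
max_abs_fold_change <- function(values, doses) {
  gm <- group_means(values, doses)
  lev <- sort(unique(doses))
  if (lev[1] != 0) stop("control group (dose 0) required")
  2^max(abs(gm[-1] - gm[1]))
}

#' Identify dose-responsive probesets
#'
#' A probeset passes the prefilter iff its Williams trend permutation
#' p-value is below `p_threshold` AND its maximum absolute fold change
#' exceeds `fc_threshold` (both criteria, conjunctively). Zero-variance
#' probesets pass iff their group means differ.
#'
#' @param study a [dose_response_study()].
#' @param params a [prefilter_params()].
#' @return character vector of passing probeset ids, in study order, with a
#'   data frame of per-probeset `p` and `fold_change` attached as attribute
#'   `"detail"`.
#' @export
prefilter <- function(study, params = prefilter_params()) {
  validate_study(study)
  gi <- group_index(study$doses)
  if (!is.null(params$seed)) set.seed(params$seed)
  inner <- prefilter_params(params$p_threshold, params$fc_threshold,
                            params$n_permutations, seed = NULL)
  ids <- study$probeset_ids
  p <- numeric(length(ids))
  fc <- numeric(length(ids))
  for (i in seq_along(ids)) {
    v <- study$matrix[i, ]
    fc[i] <- max_abs_fold_change(v, study$doses)
    p[i] <- tryCatch(
      as.numeric(williams_trend_pvalue(v, study$doses, inner)),
      tpod_degenerate_error = function(e) if (e$means_differ) 0 else 1)
  }
  pass <- p < params$p_threshold & fc > params$fc_threshold
  out <- ids[pass]
  attr(out, "detail") <- data.frame(probeset_id = ids, p = p,
                                    fold_change = fc, pass = pass,
                                    stringsAsFactors = FALSE)
  out
}
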