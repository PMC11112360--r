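#' Parameters for the distribution-based tPOD estimators
#'
#' @param min_probesets minimum number of BMD values required before any
#'   distribution-based method reports a tPOD (default 25).
#' @param percentiles percentiles used by the percentile methods.
#' @param rank order statistic used by the rank method (default 25).
#' @param kde_min_bandwidth lower bound on the kernel bandwidth, in log10
#'   mg/kg/d (default 0.015).
#' @param mode_min_density minimum density a local maximum must reach to
#'   count as a mode (default 0.055). Interpreted as an absolute density on
#'   the log10-dose axis when `mode_density_scale = "absolute"` (densities
#'   integrate to 1), or as a fraction of the peak density when
#'   `"relative"`.
#' @param mode_density_scale `"absolute"` (default) or `"relative"`.
#' @param kneedle_sensitivity sensitivity of the knee detector (default 1);
#'   larger values demand a more pronounced knee.
#' @param kde_grid_n evaluation grid size for the density (default 512).
#' @return a list of class `distribution_params`.
#' @export
distribution_params <- function(min_probesets = 25, percentiles = c(5, 10),
                                rank = 25, kde_min_bandwidth = 0.015,
                                mode_min_density = 0.055,
                                mode_density_scale = c("absolute", "relative"),
                                kneedle_sensitivity = 1,
                                kde_grid_n = 512) {
  mode_density_scale <- match.arg(mode_density_scale)
  stopifnot(min_probesets >= 1, kde_min_bandwidth > 0, mode_min_density > 0)
  structure(list(min_probesets = as.integer(min_probesets),
                 percentiles = percentiles, rank = as.integer(rank),
                 kde_min_bandwidth = kde_min_bandwidth,
                 mode_min_density = mode_min_density,
                 mode_density_scale = mode_density_scale,
                 kneedle_sensitivity = kneedle_sensitivity,
                 kde_grid_n = as.integer(kde_grid_n)),
            class = "distribution_params")
}

check_bmds <- function(bmds) {
  bmds <- as.numeric(bmds)
  if (any(!is.finite(bmds)) || any(bmds <= 0))
    stop("BMD values must be finite and positive")
  bmds
}

#' Percentile tPOD
#'
#' The q-th percentile of the BMD values under the linear-interpolation
#' quantile convention; `NA` when fewer than `min_probesets` values are
#' available.
#'
#' @param bmds positive BMD values.
#' @param q percentile (e.g. 5 or 10).
#' @param params a [distribution_params()].
#' @return the tPOD, or `NA_real_`.
#' @export
pod_percentile <- function(bmds, q, params = distribution_params()) {
  bmds <- check_bmds(bmds)
  if (length(bmds) < params$min_probesets) return(NA_real_)
  unname(stats::quantile(bmds, q / 100, type = 7))
}

#' Rank tPOD
#'
#' The r-th smallest BMD value (duplicates counted); no tPOD when fewer than
#' `r` values exist.
#'
#' @param bmds positive BMD values.
#' @param r rank (default 25).
#' @return the tPOD, or `NA_real_`.
#' @export
pod_rank <- function(bmds, r = 25) {
  bmds <- check_bmds(bmds)
  if (length(bmds) < r) return(NA_real_)
  sort(bmds)[r]
}

#' First-mode tPOD
#'
#' Gaussian kernel density of log10(BMD), with bandwidth the larger of the
#' Sheather-Jones estimate and `kde_min_bandwidth`, evaluated on a
#' `kde_grid_n`-point grid spanning the data range plus three bandwidths.
#' Modes are local density maxima reaching `mode_min_density`; the tPOD is
#' 10^(location of the lowest-dose mode). `NA` when no local maximum
#' qualifies or fewer than `min_probesets` values are available.
#'
#' @inheritParams pod_percentile
#' @return the tPOD, or `NA_real_`.
#' @export
pod_first_mode <- function(bmds, params = distribution_params()) {
  bmds <- check_bmds(bmds)
  if (length(bmds) < params$min_probesets) return(NA_real_)
  x <- log10(bmds)
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) NA_real_)
  if (!is.finite(bw)) bw <- params$kde_min_bandwidth
  bw <- max(bw, params$kde_min_bandwidth)
  den <- stats::density(x, bw = bw, kernel = "gaussian",
                        n = params$kde_grid_n, cut = 3)
  y <- den$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  thr <- if (params$mode_density_scale == "absolute") params$mode_min_density
         else params$mode_min_density * max(y)
  cand <- which(is_max & y >= thr)
  if (length(cand) == 0) return(NA_real_)
  10^den$x[cand[1]]
}

# Knee-point detection on a normalized curve (Kneedle). The curve is
# interpolated onto a uniform grid on [0,1] and lightly smoothed (the
# published algorithm smooths before differencing; without it, sampling
# noise in an empirical accumulation curve fires spurious early knees).
# The difference between the smoothed curve and the diagonal is scanned for
# local maxima. Orientation is adaptive: the dominant bend (the side on
# which the curve departs farthest from the diagonal) is used, so both
# flat-then-steep and steep-then-flat accumulation shapes are handled. A
# local maximum is declared a knee when the difference later drops below
# (maximum - sensitivity * mean grid spacing) before the next local maximum;
# if the largest departure never exceeds sensitivity * mean spacing (a
# near-straight curve) no knee exists.
kneedle <- function(x, y, sensitivity = 1, n_grid = 512) {
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0) return(NA_real_)
  xn <- (x - rx[1]) / diff(rx)
  yn <- (y - ry[1]) / diff(ry)
  xs <- seq(0, 1, length.out = n_grid)
  ys <- stats::approx(xn, yn, xout = xs, ties = list("ordered", max),
                      rule = 2)$y
  w <- max(3, 2 * floor(n_grid / 64) + 1)
  ys_s <- stats::filter(ys, rep(1 / w, w), sides = 2)
  pad <- (w - 1) / 2
  ys_s[seq_len(pad)] <- ys[seq_len(pad)]
  ys_s[n_grid - seq_len(pad) + 1] <- ys[n_grid - seq_len(pad) + 1]
  ys_s <- as.numeric(ys_s)
  d_knee <- ys_s - xs
  d_elbow <- xs - ys_s
  d <- if (max(d_knee) >= max(d_elbow)) d_knee else d_elbow
  spacing <- 1 / (n_grid - 1)
  if (max(d) <= sensitivity * spacing) return(NA_real_)
  n <- length(d)
  lmx <- which(c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] &
                        d[2:(n - 1)] >= d[3:n], FALSE))
  if (length(lmx) == 0) lmx <- which.max(d)
  for (j in seq_along(lmx)) {
    i <- lmx[j]
    thr <- d[i] - sensitivity * spacing
    upto <- if (j < length(lmx)) lmx[j + 1] else n
    seg <- d[i:upto]
    if (any(seg < thr)) return(rx[1] + xs[i] * diff(rx))
  }
  NA_real_
}

#' Accumulation-curve maximum-curvature tPOD
#'
#' Builds the accumulation curve (sorted log10 BMD versus cumulative
#' fraction), min-max normalizes both axes, and locates the knee with the
#' Kneedle algorithm; the tPOD is 10^(knee position). Degenerate input (all
#' BMDs equal) returns the common value; a near-straight accumulation curve
#' yields no knee and `NA`.
#'
#' @inheritParams pod_percentile
#' @return the tPOD, or `NA_real_`.
#' @export
pod_acc_curvature <- function(bmds, params = distribution_params()) {
  bmds <- check_bmds(bmds)
  if (length(bmds) < params$min_probesets) return(NA_real_)
  if (diff(range(bmds)) == 0) return(bmds[1])
  x <- sort(log10(bmds))
  y <- seq_along(x) / length(x)
  knee <- kneedle(x, y, params$kneedle_sensitivity, params$kde_grid_n)
  if (!is.finite(knee)) return(NA_real_)
  10^knee
}

#' All five distribution-based tPODs
#'
#' Runs PODAcc (accumulation-curve knee), FirstMode (KDE first mode), Perc05,
#' Perc10 and Rank25 on one molecule's BMD list. All five return no tPOD when
#' fewer than `min_probesets` BMD values are available.
#'
#' @param bmds positive BMD values (one molecule).
#' @param params a [distribution_params()].
#' @param molecule_id label recorded in the results.
#' @return data frame with one row per method: `molecule_id`, `method`,
#'   `tpod`, `n_probesets_with_bmd`, `driver` (always NA here).
#' @export
distribution_tpods <- function(bmds, params = distribution_params(),
                               molecule_id = "molecule") {
  bmds <- check_bmds(bmds)
  n <- length(bmds)
  enough <- n >= params$min_probesets
  vals <- c(
    PODAcc = if (enough) pod_acc_curvature(bmds, params) else NA_real_,
    FirstMode = if (enough) pod_first_mode(bmds, params) else NA_real_,
    Perc05 = if (enough) pod_percentile(bmds, params$percentiles[1], params)
             else NA_real_,
    Perc10 = if (enough) pod_percentile(bmds, params$percentiles[2], params)
             else NA_real_,
    Rank25 = if (enough) pod_rank(bmds, params$rank) else NA_real_)
  do.call(rbind, lapply(names(vals), function(m)
    tpod_result(molecule_id, m, vals[[m]], n)))
}
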