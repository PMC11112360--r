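# Shared fixtures, built in code. Expensive objects (the standard synthetic
# study with its full BMD run) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A tiny 3-probeset, 3-dose-group study used by I/O and shape tests.
tiny_study <- function() {
  m <- rbind(
    p1 = c(8.0, 8.1, 7.9, 8.5, 8.6, 8.4, 9.0, 9.1, 8.9),
    p2 = c(7.0, 7.2, 7.1, 7.0, 7.1, 7.2, 7.1, 7.0, 7.2),
    p3 = c(10.0, 10.1, 9.9, 9.5, 9.4, 9.6, 9.0, 9.1, 8.9))
  colnames(m) <- paste0("s", 1:9)
  dose_response_study(m, rep(c(0, 10, 100), each = 3), "tiny")
}

# A small gene set structure with a known multi-gene probeset.
tiny_structure <- function() {
  pm <- data.frame(
    probeset_id = c("p1", "p2", "p3", "p3", "p4", "p5"),
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g5"),
    stringsAsFactors = FALSE)
  gene_set_structure(pm, list(S1 = c("g1", "g2"), S2 = c("g4", "g5", "g6")),
                     c(S1 = "setA", S2 = "setB"))
}

# A modest synthetic study for pipeline-level unit tests (fast: ~10 s).
small_pipeline_fixture <- function() {
  cached("small_pipeline", {
    cfg <- synthetic_study_config(
      n_probesets = 80, n_responsive = 50, n_replicates = 3,
      dose_levels = c(0, 3, 10, 30, 100, 300, 1000), seed = 31)
    sim <- simulate_study(cfg)
    passing <- prefilter(sim$study,
                         prefilter_params(n_permutations = 200, seed = 32))
    records <- run_bmd_analysis(sim$study, passing)
    pm <- simulate_probe_map(sim$study$probeset_ids, n_genes = 70, seed = 33)
    st <- simulate_structure(
      40, function(n) pmax(3, pmin(30, round(stats::rlnorm(n, log(8), 0.7)))),
      unique(pm$gene_id), "allowed", seed = 34, probe_to_gene = pm)
    list(cfg = cfg, sim = sim, passing = passing, records = records,
         structure = st)
  })
}

# The standard synthetic study: 500 probesets, 300 responsive, 5 replicates,
# noise SD 0.1 (the parameter-recovery reference conditions). Expensive
# (~1 min); shared by the acceptance checks.
standard_study_fixture <- function(seed = 11) {
  cached(paste0("standard_study_", seed), {
    cfg <- synthetic_study_config(seed = seed)
    sim <- simulate_study(cfg)
    passing <- prefilter(sim$study, prefilter_params(seed = seed + 1000))
    records <- run_bmd_analysis(sim$study, passing)
    pm <- simulate_probe_map(sim$study$probeset_ids, n_genes = 420,
                             seed = seed + 2000)
    st <- simulate_structure(
      150,
      function(n) pmax(3, pmin(120, round(stats::rlnorm(n, log(12), 0.9)))),
      unique(pm$gene_id), "allowed", seed = seed + 3000, probe_to_gene = pm)
    list(cfg = cfg, sim = sim, passing = passing, records = records,
         structure = st)
  })
}

# A whole-transcriptome-like molecule for the randomization study:
# responders are a minority of the platform (330 of 1200 probesets), as in
# real cohorts, with a structure of GOBP-like set:gene ratio. Expensive
# (~1.5 min each); cached.
randomization_fixture <- function(s) {
  cached(paste0("randomization_", s), {
    cfg <- synthetic_study_config(n_probesets = 1200, n_responsive = 330,
                                  seed = 100 + s)
    sim <- simulate_study(cfg)
    passing <- prefilter(sim$study, prefilter_params(seed = 200 + s))
    records <- run_bmd_analysis(sim$study, passing)
    pm <- simulate_probe_map(sim$study$probeset_ids, n_genes = 1000,
                             seed = 300 + s)
    st <- simulate_structure(
      450,
      function(n) pmax(3, pmin(120, round(stats::rlnorm(n, log(12), 0.9)))),
      unique(pm$gene_id), "allowed", seed = 400 + s, probe_to_gene = pm)
    list(sim = sim, records = records, structure = st)
  })
}

# Independent interpolated-quantile oracle (R type-7 convention, coded from
# the order-statistic definition rather than through stats::quantile).
quantile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent Williams statistic for a single dataset: explicit isotonic
# amalgamation over treated groups by pool-adjacent-violators, both
# directions, pooled within-group variance.
williams_oracle_stat <- function(values, doses) {
  lev <- sort(unique(doses))
  ms <- sapply(lev, function(l) mean(values[doses == l]))
  ns <- sapply(lev, function(l) sum(doses == l))
  s2 <- sum((values - ms[match(doses, lev)])^2) / (length(values) - length(lev))
  pava <- function(y, w) {
    y <- as.numeric(y); w <- as.numeric(w)
    i <- 2
    while (i <= length(y)) {
      if (y[i] < y[i - 1]) {
        yw <- (y[i] * w[i] + y[i - 1] * w[i - 1]) / (w[i] + w[i - 1])
        y[i - 1] <- yw; w[i - 1] <- w[i] + w[i - 1]
        y <- y[-i]; w <- w[-i]
        i <- max(i - 1, 2)
      } else i <- i + 1
    }
    list(y = y, w = w)
  }
  tr <- 2:length(lev)
  up <- pava(ms[tr], ns[tr])
  dn <- pava(-ms[tr], ns[tr])
  se <- sqrt(s2 * (1 / ns[length(ns)] + 1 / ns[1]))
  max((up$y[length(up$y)] - ms[1]) / se,
      (ms[1] - (-dn$y[length(dn$y)])) / se)
}

# Discrete-curvature oracle for the accumulation-curve knee. The normalized
# curve is reduced to a coarse polyline (each node averages many data
# points, which suppresses the sampling noise of the empirical CDF); the
# discrete curvature at a node is the turn of the tangent angle per unit
# arc length, the finite-difference form of |y''|/(1+y'^2)^1.5. The knee is
# the curvature-weighted centroid of the maximal node and its neighbors
# (parabolic-peak refinement); `step` is the node spacing, the oracle's
# resolution.
curvature_knee_oracle <- function(bmds, n_grid = 31) {
  x <- sort(log10(bmds))
  y <- seq_along(x) / length(x)
  rx <- range(x)
  xn <- (x - rx[1]) / diff(rx)
  yn <- (y - min(y)) / diff(range(y))
  xs <- seq(0, 1, length.out = n_grid)
  ys <- stats::approx(xn, yn, xout = xs, ties = list("ordered", max),
                      rule = 2)$y
  dx <- diff(xs); dy <- diff(ys)
  theta <- atan2(dy, dx)
  ds <- sqrt(dx^2 + dy^2)
  kap <- abs(diff(theta)) / ((ds[-1] + ds[-length(ds)]) / 2)
  i <- which.max(kap)
  nb <- max(1, i - 1):min(length(kap), i + 1)
  pos <- rx[1] + xs[nb + 1] * diff(rx)
  list(knee = sum(pos * kap[nb]) / sum(kap[nb]),
       step = (xs[2] - xs[1]) * diff(rx))
}

# A sharp-onset accumulation curve: a few low-dose stragglers, a tight
# cluster at the onset (the knee), then a long tail. The knee is interior
# to the BMD range so the discrete-curvature scan can see it, and the low
# and tail segments are quasi-regular (evenly spaced with seeded jitter):
# the knee is then the only place where the curve bends, which is the
# regime in which "the point of maximum curvature" is unambiguous and the
# two detectors must agree.
onset_curve <- function(onset, nlow, m, ntail) {
  low <- seq(onset - 1.5, onset - 0.15, length.out = nlow) +
    stats::runif(nlow, -0.02, 0.02)
  tail <- seq(onset + 0.05, onset + 2.5, length.out = ntail) +
    stats::runif(ntail, -0.005, 0.005)
  c(10^low, 10^(onset + stats::rnorm(m, 0, 0.005)), 10^tail)
}
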