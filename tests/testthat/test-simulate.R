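test_that("generated studies have the configured shape and truth bookkeeping", {
  cfg <- synthetic_study_config(n_probesets = 100, n_responsive = 30,
                                dose_levels = c(0, 10, 100, 1000),
                                n_replicates = 3, seed = 7)
  sim <- simulate_study(cfg)
  expect_equal(dim(sim$study$matrix), c(100, 12))
  expect_equal(nrow(sim$truth), 30)
  expect_true(all(sim$truth$true_bmd >= 1 & sim$truth$true_bmd <= 1000))
  expect_true(all(sim$truth$true_model %in% bmd_model_names()))
  expect_setequal(sim$truth$probeset_id, sim$study$probeset_ids[1:30])
})

test_that("generation is deterministic in the seed", {
  cfg1 <- synthetic_study_config(n_probesets = 50, n_responsive = 20, seed = 5)
  cfg2 <- synthetic_study_config(n_probesets = 50, n_responsive = 20, seed = 6)
  a <- simulate_study(cfg1)
  b <- simulate_study(cfg1)
  c <- simulate_study(cfg2)
  expect_identical(a$study$matrix, b$study$matrix)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$study$matrix, c$study$matrix))
})

test_that("linear truth satisfies the closed-form 1-SD BMR relation", {
  # for a straight line with slope beta1, the BMR crossing is sigma/|beta1|,
  # so effect_size * true_bmd = sigma * dmax by construction
  w <- stats::setNames(c(0, 0, 1, 0, 0, 0, 0, 0), bmd_model_names())
  cfg <- synthetic_study_config(
    n_probesets = 30, n_responsive = 30, noise_sd = 0.1,
    model_family_weights = w, true_bmd_range = c(40, 100),
    effect_size_range = c(1, 2.5), seed = 9)
  sim <- simulate_study(cfg)
  expect_true(all(sim$truth$true_model == "linear"))
  dmax <- max(cfg$dose_levels)
  expect_equal(sim$truth$effect_size * sim$truth$true_bmd,
               rep(0.1 * dmax, 30), tolerance = 1e-9)
})

test_that("every responsive mean curve crosses the BMR exactly at its true BMD", {
  # regenerate the noiseless means by averaging many replicates away: use a
  # direct check instead -- refit the curve family to the noise-free means is
  # circular, so verify via high-replicate group means straddling the BMR
  cfg <- synthetic_study_config(n_probesets = 40, n_responsive = 40,
                                n_replicates = 100, noise_sd = 0.1, seed = 13)
  sim <- simulate_study(cfg)
  gm0 <- apply(sim$study$matrix[, sim$study$doses == 0, drop = FALSE], 1, mean)
  for (i in seq_len(20)) {
    tr <- sim$truth[i, ]
    lev <- sort(unique(sim$study$doses))
    gm <- sapply(lev, function(l)
      mean(sim$study$matrix[tr$probeset_id, sim$study$doses == l]))
    dep <- abs(gm - gm[1])
    # departure at dose levels below the true BMD must stay below ~1 BMR and
    # above it must exceed it (up to replicate noise of ~0.01 * sqrt(2))
    below <- lev > 0 & lev < tr$true_bmd / 1.2
    above <- lev > tr$true_bmd * 1.2
    if (any(below)) expect_lt(max(dep[below]), 0.1 + 0.05)
    if (any(above)) expect_gt(max(dep[above]), 0.1 - 0.05)
  }
})

test_that("infeasible effect sizes are rejected at configuration", {
  expect_error(
    synthetic_study_config(noise_sd = 0.5, effect_size_range = c(0.2, 0.4)),
    "infeasible calibration")
})

test_that("disjoint structures never repeat a gene; overlapping ones may", {
  genes <- sprintf("g%04d", 1:1000)
  st <- simulate_structure(50, 10, genes, "disjoint", seed = 3)
  cnt <- table(unlist(st$set_members))
  expect_true(all(cnt == 1))
  expect_equal(length(st$set_members), 50)
  expect_true(all(lengths(st$set_members) == 10))
  expect_error(simulate_structure(200, 10, genes[1:100], "disjoint", seed = 1),
               "infeasible")
  st2 <- simulate_structure(50, 10, genes, "allowed", seed = 3)
  expect_equal(unname(lengths(st2$set_members)), rep(10L, 50))
})

test_that("overlapping membership counts follow the binomial sampling model", {
  # each gene's number of memberships is Binomial(n_sets, size/|universe|)
  genes <- sprintf("g%04d", 1:1000)
  counts <- integer(0)
  for (s in 1:40) {
    st <- simulate_structure(50, 10, genes, "allowed", seed = 1000 + s)
    tab <- table(factor(unlist(st$set_members), levels = genes))
    counts <- c(counts, as.integer(tab))
  }
  n <- length(counts)
  kmax <- 3
  obs <- vapply(0:kmax, function(k)
    if (k < kmax) sum(counts == k) else sum(counts >= k), numeric(1))
  pr <- stats::dbinom(0:kmax, 50, 10 / 1000)
  pr[kmax + 1] <- 1 - sum(pr[1:kmax])
  chi <- sum((obs - n * pr)^2 / (n * pr))
  expect_lt(chi, stats::qchisq(0.99, df = kmax))
})

test_that("two structure seeds differ, same seed repeats", {
  genes <- sprintf("g%03d", 1:200)
  a <- simulate_structure(20, 8, genes, "allowed", seed = 1)
  b <- simulate_structure(20, 8, genes, "allowed", seed = 1)
  c <- simulate_structure(20, 8, genes, "allowed", seed = 2)
  expect_identical(a$set_members, b$set_members)
  expect_false(identical(a$set_members, c$set_members))
})

test_that("synthetic probe maps expose multi-gene probesets at the requested rate", {
  probes <- sprintf("p%04d", 1:500)
  pm <- simulate_probe_map(probes, n_genes = 400, multi_gene_fraction = 0.04,
                           seed = 17)
  st <- gene_set_structure(pm, list(S = unique(pm$gene_id)))
  expect_equal(length(st$multi_gene_probesets), 20)
  expect_setequal(unique(pm$probeset_id), probes)
})
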