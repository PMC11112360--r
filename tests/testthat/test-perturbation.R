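test_that("randomized structures preserve the set-size multiset exactly", {
  fix <- small_pipeline_fixture()
  st <- fix$structure
  r1 <- randomize_structure(st, "overlap", seed = 1)
  expect_identical(lengths(r1$set_members), lengths(st$set_members))
  expect_identical(names(r1$set_members), names(st$set_members))
  expect_identical(r1$probe_to_gene, st$probe_to_gene)
  # same seed repeats; different seed differs
  r1b <- randomize_structure(st, "overlap", seed = 1)
  r2 <- randomize_structure(st, "overlap", seed = 2)
  expect_identical(r1$set_members, r1b$set_members)
  expect_false(identical(r1$set_members, r2$set_members))
})

test_that("no-overlap randomization uses each gene at most once", {
  genes <- sprintf("g%04d", 1:400)
  pm <- data.frame(probeset_id = paste0("p", genes), gene_id = genes)
  st <- simulate_structure(20, 12, genes, "disjoint", seed = 5,
                           probe_to_gene = pm)
  rn <- randomize_structure(st, "no_overlap", seed = 6)
  cnt <- table(unlist(rn$set_members))
  expect_true(all(cnt == 1))
  expect_identical(lengths(rn$set_members), lengths(st$set_members))
  # infeasible when total size exceeds the universe
  st_big <- simulate_structure(30, 12, genes, "allowed", seed = 7,
                               probe_to_gene = pm)
  small_universe <- genes[1:100]
  expect_error(randomize_structure(st_big, "no_overlap", seed = 1,
                                   universe = small_universe),
               "infeasible")
})

test_that("down-sampling counts and keep-list intersections are exact", {
  platform <- sprintf("p%05d", 1:31000)
  s1 <- reduction_scenario("S1", "random_fraction", fraction = 0.60)
  kept <- downsample_probesets(platform, s1, seed = 9)
  expect_length(kept, 18600)
  expect_true(all(kept %in% platform))
  expect_false(anyDuplicated(kept) > 0)
  # keep-list: intersection with the platform, deterministic
  kl <- c(sprintf("p%05d", 101:3500), sprintf("x%04d", 1:100))
  s3 <- reduction_scenario("S3", "keep_list", keep_list = kl)
  kept3 <- downsample_probesets(platform, s3, seed = 1)
  expect_length(kept3, 3400)
  expect_identical(kept3, downsample_probesets(platform, s3, seed = 99))
})

test_that("the at-least-half reporting rule is exact", {
  sm <- tpodkit:::summarize_sims("m", "x", c(1, 2, NA, NA, NA), 5)
  expect_false(sm$reported)  # 2 < ceiling(5/2)
  sm2 <- tpodkit:::summarize_sims("m", "x", c(1, 2, 4, NA, NA), 5)
  expect_true(sm2$reported)  # 3 >= 2.5
  expect_equal(sm2$median_tpod, 2)
  sm3 <- tpodkit:::summarize_sims("m", "x", c(NA, NA), 2)
  expect_false(sm3$reported)
  expect_true(is.na(sm3$median_tpod))
  # n_sims = 1: the median is that simulation's value
  sm4 <- tpodkit:::summarize_sims("m", "x", 3.3, 1)
  expect_equal(sm4$median_tpod, 3.3)
  expect_true(sm4$reported)
})

test_that("randomization studies aggregate and report fold changes", {
  fix <- small_pipeline_fixture()
  rr <- run_randomization_study(fix$records, fix$structure,
                                fix$sim$study$probeset_ids,
                                n_sims = 20, seed = 3, molecule_id = "m1")
  expect_length(rr$sim_tpods, 20)
  expect_equal(rr$summary$n_success, sum(!is.na(rr$sim_tpods)))
  if (rr$summary$reported) {
    expect_equal(rr$summary$median_tpod,
                 median(rr$sim_tpods, na.rm = TRUE))
    expect_equal(rr$summary$fold_change,
                 rr$summary$original_tpod / rr$summary$median_tpod)
  }
  # single simulation: median equals that simulation's tPOD
  rr1 <- run_randomization_study(fix$records, fix$structure,
                                 fix$sim$study$probeset_ids,
                                 n_sims = 1, seed = 4)
  expect_equal(rr1$summary$median_tpod, rr1$sim_tpods[1])
})

test_that("reduction studies restrict and never add records", {
  fix <- small_pipeline_fixture()
  s1 <- reduction_scenario("S1", "random_fraction", fraction = 0.6)
  rs <- run_reduction_study(fix$records, fix$structure,
                            fix$sim$study$probeset_ids, s1,
                            n_sims = 10, seed = 5)
  expect_equal(nrow(rs$sim_tpods), 10)
  expect_setequal(rs$summary$method,
                  c("geneset", "PODAcc", "FirstMode", "Perc05", "Perc10",
                    "Rank25"))
  # every simulated BMD list is a subset restriction: Rank25 can only rise
  r25 <- rs$sim_tpods[, "Rank25"]
  full_r25 <- rs$summary$original_tpod[rs$summary$method == "Rank25"]
  expect_true(all(is.na(r25) | r25 >= full_r25 - 1e-12))
  # keep-list scenarios run exactly once
  s3 <- reduction_scenario("S3", "keep_list",
                           keep_list = fix$sim$study$probeset_ids[1:60])
  rs3 <- run_reduction_study(fix$records, fix$structure,
                             fix$sim$study$probeset_ids, s3,
                             n_sims = 500, seed = 6)
  expect_equal(nrow(rs3$sim_tpods), 1)
  expect_equal(unique(rs3$summary$n_sims), 1)
})

test_that("harsher down-sampling reduces gene-set sensitivity more", {
  fix <- small_pipeline_fixture()
  run_scn <- function(frac, seed) {
    scn <- reduction_scenario(paste0("S", frac), "random_fraction",
                              fraction = frac)
    rs <- run_reduction_study(fix$records, fix$structure,
                              fix$sim$study$probeset_ids, scn,
                              pipeline = "geneset", n_sims = 25, seed = seed)
    rs$summary$n_success[rs$summary$method == "geneset"]
  }
  s1 <- run_scn(0.60, 11)
  s2 <- run_scn(0.113, 11)
  expect_lte(s2, s1)
  expect_gt(s1, 0)
})
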