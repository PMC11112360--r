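test_that("annotation TSVs round-trip and deduplicate", {
  st <- tiny_structure()
  fp <- withr::local_tempfile(fileext = ".tsv")
  fc <- withr::local_tempfile(fileext = ".tsv")
  write_gene_set_structure(st, fp, fc)
  st2 <- read_gene_set_structure(fp, fc)
  expect_equal(st2$set_members, st$set_members)
  expect_equal(st2$probe_to_gene, st$probe_to_gene)
  expect_identical(st2$multi_gene_probesets, "p3")

  # duplicated (set, gene) rows collapse to one membership
  cm <- utils::read.delim(fc, colClasses = "character")
  utils::write.table(rbind(cm, cm[1, ]), fc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  st3 <- read_gene_set_structure(fp, fc)
  expect_equal(st3$set_members, st$set_members)

  writeLines("probeset_id\tgene_id", fp)
  expect_error(read_gene_set_structure(fp, fc), "empty")
})

test_that("structure construction flags multi-gene probesets and drops empty sets", {
  pm <- data.frame(probeset_id = c("p1", "p2", "p3"),
                   gene_id = c("g1", "g1", "g2"))
  st <- gene_set_structure(pm, list(S1 = c("g1", "g2"), S0 = character(0)))
  expect_equal(length(st$set_members), 1L)
  expect_equal(sort(st$set_members$S1), c("g1", "g2"))
  expect_length(st$multi_gene_probesets, 0)

  pm2 <- rbind(pm, data.frame(probeset_id = "p1", gene_id = "g2"))
  st2 <- gene_set_structure(pm2, list(S1 = c("g1", "g2")))
  expect_identical(st2$multi_gene_probesets, "p1")
  # both mappings are retained in the probe map
  expect_equal(sum(st2$probe_to_gene$probeset_id == "p1"), 2L)
})

test_that("structure_stats computes unmapped percentages and is row-order invariant", {
  # platform of 10 probesets, 4 map into sets -> 60% unmapped
  pm <- data.frame(probeset_id = paste0("p", 1:10),
                   gene_id = paste0("g", 1:10))
  st <- gene_set_structure(pm, list(S1 = paste0("g", 1:4)))
  stats1 <- structure_stats(st, paste0("p", 1:10))
  expect_equal(stats1$pct_probesets_unmapped, 60)
  expect_equal(stats1$n_genes_covered, 4)

  # full coverage -> 0% unmapped
  st_full <- gene_set_structure(pm, list(S1 = paste0("g", 1:10)))
  expect_equal(structure_stats(st_full, paste0("p", 1:10))$pct_probesets_unmapped, 0)

  # shuffling annotation rows changes nothing
  pm_shuf <- pm[sample(nrow(pm)), ]
  st_shuf <- gene_set_structure(pm_shuf, list(S1 = paste0("g", c(3, 1, 4, 2))))
  expect_equal(structure_stats(st_shuf, paste0("p", 1:10)), stats1)
})

test_that("platform-restricted set sizes count only exposed genes", {
  st <- tiny_structure()
  # platform without p4/p5: S2 keeps no platform genes; g6 never on platform
  sizes <- platform_set_sizes(st, c("p1", "p2", "p3"))
  expect_equal(sizes[["S1"]], 2L)
  expect_equal(sizes[["S2"]], 0L)
  sizes_all <- platform_set_sizes(st, paste0("p", 1:5))
  expect_equal(sizes_all[["S2"]], 2L)
})

test_that("set-size histogram matches an independent one-pass counter", {
  fix <- small_pipeline_fixture()
  st <- fix$structure
  fp <- withr::local_tempfile(); fc <- withr::local_tempfile()
  write_gene_set_structure(st, fp, fc)
  cm <- utils::read.delim(fc, colClasses = "character")
  one_pass <- table(cm$set_id)
  expect_equal(as.integer(one_pass[names(st$set_members)]),
               unname(lengths(st$set_members)))
  expect_equal(table(as.integer(one_pass)),
               table(unname(lengths(st$set_members))))
})

test_that("generated structures hit a target coverage within 2% over seeded draws", {
  # 500 probesets map 1-1 to 500 genes; sets sample only a 250-gene pool, so
  # the expected unmapped share is 50%; the generator's own bookkeeping (the
  # realized set membership) must agree with structure_stats.
  probes <- sprintf("p%03d", 1:500)
  genes <- sprintf("g%03d", 1:500)
  pm <- data.frame(probeset_id = probes, gene_id = genes)
  pool <- genes[1:250]
  pcts <- vapply(1:100, function(s) {
    st <- simulate_structure(50, 25, pool, "allowed", seed = s,
                             probe_to_gene = pm)
    got <- structure_stats(st, probes)$pct_probesets_unmapped
    covered <- unique(unlist(st$set_members))
    book <- 100 * (1 - length(covered) / length(probes))
    expect_equal(got, book)
    got
  }, numeric(1))
  expect_lt(abs(mean(pcts) - 50), 2)
})

test_that("overlap counts across structures use union / common / unique set ops", {
  pm <- data.frame(probeset_id = "p1", gene_id = "g1")
  s1 <- gene_set_structure(pm, list(A = c("g1", "g2", "g3")))
  s2 <- gene_set_structure(pm, list(B = c("g2", "g3", "g4")))
  s3 <- gene_set_structure(pm, list(C = c("g3", "g5")))
  oc <- structure_overlap_counts(list(s1, s2, s3))
  expect_equal(oc$n_union, 5)
  expect_equal(oc$n_common_all, 1)   # g3
  expect_equal(oc$n_unique_single, 3) # g1, g4, g5
})
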