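manifest4 <- default_manifest(n_pd = 2, n_control = 2)

test_that("stimulation comparison plans have the intra + cross structure", {
  plan <- build_hfs_comparisons(manifest4, "PD")
  expect_equal(nrow(plan), 4)
  expect_equal(sum(plan$kind == "intra"), 2)
  expect_equal(sum(plan$kind == "cross"), 2)
  # experiments are stim chips, baselines non-stim
  hemis <- manifest4$hemisphere[match(plan$experiment, manifest4$sample_id)]
  expect_true(all(hemis == "stim"))
  hemis <- manifest4$hemisphere[match(plan$baseline, manifest4$sample_id)]
  expect_true(all(hemis == "nonstim"))
  expect_false(any(duplicated(plan[, c("experiment", "baseline")])))
  # 3 animals: 3 intra + 6 cross
  m3 <- default_manifest(n_pd = 3, n_control = 2)
  plan3 <- build_hfs_comparisons(m3, "PD")
  expect_equal(nrow(plan3), 9)
  expect_equal(sum(plan3$kind == "intra"), 3)
  # one animal: no cross-comparison possible
  m1 <- default_manifest(n_pd = 1, n_control = 2)
  expect_error(build_hfs_comparisons(m1, "PD"), "2 animals")
  # missing hemisphere is reported with the animal's name
  m_bad <- manifest4[!(manifest4$animal_id == "PD2" &
                         manifest4$hemisphere == "stim"), ]
  expect_error(build_hfs_comparisons(m_bad, "PD"), "PD2")
})

test_that("lesion comparison plans pair all non-stim chips across groups", {
  plan <- build_lesion_comparisons(manifest4)
  expect_equal(nrow(plan), 4)
  expect_true(all(plan$contrast == "lesion"))
  expect_equal(nrow(build_lesion_comparisons(default_manifest(1, 1))), 1)
  expect_equal(nrow(build_lesion_comparisons(default_manifest(3, 2))), 6)
  expect_error(build_lesion_comparisons(manifest4[manifest4$group == "PD", ]),
               "per group")
})

test_that("consensus filter applies the homonymous-call and slr rules", {
  calls <- rbind(g1 = c("D", "D", "D", "D"),
                 g2 = c("D", "D", "D", "NC"),
                 g3 = c("NC", "NC", "NC", "NC"),
                 g4 = c("D", "D", "D", "D"))
  slr <- rbind(g1 = c(-2.9, -2.8, -2.6, -2.5),
               g2 = c(-2.0, -1.8, -1.5, 0),
               g3 = c(0, 0, 0, 0),
               g4 = c(-2.0, -1.8, -0.5, -1.2))   # one slr inside the gate
  rec <- consensus_filter(calls, slr, required_count = 4)
  g1 <- rec[rec$probe_set_id == "g1", ]
  expect_true(g1$included)
  expect_equal(g1$D_count, 4)
  expect_equal(g1$I_count, 0)
  expect_equal(g1$mean_slr, -2.7)
  # three of four homonymous calls fail the strict rule
  expect_false(rec$included[rec$probe_set_id == "g2"])
  expect_false(rec$included[rec$probe_set_id == "g3"])
  # slr gate applies per comparison, not to the mean
  expect_false(rec$included[rec$probe_set_id == "g4"])
  # relaxing the required count can only grow the list
  rec3 <- consensus_filter(calls, slr, required_count = 3)
  expect_true(all(rec$probe_set_id[rec$included] %in%
                    rec3$probe_set_id[rec3$included]))
  expect_true(rec3$included[rec3$probe_set_id == "g2"])
  expect_error(consensus_filter(calls, slr, required_count = 5), "exceeds")
})

test_that("counter-regulation requires opposite slr signs and lesion support", {
  hfs <- data.frame(probe_set_id = c("rt1da", "rt1ce5", "gx"),
                    direction = "D", D_count = 4, I_count = 0,
                    mean_slr = c(-2.7, -1.4, -1.1), included = TRUE,
                    stringsAsFactors = FALSE)
  lesion <- data.frame(probe_set_id = c("rt1da", "rt1ce5", "gx"),
                       direction = c("I", NA, "D"),
                       D_count = c(0, 0, 4), I_count = c(4, 0, 0),
                       mean_slr = c(1.5, NA, -1.2),
                       included = c(TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
  res <- detect_counter_regulation(hfs, lesion, lesion_min_count = 3)
  # stimulation-down gene, lesion-up with 4/4 support: counter-regulated
  expect_true(res$counter[res$probe_set_id == "rt1da"])
  # no lesion regulation at all: not counter
  expect_false(res$counter[res$probe_set_id == "rt1ce5"])
  # both effects in the same direction: not counter
  expect_false(res$counter[res$probe_set_id == "gx"])
  # output does not depend on input row order
  perm <- detect_counter_regulation(hfs[c(3, 1, 2), ], lesion[c(2, 3, 1), ],
                                    lesion_min_count = 3)
  expect_equal(res, perm)
})

test_that("EASE score equals the jackknifed hypergeometric tail", {
  expect_equal(ease_score(0, 8, 10, 1000)$score, 0)
  # the k-1 jackknife floors a single hit to p = 1
  expect_equal(ease_score(1, 8, 10, 1000)$score, 0)
  got <- ease_score(5, 8, 10, 1000)
  expect_equal(got$p, enumerate_hyper_tail(4, 8, 10, 1000), tolerance = 1e-12)
  expect_equal(got$score, -log10(enumerate_hyper_tail(4, 8, 10, 1000)),
               tolerance = 1e-9)
  expect_error(ease_score(9, 8, 10, 1000), "inconsistent")
})
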