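test_that("toggle observation captures the reference geometries", {
  map <- ref_map()
  obs_a <- observe_toggle(ref_active(), map, ref_inactive(), ref_active(),
                          tm3_range())
  obs_i <- observe_toggle(ref_inactive(), map, ref_inactive(), ref_active(),
                          tm3_range())
  # active structure: positions swapped, chi near active rotamers, no slide
  expect_true(obs_a$pos_reversed)
  expect_equal(obs_a$chi1_336, ref_params()$chi$A[["chi1_336"]],
               tolerance = 1e-3)
  expect_equal(obs_a$chi2_648, ref_params()$chi$A[["chi2_648"]],
               tolerance = 1e-3)
  expect_equal(obs_a$ca_slide_648, 0, tolerance = 1e-6)
  # inactive structure: unswapped, 6.8 A from the active-state position
  expect_false(obs_i$pos_reversed)
  expect_equal(obs_i$ca_slide_648, 6.8, tolerance = 0.05)
})

test_that("the double mutant is detected, not classified", {
  s <- ref_active()
  sel <- s$atom$resseq %in% c(200, 356)
  keep <- !sel | s$atom$elety %in% c("N", "CA", "C", "O", "CB")
  mut <- s$atom[keep, ]
  mut$resname[mut$resseq %in% c(200, 356)] <- "ALA"
  mutant <- gpcr_structure(mut, id = "F200A_W356A")
  expect_error(observe_toggle(mutant, ref_map(), ref_inactive(), ref_active(),
                              tm3_range()),
               class = "gpcr_mutant_error")
})

test_that("classification follows the centroid decision rule", {
  tab <- centroid_table(list(active = c(-175, 95), inactive = c(-65, 95),
                             pushed = c(-175, -145)),
                        window = 40, slide_threshold = 2)
  obs <- function(chi1, chi2, rev = FALSE, slide = 0)
    list(chi1_336 = chi1, chi2_648 = chi2, pos_reversed = rev,
         ca_slide_648 = slide)
  # at centroids
  expect_equal(classify_toggle(obs(-175, 95, rev = TRUE), tab), "active")
  expect_equal(classify_toggle(obs(-65, 95, rev = TRUE), tab),
               "reversed_inactive")
  expect_equal(classify_toggle(obs(-65, 95, rev = FALSE), tab), "inactive")
  expect_equal(classify_toggle(obs(-175, -145), tab), "pushed")
  # chi1 active-like, chi2 shifted off every well, slid main chain
  expect_equal(classify_toggle(obs(-175, 25, slide = 3), tab), "sliding")
  # same chi but no slide: unassigned
  expect_equal(classify_toggle(obs(-175, 25, slide = 0.5), tab), "unassigned")
  # nothing matches at all
  expect_equal(classify_toggle(obs(60, 25), tab), "unassigned")
  # wrap-around: chi near -180/+180 boundary matches the active well
  expect_equal(classify_toggle(obs(175, 95, rev = TRUE), tab), "active")
})

test_that("default centroid table is measured from the references", {
  tab <- default_centroid_table(ref_active(), ref_inactive(), ref_map())
  p <- ref_params()
  expect_equal(tab$centroids$active[1], p$chi$A[["chi1_336"]],
               tolerance = 1e-3)
  expect_equal(tab$centroids$inactive[1], p$chi$I[["chi1_336"]],
               tolerance = 1e-3)
  expect_equal(tab$centroids$pushed[2],
               wrap_angle(p$chi$I[["chi2_648"]] + 120), tolerance = 1e-3)
})

test_that("classifier recovers generating labels under chi jitter", {
  p <- ref_params()
  map <- ref_map()
  # zero noise: exact recovery
  tf0 <- generate_toggle_frames(p, n_per_label = 4, chi_sd = 0, seed = 3)
  cls0 <- classify_frames(tf0$structures, map, ref_inactive(), ref_active(),
                          tm3_range())
  expect_equal(cls0$label, tf0$labels)
  # 10 degree jitter, 500 frames: at least 95% recovery
  tf <- generate_toggle_frames(p, n_per_label = 100, chi_sd = 10, seed = 7)
  cls <- classify_frames(tf$structures, map, ref_inactive(), ref_active(),
                         tm3_range())
  expect_gte(mean(cls$label == tf$labels), 0.95)
})

test_that("active ratio pools frames and ignores order", {
  expect_equal(active_ratio(c("active", "active", "pushed", "active")), 0.75)
  expect_equal(active_ratio(rep("active", 10)), 1)
  expect_equal(active_ratio(rep("inactive", 10)), 0)
  set.seed(4)
  labs <- sample(c("active", "pushed", "sliding"), 60, replace = TRUE)
  expect_equal(active_ratio(labs), active_ratio(sample(labs)))
  # pooling is invariant to how frames are split into runs
  runs1 <- list(labs[1:20], labs[21:60])
  runs2 <- list(labs[41:60], labs[1:40])
  expect_equal(active_ratio(runs1), active_ratio(runs2))
  expect_equal(active_ratio(runs1), active_ratio(labs))
  # per-run averaging differs when run lengths differ
  expect_equal(active_ratio(list(c("active", "active"), c("pushed")),
                            per_run_average = TRUE), 0.5)
  expect_error(active_ratio(character(0)), "no frames")
})

test_that("dwell segments are maximal constant-label runs", {
  d <- dwell_segments(c("a", "a", "b"), c(1, 2, 3))
  expect_equal(d$label, c("a", "b"))
  expect_equal(d$start_ns, c(1, 3))
  expect_equal(d$end_ns, c(2, 3))
  d1 <- dwell_segments("a", 5)
  expect_equal(nrow(d1), 1)
  alt <- dwell_segments(rep(c("a", "b"), 5), 1:10)
  expect_equal(nrow(alt), 10)
  expect_true(all(alt$frames == 1))
  expect_error(dwell_segments(c("a", "b"), 1), "lengths differ")
})
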