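test_that("the built-in CB1 indicator set matches the published design", {
  specs <- builtin_cb1_indicator_set()
  expect_length(specs, 6)
  expect_setequal(names(specs), c("Y5.58-Y7.53", "TM3-TM6", "TM2-TM1",
                                  "TM2-TM7", "NT-F3.25", "NT-ECL2"))
  expect_equal(specs[["TM3-TM6"]]$ref_inactive, 8.2)
  expect_equal(specs[["TM3-TM6"]]$ref_active, 13.8)
  expect_equal(specs[["Y5.58-Y7.53"]]$ref_inactive, 10.5)
  expect_equal(specs[["Y5.58-Y7.53"]]$ref_active, 3.4)
  # the N-terminal residue is unresolved in the active structure
  expect_true(is.na(specs[["NT-ECL2"]]$ref_active))
  expect_true(is.na(specs[["NT-F3.25"]]$ref_active))
  expect_equal(specs[["TM2-TM1"]]$a$atom, "CZ")
  expect_equal(specs[["TM2-TM1"]]$b$atom, "O")
  expect_equal(specs[["NT-ECL2"]]$a$mode, "ring")
})

test_that("indicators reproduce reference distances on the state models", {
  specs <- builtin_cb1_indicator_set()
  map <- ref_map()
  expect_equal(evaluate_indicator(ref_inactive(), specs[["Y5.58-Y7.53"]], map),
               10.5, tolerance = 0.05)
  expect_equal(evaluate_indicator(ref_active(), specs[["Y5.58-Y7.53"]], map),
               3.4, tolerance = 0.05)
  expect_equal(evaluate_indicator(ref_inactive(), specs[["TM3-TM6"]], map),
               8.2, tolerance = 0.05)
  expect_equal(evaluate_indicator(ref_active(), specs[["TM3-TM6"]], map),
               13.8, tolerance = 0.05)
})

test_that("a by-construction endpoint separation is returned exactly", {
  atom <- data.frame(chain = "A", resseq = c(1, 2), icode = "",
                     resname = "ALA", elety = "CA", elesy = "C",
                     x = c(0, 7), y = 0, z = 0, stringsAsFactors = FALSE)
  s <- gpcr_structure(atom)
  spec <- indicator_spec("probe", "p1", "p2", atom_a = "CA", atom_b = "CA")
  map <- bw_map(c("p1", "p2"), c("A", "A"), c(1, 2))
  expect_equal(evaluate_indicator(s, spec, map), 7.0)
})

test_that("a missing optional endpoint yields a flagged NA, not an error", {
  s <- ref_inactive()
  s2 <- gpcr_structure(s$atom[s$atom$resseq != 102, ], id = "no_nterm")
  spec <- builtin_cb1_indicator_set()[["NT-ECL2"]]
  v <- evaluate_indicator(s2, spec, ref_map())
  expect_true(is.na(v))
  expect_equal(attr(v, "missing_endpoint"), "N-term")
  # a missing non-optional endpoint is still an error
  s3 <- gpcr_structure(s$atom[s$atom$resseq != 294, ], id = "no_558")
  expect_error(evaluate_indicator(s3, builtin_cb1_indicator_set()[[1]],
                                  ref_map()),
               class = "gpcr_lookup_error")
})

test_that("indicator values are invariant under global rigid motion", {
  specs <- builtin_cb1_indicator_set()
  map <- ref_map()
  base <- vapply(specs, function(sp)
    evaluate_indicator(ref_active(), sp, map), numeric(1))
  set.seed(21)
  for (i in 1:5) {
    moved <- apply_rigid_motion(ref_active(), random_rigid_motion())
    v <- vapply(specs, function(sp) evaluate_indicator(moved, sp, map),
                numeric(1))
    expect_equal(v, base, tolerance = 1e-8)
  }
})

test_that("series evaluation tracks the trajectory schedule", {
  p <- ref_params()
  map <- ref_map()
  sched <- trajectory_schedule(list(list(state = "A", frames = 3),
                                    list(state = "I", frames = 3)),
                               interp_frames = 4, noise_sd = 0, seed = 1)
  fs <- generate_trajectory(p, sched)$frames
  ser <- indicator_series(fs, builtin_cb1_indicator_set(), map)
  tm36 <- ser$value_A[ser$indicator == "TM3-TM6"]
  expect_length(tm36, 10)
  # noise-free interpolation from active 13.8 to inactive 8.2 is monotone
  expect_true(all(diff(tm36) <= 1e-9))
  expect_equal(tm36[1], 13.8, tolerance = 0.05)
  expect_equal(tm36[10], 8.2, tolerance = 0.05)
  # constant segments give constant values
  expect_equal(tm36[1], tm36[3], tolerance = 1e-9)
  # empty spec list gives empty output
  expect_equal(nrow(indicator_series(fs, list(), map)), 0)
})

test_that("state calling follows the nearest-reference rule", {
  spec <- builtin_cb1_indicator_set()[["TM3-TM6"]]
  expect_equal(call_state(13.8, spec, 1.0), "active-like")
  expect_equal(call_state(8.2, spec, 1.0), "inactive-like")
  expect_equal(call_state(11.0, spec, 1.0), "intermediate")
  expect_equal(call_state(c(13.8, 8.2, 11.0), spec, 1.0),
               c("active-like", "inactive-like", "intermediate"))
  # reference structures themselves always match for any tolerance > 0
  for (tol in c(0.01, 0.5, 2)) {
    expect_equal(call_state(spec$ref_active, spec, tol), "active-like")
    expect_equal(call_state(spec$ref_inactive, spec, tol), "inactive-like")
  }
  no_ref <- builtin_cb1_indicator_set()[["TM2-TM1"]]
  expect_error(call_state(9, no_ref, 1), "lacks reference")
})

test_that("TM3-aligned 6.48 CA displacement matches construction", {
  map <- ref_map()
  expect_equal(toggle_ca_displacement(ref_inactive(), ref_inactive(), map,
                                      tm3_range()), 0, tolerance = 1e-9)
  expect_equal(toggle_ca_displacement(ref_inactive(), ref_active(), map,
                                      tm3_range()), 6.8, tolerance = 0.05)
  # displacing only the 6.48 CA region by a known offset is recovered
  s <- ref_inactive()
  rows <- which(s$atom$resseq > 350 & s$atom$resseq <= 364)
  xyz <- coords(s); xyz[rows, 1] <- xyz[rows, 1] + 2
  s2 <- set_coords(s, xyz)
  expect_equal(toggle_ca_displacement(s, s2, map, tm3_range()), 2,
               tolerance = 1e-9)
})

test_that("overall RMSD traces cross at the scheduled transition", {
  p <- ref_params()
  sched <- trajectory_schedule(list(list(state = "A", frames = 10),
                                    list(state = "I", frames = 10)),
                               interp_frames = 10, noise_sd = 0, seed = 1)
  sim <- generate_trajectory(p, sched)
  ranges <- list(c(106, 306), c(335, 411))
  to_a <- overall_rmsd_trace(sim$frames, ref_active(), ranges)$value_A
  to_i <- overall_rmsd_trace(sim$frames, ref_inactive(), ranges)$value_A
  expect_equal(to_a[1], 0, tolerance = 1e-6)
  expect_equal(to_i[30], 0, tolerance = 1e-6)
  # drifting from A to I: distance to A nondecreasing, to I nonincreasing
  expect_true(all(diff(to_a) >= -1e-9))
  expect_true(all(diff(to_i) <= 1e-9))
  # crossing frame equals the scheduled midpoint within one frame
  crossing <- which(to_i < to_a)[1]
  expect_equal(crossing, attr(sim$truth, "transitions")[1], tolerance = 1)
})
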