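test_that("PDB write/read round-trips coordinates to the 3-decimal grid", {
  s <- ref_inactive()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2$atom), nrow(s$atom))
  expect_equal(coords(s2), round(coords(s), 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  expect_identical(coords(read_pdb(f2)), coords(s2))
})

test_that("single-record files and altlocs parse per policy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atom), 1)
  expect_equal(as.numeric(coords(s)), c(1, 2, 3))

  # two altlocs: the higher-occupancy one is kept; ties keep "A"
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atom), 2)
  expect_equal(s$atom$x[s$atom$elety == "CA"], 2)  # occupancy 0.6 wins
  expect_equal(s$atom$x[s$atom$elety == "CB"], 3)  # tie -> altloc A
})

test_that("empty or invalid structures are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_pdb(f), "gpcr_")
  expect_error(read_pdb(file.path(tempdir(), "no_such_file.pdb")), "not found")
  s <- ref_inactive()
  s_far <- set_coords(s, coords(s) + 1e5)
  expect_error(write_pdb(s_far, f), "fixed-width")
})

test_that("frame series round-trip through multi-model PDB", {
  p <- ref_params()
  sched <- trajectory_schedule(list(list(state = "A", frames = 3)),
                               noise_sd = 0, seed = 1)
  fs <- generate_trajectory(p, sched)$frames
  f <- withr::local_tempfile(fileext = ".pdb")
  write_frames(fs, f)
  fs2 <- read_frames(f)
  expect_equal(n_frames(fs2), 3)
  expect_equal(fs2$times, c(1, 2, 3))
  expect_equal(nrow(fs2$topology$atom), nrow(fs$topology$atom))
  expect_equal(fs2$xyz, round(fs$xyz, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical models give identical frames
  expect_equal(fs2$xyz[1, ], fs2$xyz[2, ], ignore_attr = TRUE)
})

test_that("frame series validate topology and times", {
  s <- ref_inactive()
  xyz1 <- as.numeric(t(coords(s)))
  expect_error(frame_series(s, cbind(rbind(xyz1, xyz1), 0), 1:2),
               "atom count")
  expect_error(frame_series(s, rbind(xyz1, xyz1), c(2, 1)),
               "strictly increasing")
  fs <- frame_series(s, rbind(xyz1, xyz1), c(1, 2))
  expect_equal(n_frames(fs), 2)
  # frames with differing atom counts across files error
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f1)
  s_small <- gpcr_structure(s$atom[1:100, ], id = "small")
  write_pdb(s_small, f2)
  expect_error(read_frames(c(f1, f2)), "inconsistent atom counts")
})

test_that("generic-number labels resolve bijectively", {
  s <- ref_inactive()
  map <- ref_map()
  expect_equal(resolve_label(s, map, "3.36")$resseq, 200)
  expect_equal(resolve_label(s, map, "6.48")$resseq, 356)
  expect_equal(resolve_label(s, map, "3.36")$resname, "PHE")
  # every label resolves to a distinct residue
  keys <- vapply(map$label, function(l) {
    r <- resolve_label(s, map, l)
    paste(r$chain, r$resseq, r$icode)
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_error(resolve_label(s, map, "9.99"), class = "gpcr_lookup_error")
  map2 <- bw_map("1.50", "A", 9999)
  expect_error(resolve_label(s, map2, "1.50"), class = "gpcr_lookup_error")
})

test_that("map and segment tables read from TSV and validate", {
  map <- read_bw_map(system.file("extdata", "cb1_bw_map.tsv",
                                 package = "gpcrstate"))
  expect_s3_class(map, "bw_map")
  expect_equal(map$resseq[map$label == "6.48"], 356)
  segs <- read_tm_segments(system.file("extdata", "cb1_tm_segments.tsv",
                                       package = "gpcrstate"))
  expect_s3_class(segs, "tm_segments")
  expect_equal(segs["TM6", "start"], 335)
  expect_error(tm_segments(paste0("TM", 1:6), rep("A", 6), 1:6 * 10,
                           1:6 * 10 + 5), "TM1..TM7")
  expect_error(tm_segments(paste0("TM", 1:7), rep("A", 7),
                           c(1, 2, 30, 40, 50, 60, 70),
                           c(10, 12, 35, 45, 55, 65, 75)), "overlap")
})

test_that("selection RMSD errors list unmatched residues", {
  a <- ref_inactive()
  expect_equal(rmsd_after_superposition(a, a, list(c(186, 215))), 0,
               tolerance = 1e-9)
  b <- gpcr_structure(a$atom[a$atom$resseq != 200, ], id = "gappy")
  err <- tryCatch(rmsd_after_superposition(a, b, list(c(186, 215))),
                  error = identity)
  expect_s3_class(err, "gpcr_pairing_error")
  expect_match(conditionMessage(err), "200")
})
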