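test_that("the piecewise contact score evaluates its three branches", {
  # far apart: zero
  expect_equal({
    s <- make_two_residue_probe(10)
    rrcs_pair(s, get_residue(s, "A", 1), get_residue(s, "A", 50))
  }, 0)
  # saturated below d_full
  expect_equal({
    s <- make_two_residue_probe(3.23 - 0.1)
    rrcs_pair(s, get_residue(s, "A", 1), get_residue(s, "A", 50))
  }, 1)
  # linear branch: hand-computed (4.63 - 3.93) / 1.40 = 0.5
  expect_equal({
    s <- make_two_residue_probe(3.93)
    rrcs_pair(s, get_residue(s, "A", 1), get_residue(s, "A", 50))
  }, 0.5)
  # a saturated pair plus extras never scores below 1
  s <- make_two_residue_probe(1.0, extra_a = 2, extra_b = 2)
  expect_gte(rrcs_pair(s, get_residue(s, "A", 1), get_residue(s, "A", 50)), 1)
  expect_error(rrcs_pair(s, get_residue(s, "A", 1), get_residue(s, "A", 1)),
               "itself")
})

test_that("rrcs_pair equals a brute-force double loop on random pairs", {
  params <- rrcs_params()
  brute <- function(res_a, res_b) {
    total <- 0
    for (i in seq_len(nrow(res_a$atom))) {
      for (j in seq_len(nrow(res_b$atom))) {
        d <- sqrt(sum((c(res_a$atom$x[i], res_a$atom$y[i], res_a$atom$z[i]) -
                       c(res_b$atom$x[j], res_b$atom$y[j], res_b$atom$z[j]))^2))
        total <- total + if (d <= params$d_full) 1
          else if (d >= params$d_zero) 0
          else (params$d_zero - d) / (params$d_zero - params$d_full)
      }
    }
    total
  }
  set.seed(13)
  for (i in 1:100) {
    s <- random_residue_structure(n_a = sample(2:6, 1), n_b = sample(2:6, 1))
    ra <- get_residue(s, "A", 10); rb <- get_residue(s, "A", 40)
    expect_equal(rrcs_pair(s, ra, rb, params), brute(ra, rb),
                 tolerance = 1e-12)
    # symmetry in argument order
    expect_identical(rrcs_pair(s, ra, rb, params), rrcs_pair(s, rb, ra, params))
  }
})

test_that("backbone atoms are excluded only for sequence-near pairs", {
  mk <- function(gap) {
    atom <- data.frame(chain = "A", resseq = c(1, 1, 1 + gap, 1 + gap),
                       icode = "", resname = "ALA",
                       elety = c("CA", "CB", "CA", "CB"), elesy = "C",
                       x = c(0, 0, 3, 3), y = c(0, 1, 0, 1), z = 0,
                       stringsAsFactors = FALSE)
    gpcr_structure(atom)
  }
  params <- rrcs_params()
  near <- mk(2)   # separation 2 <= 4: backbone CA excluded
  far <- mk(20)   # separation 20 > 4: all heavy atoms count
  sc_near <- rrcs_pair(near, get_residue(near, "A", 1),
                       get_residue(near, "A", 3), params)
  sc_far <- rrcs_pair(far, get_residue(far, "A", 1),
                      get_residue(far, "A", 21), params)
  expect_lt(sc_near, sc_far)
  # hydrogens never score
  ath <- near$atom
  ath$elety[2] <- "HB1"; ath$elesy[2] <- "H"
  sh <- gpcr_structure(ath)
  expect_lt(rrcs_pair(sh, get_residue(sh, "A", 1), get_residue(sh, "A", 3),
                      params), sc_near + 1e-12)
})

test_that("moving residues apart never increases the score", {
  set.seed(17)
  for (i in 1:10) {
    s <- random_residue_structure(4, 4, spread = 3)
    sel <- s$atom$resseq == 40
    axis <- colMeans(coords(s)[sel, ]) - colMeans(coords(s)[!sel, ])
    axis <- axis / sqrt(sum(axis^2))
    sep <- seq(0, 8, by = 0.5)
    scores <- vapply(sep, function(d) {
      a <- s$atom
      a$x[sel] <- a$x[sel] + d * axis[1]
      a$y[sel] <- a$y[sel] + d * axis[2]
      a$z[sel] <- a$z[sel] + d * axis[3]
      s2 <- gpcr_structure(a)
      rrcs_pair(s2, get_residue(s2, "A", 10), get_residue(s2, "A", 40))
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-9))
  }
})

test_that("|delta RRCS| is symmetric, zero on identical states, additive", {
  map <- ref_map()
  d0 <- delta_rrcs(ref_inactive(), ref_inactive(), map)
  expect_equal(d0$value, 0)
  d <- delta_rrcs(ref_inactive(), ref_active(), map)
  d_swapped <- delta_rrcs(ref_active(), ref_inactive(), map)
  expect_equal(d$value, d_swapped$value)
  expect_gt(d$value, 0)
  expect_equal(d$value, abs(d$rrcs_inactive - d$rrcs_active))
})

test_that("receptor ranking orders by |delta RRCS| with stable ties", {
  p <- ref_params()
  map <- ref_map()
  cb1 <- build_state_pair(p, "cb1")
  rigid <- build_state_pair(p, "rigid_tm4")
  entries <- list(
    list(id = "SWAPPER", inactive = cb1$inactive, active = cb1$active,
         map = map),
    list(id = "RIGID", inactive = rigid$inactive, active = rigid$active,
         map = map))
  ranked <- rank_receptors(entries)
  # the receptor whose toggle pair swaps between states ranks first
  expect_equal(ranked$receptor[1], "SWAPPER")
  expect_equal(ranked$rank, c(1, 2))
  # cross-check against direct pair evaluation
  direct <- vapply(entries, function(e)
    delta_rrcs(e$inactive, e$active, e$map)$value, numeric(1))
  expect_equal(ranked$abs_delta, sort(direct, decreasing = TRUE))
  # ties break lexicographically by id
  tie_entries <- list(
    list(id = "B", inactive = cb1$inactive, active = cb1$inactive, map = map),
    list(id = "A", inactive = cb1$inactive, active = cb1$inactive, map = map))
  expect_equal(rank_receptors(tie_entries)$receptor, c("A", "B"))
  expect_error(rank_receptors(list()), "no receptors")
})
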