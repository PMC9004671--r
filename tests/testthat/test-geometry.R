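test_that("superposition recovers exact fits and beats random rotations", {
  # identity
  pts <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(superpose(pts, pts)$rmsd, 0, tolerance = 1e-10)

  # rigid motion invariance: rotated + translated copy fits exactly
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(pts %*% t(R), 2, c(5, 0, 0), "+")
  xf <- superpose(pts, moved)
  expect_equal(xf$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(xf, pts), moved, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(xf$rotation), 1, tolerance = 1e-9)

  # frozen value from an independent numerical minimizer over rotations
  mob <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0.5))
  expect_equal(superpose(mob, ref)$rmsd, 0.0522555460, tolerance = 1e-6)

  # optimality: no random rotation does better
  set.seed(11)
  mob2 <- matrix(stats::rnorm(24), ncol = 3)
  ref2 <- mob2 + matrix(stats::rnorm(24, sd = 0.3), ncol = 3)
  best <- superpose(mob2, ref2)$rmsd
  X <- sweep(mob2, 2, colMeans(mob2)); Y <- sweep(ref2, 2, colMeans(ref2))
  worse <- vapply(seq_len(1000), function(i) {
    m <- random_rigid_motion()
    sqrt(mean(rowSums((X %*% t(m$R) - Y)^2)))
  }, numeric(1))
  expect_true(all(worse >= best - 1e-9))
})

test_that("superposition rejects degenerate input", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("dihedral follows the IUPAC sign convention", {
  # planar cis and trans
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # out-of-plane: sign frozen from the cross/dot vector-algebra oracle
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), -90)
  # IUPAC torsions are invariant under atom-order reversal and negate
  # under mirror reflection
  set.seed(5)
  for (i in 1:25) {
    p <- lapply(1:4, function(j) stats::rnorm(3))
    d1 <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    d2 <- dihedral(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(wrap_angle(d1 - d2), 0, tolerance = 1e-9)
    refl <- lapply(p, function(v) c(v[1], v[2], -v[3]))
    d3 <- dihedral(refl[[1]], refl[[2]], refl[[3]], refl[[4]])
    expect_equal(wrap_angle(d1 + d3), 0, tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident")
})

test_that("angle wrapping keeps values in (-180, 180]", {
  expect_equal(wrap_angle(c(190, -190, 360, -180, 180)),
               c(-170, 170, 0, 180, 180))
  expect_equal(angle_diff(179, -179), 2)
})

test_that("distances are Euclidean and satisfy the triangle inequality", {
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  for (i in 1:50) {
    p <- stats::rnorm(3); q <- stats::rnorm(3); r <- stats::rnorm(3)
    expect_equal(atom_distance(p, q), sqrt(sum((p - q)^2)))
    expect_lte(atom_distance(p, r),
               atom_distance(p, q) + atom_distance(q, r) + 1e-12)
  }
})

test_that("ring centroids average the ring atoms", {
  hex <- t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  atom <- data.frame(chain = "A", resseq = 1, icode = "", resname = "PHE",
                     elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                     elesy = "C", x = hex[, 1], y = hex[, 2], z = hex[, 3],
                     stringsAsFactors = FALSE)
  s <- gpcr_structure(atom)
  expect_equal(ring_centroid(get_residue(s, "A", 1)), c(0, 0, 0),
               tolerance = 1e-12)
  # a missing ring atom is an incomplete side chain
  s5 <- gpcr_structure(atom[-6, ])
  expect_error(ring_centroid(get_residue(s5, "A", 1)),
               class = "gpcr_incomplete_sidechain_error")
})

test_that("chi angles match construction targets and flag no-chi residues", {
  p <- ref_params()
  s <- build_bundle(p, "A", chi_override = c(chi1_336 = -60, chi2_648 = 90),
                    check = FALSE)
  r336 <- get_residue(s, "A", 200)
  r648 <- get_residue(s, "A", 356)
  expect_equal(chi_angles(r336)$chi1, -60, tolerance = 1e-3)
  expect_equal(chi_angles(r648)$chi2, 90, tolerance = 1e-3)
  # chi1 = 180 exactly
  s2 <- build_bundle(p, "I", chi_override = c(chi1_336 = 180), check = FALSE)
  expect_equal(chi_angles(get_residue(s2, "A", 200))$chi1, 180,
               tolerance = 1e-3)
  # alanine has no chi (toggle-mutant detection)
  expect_error(chi_angles(get_residue(s, "A", 342)),
               class = "gpcr_no_chi_error")
})
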