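# Shared fixtures.  The synthetic reference pair is expensive enough to
# build that the suite constructs it once and treats it as read-only.

fx <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(fx$params)) fx$params <- bundle_params()
  fx$params
}

ref_inactive <- function() {
  if (is.null(fx$inactive)) fx$inactive <- build_bundle(ref_params(), "I")
  fx$inactive
}

ref_active <- function() {
  if (is.null(fx$active)) fx$active <- build_bundle(ref_params(), "A")
  fx$active
}

ref_map <- function() cb1_bw_map()
ref_segments <- function() cb1_tm_segments()
tm3_range <- function() c(186, 215)

# random rigid motion, seeded by the caller
random_rigid_motion <- function() {
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = Rz %*% Ry %*% Rx, t = stats::runif(3, -20, 20))
}

apply_rigid_motion <- function(s, motion) {
  set_coords(s, sweep(coords(s) %*% t(motion$R), 2, motion$t, "+"))
}

# a small residue with randomly placed heavy atoms, for RRCS property tests
random_residue_structure <- function(n_a = 5, n_b = 5, spread = 6) {
  atom <- data.frame(
    chain = "A",
    resseq = rep(c(10, 40), c(n_a, n_b)),
    icode = "",
    resname = "UNK",
    elety = c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b))),
    elesy = "C",
    x = stats::runif(n_a + n_b, -spread, spread),
    y = stats::runif(n_a + n_b, -spread, spread),
    z = stats::runif(n_a + n_b, -spread, spread),
    stringsAsFactors = FALSE)
  gpcr_structure(atom, id = "random_pair")
}
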