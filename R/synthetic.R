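# Synthetic receptor generator.
#
# Builds an idealized seven-helix bundle with CB1-like residue numbering
# and two distinguishable activation-state geometries.  Helix backbones
# are ideal alpha-helices (1.5 A rise, 100 deg/residue); marker side
# chains are built from internal coordinates so chi targets are exact by
# construction; per-state rigid helix moves are solved in closed form so
# the six activation indicators reproduce their configured reference
# distances exactly, and the TM3-aligned 6.48 CA slide between states
# equals its configured value.  No force field, no sterics: the point is
# known ground truth, not physical realism.

#' CB1-like generic-number map used by the synthetic bundle
#' @return a [bw_map()] with the residue labels the analysis needs.
#' @export
cb1_bw_map <- function() {
  lab <- c("1.36", "2.61", "3.25", "3.36", "3.40", "3.50",
           "5.50", "5.58", "6.34", "6.44", "6.48", "7.36", "7.53",
           "N-term", "ECL2")
  res <- c(120, 174, 189, 200, 204, 214,
           286, 294, 342, 352, 356, 380, 397,
           102, 268)
  bw_map(lab, rep("A", length(lab)), res)
}

#' CB1-like TM segment table used by the synthetic bundle
#' @return a [tm_segments()] table (chain A).
#' @export
cb1_tm_segments <- function() {
  tm_segments(paste0("TM", 1:7), rep("A", 7),
              start = c(113, 150, 186, 222, 275, 335, 372),
              end   = c(142, 179, 215, 251, 304, 364, 401))
}

# residues that get full ring side chains, and their types
.special_resnames <- c("102" = "PHE", "120" = "ALA", "174" = "PHE",
                       "189" = "PHE", "200" = "PHE", "204" = "VAL",
                       "214" = "ARG", "268" = "PHE", "286" = "LEU",
                       "294" = "TYR", "342" = "ALA", "352" = "LEU",
                       "356" = "TRP", "380" = "ALA", "397" = "TYR")
.ring_residues <- c(102, 174, 189, 268, 294, 397)   # built at default chi

#' Parameters of the synthetic receptor bundle
#'
#' Defaults encode the study conditions: the Y5.58-Y7.53 and TM3-TM6
#' indicator references printed for CB1 (10.5/3.4 and 8.2/13.8 A), the
#' 6.8 A TM3-aligned slide of the 6.48 CA atom, and field-plausible
#' values for the orthosteric-pocket and N-terminal indicators, for which
#' no reference is printed (the N-terminal residue being unresolved in
#' the active structure).
#'
#' @param bundle_radius radius of the helix-axis circle, Angstrom.
#' @param ca_radius CA helix radius, Angstrom.
#' @param rise helical rise per residue, Angstrom.
#' @param twist helical twist per residue, degrees.
#' @param tm6_z_shift vertical offset of TM6, Angstrom (places the toggle
#'   tryptophan below the toggle phenylalanine in the inactive state).
#' @param tm6_kink residue number of the TM6 hinge: the helix halves above
#'   and below it move as separate rigid bodies between states, emulating
#'   the kink at the conserved CWxP region.
#' @param helix_phase named per-helix azimuthal phase offsets (degrees);
#'   the TM3/TM6 defaults orient the toggle side chains toward each other.
#' @param slide_648 TM3-aligned displacement of the 6.48 CA between the
#'   two states, Angstrom, directed along the 6.48-to-3.36 swap axis.
#' @param targets named list of per-indicator `c(I = ..., A = ...)`
#'   distances, Angstrom.
#' @param chi named list of per-state toggle dihedral targets, degrees:
#'   `chi1_336` (F3.36 chi1) and `chi2_648` (W6.48 chi2); chi1 of the
#'   tryptophan and chi2 of the phenylalanine are held at `chi_other`.
#' @param chi_other default chi values for side chains without state
#'   targets, degrees.
#' @param check_tol post-build verification tolerance, Angstrom.
#' @return list of class `bundle_params`.
#' @export
bundle_params <- function(bundle_radius = 11, ca_radius = 2.3,
                          rise = 1.5, twist = 100, tm6_z_shift = -13,
                          tm6_kink = 350,
                          helix_phase = c(TM3 = 70, TM6 = 190),
                          slide_648 = 6.8,
                          targets = list(
                            "Y5.58-Y7.53" = c(I = 10.5, A = 3.4),
                            "TM3-TM6"     = c(I = 8.2,  A = 13.8),
                            "TM2-TM1"     = c(I = 8.0,  A = 11.0),
                            "TM2-TM7"     = c(I = 7.0,  A = 10.0),
                            "NT-F3.25"    = c(I = 6.0,  A = 18.0),
                            "NT-ECL2"     = c(I = 5.5,  A = 20.0)),
                          chi = list(A = c(chi1_336 = -175, chi2_648 = 95),
                                     I = c(chi1_336 = -65,  chi2_648 = 95)),
                          chi_other = c(chi1 = -65, chi2 = 90),
                          check_tol = 0.05) {
  stopifnot(bundle_radius > 0, ca_radius > 0, rise > 0, slide_648 > 0)
  if (!all(vapply(targets, function(t) all(is.finite(t) & t > 0), logical(1))))
    stop("gpcr_value_error: indicator targets must be positive and finite",
         call. = FALSE)
  structure(list(segments = cb1_tm_segments(), map = cb1_bw_map(),
                 chain = "A", bundle_radius = bundle_radius,
                 ca_radius = ca_radius, rise = rise, twist = twist,
                 tm6_z_shift = tm6_z_shift, tm6_kink = tm6_kink,
                 helix_phase = helix_phase, slide_648 = slide_648,
                 targets = targets, chi = chi, chi_other = chi_other,
                 check_tol = check_tol),
            class = "bundle_params")
}

# ---- internal coordinate builders --------------------------------------

# side-chain atoms for one residue built from N/CA/CB by NeRF; returns a
# named list of positions.
.sidechain_atoms <- function(resname, n, ca, cb, chi1, chi2) {
  out <- list()
  if (resname %in% c("PHE", "TYR")) {
    out$CG  <- place_atom_nerf(n, ca, cb, 1.52, 113.8, chi1)
    out$CD1 <- place_atom_nerf(ca, cb, out$CG, 1.39, 120.7, chi2)
    out$CD2 <- place_atom_nerf(ca, cb, out$CG, 1.39, 120.7, chi2 + 180)
    out$CE1 <- place_atom_nerf(cb, out$CG, out$CD1, 1.39, 120, 180)
    out$CE2 <- place_atom_nerf(cb, out$CG, out$CD2, 1.39, 120, 180)
    out$CZ  <- place_atom_nerf(out$CG, out$CD1, out$CE1, 1.39, 120, 0)
    if (resname == "TYR")
      out$OH <- place_atom_nerf(out$CD1, out$CE1, out$CZ, 1.38, 120, 180)
  } else if (resname == "TRP") {
    out$CG  <- place_atom_nerf(n, ca, cb, 1.50, 114, chi1)
    out$CD1 <- place_atom_nerf(ca, cb, out$CG, 1.37, 127.0, chi2)
    out$CD2 <- place_atom_nerf(ca, cb, out$CG, 1.43, 126.6, chi2 + 180)
    out$NE1 <- place_atom_nerf(cb, out$CG, out$CD1, 1.38, 110, 180)
    out$CE2 <- place_atom_nerf(cb, out$CG, out$CD2, 1.40, 107, 180)
    out$CE3 <- place_atom_nerf(cb, out$CG, out$CD2, 1.40, 133.9, 0)
    out$CZ2 <- place_atom_nerf(out$CG, out$CD2, out$CE2, 1.40, 122.4, 180)
    out$CZ3 <- place_atom_nerf(out$CG, out$CD2, out$CE3, 1.39, 118.8, 180)
    out$CH2 <- place_atom_nerf(out$CD2, out$CE3, out$CZ3, 1.37, 121.1, 0)
  } else {
    stop("gpcr_value_error: no side-chain template for ", resname,
         call. = FALSE)
  }
  out
}

# atom order used for every residue (stable topology across states)
.residue_atom_order <- function(resname) {
  base <- c("N", "CA", "C", "O")
  side <- switch(resname,
                 GLY = character(0),
                 PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                 TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
                 TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                         "CZ2", "CZ3", "CH2"),
                 "CB")
  c(base, side)
}

.element_of <- function(elety) substr(gsub("^[0-9]*", "", elety), 1, 1)

# build the state-independent base bundle; returns list(structure, info)
.base_bundle <- function(p) {
  segs <- p$segments
  acc <- new.env(parent = emptyenv())
  acc$resseq <- integer(0); acc$resname <- character(0)
  acc$elety <- character(0); acc$xyz <- list()
  add_atom <- function(resseq, resname, elety, pos) {
    acc$resseq <- c(acc$resseq, resseq)
    acc$resname <- c(acc$resname, resname)
    acc$elety <- c(acc$elety, elety)
    acc$xyz[[length(acc$xyz) + 1]] <- pos
  }
  phase0 <- 17
  for (k in 1:7) {
    seg <- segs[paste0("TM", k), ]
    n_res <- seg$end - seg$start + 1
    L <- (n_res - 1) * p$rise
    zoff <- if (k == 6) p$tm6_z_shift else 0
    down <- k %in% c(1, 3, 5, 7)
    theta <- (90 - (k - 1) * 360 / 7) * pi / 180
    axis_xy <- p$bundle_radius * c(cos(theta), sin(theta))
    extra_phase <- if (paste0("TM", k) %in% names(p$helix_phase))
      p$helix_phase[[paste0("TM", k)]] else 0
    hel_point <- function(t, radius) {
      ph <- (phase0 + 40 * k + extra_phase + p$twist * t) * pi / 180
      z <- if (down) L / 2 - p$rise * t else -L / 2 + p$rise * t
      c(axis_xy + radius * c(cos(ph), sin(ph)), z + zoff)
    }
    for (i in seq_len(n_res) - 1) {
      resseq <- seg$start + i
      resname <- if (as.character(resseq) %in% names(.special_resnames))
        .special_resnames[[as.character(resseq)]] else "ALA"
      n_pos  <- hel_point(i - 0.35, 1.65)
      ca_pos <- hel_point(i, p$ca_radius)
      c_pos  <- hel_point(i + 0.40, 1.65)
      o_pos  <- place_atom_nerf(n_pos, ca_pos, c_pos, 1.23, 120.8, -40)
      add_atom(resseq, resname, "N", n_pos)
      add_atom(resseq, resname, "CA", ca_pos)
      add_atom(resseq, resname, "C", c_pos)
      add_atom(resseq, resname, "O", o_pos)
      if (resname != "GLY") {
        cb_pos <- place_atom_nerf(c_pos, n_pos, ca_pos, 1.53, 110.4, -122)
        add_atom(resseq, resname, "CB", cb_pos)
        if (resname %in% c("PHE", "TYR", "TRP")) {
          chis <- .default_chis_for(p, resseq)
          sc <- .sidechain_atoms(resname, n_pos, ca_pos, cb_pos,
                                 chis[1], chis[2])
          for (nm in names(sc)) add_atom(resseq, resname, nm, sc[[nm]])
        }
      }
    }
  }
  # loose residues: N-terminal probe F102 and ECL2 cap F268
  theta3 <- (90 - 2 * 360 / 7) * pi / 180
  tm3_xy <- p$bundle_radius * c(cos(theta3), sin(theta3))
  add_loose_phe <- function(resseq, ca_pos) {
    n_pos <- ca_pos + c(1.45, 0, 0)
    c_pos <- ca_pos + 1.52 * .unit(c(-0.4, 1.3, 0.4))
    o_pos <- place_atom_nerf(n_pos, ca_pos, c_pos, 1.23, 120.8, -40)
    cb_pos <- place_atom_nerf(c_pos, n_pos, ca_pos, 1.53, 110.4, -122)
    add_atom(resseq, "PHE", "N", n_pos)
    add_atom(resseq, "PHE", "CA", ca_pos)
    add_atom(resseq, "PHE", "C", c_pos)
    add_atom(resseq, "PHE", "O", o_pos)
    add_atom(resseq, "PHE", "CB", cb_pos)
    sc <- .sidechain_atoms("PHE", n_pos, ca_pos, cb_pos,
                           p$chi_other[["chi1"]], p$chi_other[["chi2"]])
    for (nm in names(sc)) add_atom(resseq, "PHE", nm, sc[[nm]])
  }
  add_loose_phe(102, c(tm3_xy * 1.6, 24))
  add_loose_phe(268, c(tm3_xy * 0.55, 20))
  xyz <- do.call(rbind, acc$xyz)
  atom <- data.frame(chain = p$chain, resseq = acc$resseq, icode = "",
                     resname = acc$resname, elety = acc$elety,
                     elesy = .element_of(acc$elety),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     stringsAsFactors = FALSE)
  gpcr_structure(atom, id = "synthetic_base")
}

.default_chis_for <- function(p, resseq) {
  if (resseq == 200) c(p$chi$I[["chi1_336"]], p$chi_other[["chi2"]])
  else if (resseq == 356) c(p$chi_other[["chi1"]], p$chi$I[["chi2_648"]])
  else c(p$chi_other[["chi1"]], p$chi_other[["chi2"]])
}

# ---- closed-form placement solvers -------------------------------------

# point x with |x - c1| = r1 and |x - c2| = r2, closest to p (deterministic)
.solve_two_sphere <- function(p, c1, r1, c2, r2) {
  u <- c2 - c1
  D <- .vnorm(u)
  if (D < 1e-9)
    stop("gpcr_value_error: coincident sphere centers", call. = FALSE)
  u <- u / D
  a <- (D^2 + r1^2 - r2^2) / (2 * D)
  rad2 <- r1^2 - a^2
  if (rad2 < 0)
    stop("gpcr_value_error: placement targets geometrically infeasible ",
         sprintf("(|centers| = %.2f, radii %.2f / %.2f)", D, r1, r2),
         call. = FALSE)
  centre <- c1 + a * u
  w <- (p - centre) - sum((p - centre) * u) * u
  if (.vnorm(w) < 1e-9) {
    w <- c(1, 0, 0) - u[1] * u
    if (.vnorm(w) < 1e-9) w <- c(0, 1, 0) - u[2] * u
  }
  centre + sqrt(rad2) * w / .vnorm(w)
}

# ---- state assembly ----------------------------------------------------

.rows_of_segment <- function(s, seg) {
  which(s$atom$resseq >= seg$start & s$atom$resseq <= seg$end &
          s$atom$chain == seg$chain)
}

.rows_of_residue <- function(s, resseq) which(s$atom$resseq == resseq)

.translate_rows <- function(s, rows, t) {
  s$atom$x[rows] <- s$atom$x[rows] + t[1]
  s$atom$y[rows] <- s$atom$y[rows] + t[2]
  s$atom$z[rows] <- s$atom$z[rows] + t[3]
  s
}

.atom_pos <- function(s, resseq, elety) {
  i <- which(s$atom$resseq == resseq & s$atom$elety == elety)[1]
  c(s$atom$x[i], s$atom$y[i], s$atom$z[i])
}

# overwrite side-chain coordinates of a ring residue at given chi targets
.set_sidechain_chis <- function(s, resseq, chi1, chi2) {
  rows <- .rows_of_residue(s, resseq)
  resname <- s$atom$resname[rows[1]]
  n <- .atom_pos(s, resseq, "N")
  ca <- .atom_pos(s, resseq, "CA")
  cb <- .atom_pos(s, resseq, "CB")
  sc <- .sidechain_atoms(resname, n, ca, cb, chi1, chi2)
  for (nm in names(sc)) {
    i <- rows[s$atom$elety[rows] == nm]
    s$atom$x[i] <- sc[[nm]][1]; s$atom$y[i] <- sc[[nm]][2]
    s$atom$z[i] <- sc[[nm]][3]
  }
  s
}

#' Build a synthetic receptor structure in one activation state
#'
#' Assembles the base bundle, then applies closed-form rigid helix moves
#' so that every configured indicator reproduces its target distance for
#' the requested state, and rebuilds the toggle side chains (3.36
#' phenylalanine, 6.48 tryptophan) at the state's chi targets.  With
#' `check = TRUE` the six indicators and (for state A) the TM3-aligned
#' 6.48 CA slide are verified against the configured targets.
#'
#' @param p a [bundle_params()].
#' @param state `"A"` (active) or `"I"` (inactive).
#' @param chi_override optional named vector overriding `chi1_336` /
#'   `chi2_648` for this build (used to pose toggle configurations).
#' @param tm6_fraction position of the extracellular (6.48-bearing) half
#'   of TM6 along its inactive-to-active slide path: 1 = active position,
#'   0 = inactive position.  Defaults to the state's own position.
#'   Intermediate values pose a partially slid main chain ("sliding"
#'   configuration frames).
#' @param check verify indicator targets after building.
#' @return a `gpcr_structure`.
#' @export
build_bundle <- function(p = bundle_params(), state = c("A", "I"),
                         chi_override = NULL, tm6_fraction = NULL,
                         check = TRUE) {
  state <- match.arg(state)
  base <- .base_bundle(p)
  s <- base
  segs <- p$segments
  tgt <- function(name) p$targets[[name]][[state]]

  # --- TM6, hinged at the kink below 6.48 (the CWxP region): the whole
  # helix is first placed so the cytoplasmic 3.50/6.34 CA distance equals
  # the inactive target; upon activation the cytoplasmic half splays
  # outward along that line to the active target, while the
  # extracellular half slides along the 6.48-to-3.36 swap axis by the
  # configured slide, exchanging the toggle side-chain positions.
  ca350 <- .atom_pos(s, 214, "CA")
  ca634 <- .atom_pos(s, 342, "CA")
  d0 <- atom_distance(ca350, ca634)
  d_i <- p$targets[["TM3-TM6"]][["I"]]
  d_a <- p$targets[["TM3-TM6"]][["A"]]
  t_i <- (d_i - d0) * .unit(ca634 - ca350)
  s <- .translate_rows(s, .rows_of_segment(s, segs["TM6", ]), t_i)
  tm6 <- segs["TM6", ]
  rows_cyt <- which(s$atom$resseq >= tm6$start & s$atom$resseq <= p$tm6_kink &
                      s$atom$chain == tm6$chain)
  rows_ext <- which(s$atom$resseq > p$tm6_kink & s$atom$resseq <= tm6$end &
                      s$atom$chain == tm6$chain)
  dhat <- .unit(.atom_pos(s, 342, "CA") - ca350)
  swap_axis <- .unit(.atom_pos(s, 200, "CB") - .atom_pos(s, 356, "CB"))
  frac <- if (!is.null(tm6_fraction)) tm6_fraction
          else if (state == "A") 1 else 0
  if (state == "A")
    s <- .translate_rows(s, rows_cyt, (d_a - d_i) * dhat)
  if (frac != 0)
    s <- .translate_rows(s, rows_ext, frac * p$slide_648 * swap_axis)

  # --- TM5: set Y5.58-Y7.53 (hydroxyl oxygens; TM5 carries only the
  # 5.58 marker, so moving it leaves every other constraint untouched)
  oh294 <- .atom_pos(s, 294, "OH")
  oh397 <- .atom_pos(s, 397, "OH")
  t5 <- (tgt("Y5.58-Y7.53") - atom_distance(oh294, oh397)) *
    .unit(oh294 - oh397)
  s <- .translate_rows(s, .rows_of_segment(s, segs["TM5", ]), t5)

  # --- TM2: set TM2-TM1 and TM2-TM7 simultaneously (two-sphere solve)
  cz174 <- .atom_pos(s, 174, "CZ")
  o120 <- .atom_pos(s, 120, "O")
  o380 <- .atom_pos(s, 380, "O")
  x <- .solve_two_sphere(cz174, o120, tgt("TM2-TM1"), o380, tgt("TM2-TM7"))
  s <- .translate_rows(s, .rows_of_segment(s, segs["TM2", ]), x - cz174)

  # --- N-terminal probe: set NT-F3.25 and NT-ECL2 (ring centroids)
  c102 <- ring_centroid(get_residue(s, p$chain, 102))
  c189 <- ring_centroid(get_residue(s, p$chain, 189))
  c268 <- ring_centroid(get_residue(s, p$chain, 268))
  xn <- .solve_two_sphere(c102, c189, tgt("NT-F3.25"), c268, tgt("NT-ECL2"))
  s <- .translate_rows(s, .rows_of_residue(s, 102), xn - c102)

  # --- toggle side chains at the state's chi targets
  chi1_336 <- p$chi[[state]][["chi1_336"]]
  chi2_648 <- p$chi[[state]][["chi2_648"]]
  if (!is.null(chi_override)) {
    if ("chi1_336" %in% names(chi_override))
      chi1_336 <- chi_override[["chi1_336"]]
    if ("chi2_648" %in% names(chi_override))
      chi2_648 <- chi_override[["chi2_648"]]
  }
  s <- .set_sidechain_chis(s, 200, chi1_336, p$chi_other[["chi2"]])
  s <- .set_sidechain_chis(s, 356, p$chi_other[["chi1"]], chi2_648)
  s$id <- sprintf("synthetic_cb1_%s", if (state == "A") "active" else "inactive")

  if (check && is.null(chi_override) && is.null(tm6_fraction))
    .check_bundle(s, p, state)
  s
}

.check_bundle <- function(s, p, state) {
  specs <- builtin_cb1_indicator_set()
  for (nm in names(p$targets)) {
    v <- evaluate_indicator(s, specs[[nm]], p$map)
    if (is.na(v) || abs(v - p$targets[[nm]][[state]]) > p$check_tol)
      stop(sprintf(
        "gpcr_builder_error: indicator %s = %.3f, target %.3f (state %s)",
        nm, v, p$targets[[nm]][[state]], state), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the matched inactive/active synthetic structure pair
#'
#' `kind = "cb1"` reproduces the CB1-like activation movements (TM6
#' slide, TM7 shift, TM2 inward move, N-terminal probe insertion, toggle
#' rotamer swap).  `kind = "rigid_tm6"` moves only TM6 by a 3 A rigid
#' translation between the two structures; `kind = "rigid_tm4"` moves
#' only TM4, leaving the toggle-switch environment untouched (a receptor
#' whose 3.36/6.48 contact does not change upon activation).
#'
#' @param p a [bundle_params()].
#' @param kind pair flavour, see above.
#' @return list with `inactive` and `active` structures.
#' @export
build_state_pair <- function(p = bundle_params(),
                             kind = c("cb1", "rigid_tm6", "rigid_tm4")) {
  kind <- match.arg(kind)
  inactive <- build_bundle(p, "I")
  if (kind == "cb1") {
    active <- build_bundle(p, "A")
  } else {
    seg <- p$segments[if (kind == "rigid_tm6") "TM6" else "TM4", ]
    active <- .translate_rows(inactive, .rows_of_segment(inactive, seg),
                              c(3, 0, 0))
    active$id <- paste0("synthetic_", kind, "_moved")
  }
  list(inactive = inactive, active = active)
}

# ---- trajectories ------------------------------------------------------

#' Define a trajectory schedule
#'
#' @param segments list of `list(state = "A"|"I", frames = n)` held
#'   segments, in order.
#' @param interp_frames number of linearly interpolated frames inserted
#'   between consecutive segments of different states.
#' @param noise_sd isotropic Gaussian coordinate noise per atom, Angstrom.
#' @param seed RNG seed (the generator is bit-reproducible given the seed).
#' @param frame_interval frame spacing, ns.
#' @return list of class `trajectory_schedule`.
#' @export
trajectory_schedule <- function(segments, interp_frames = 0, noise_sd = 0,
                                seed = 1, frame_interval = 1) {
  stopifnot(length(segments) >= 1, interp_frames >= 0, noise_sd >= 0)
  total <- sum(vapply(segments, `[[`, numeric(1), "frames"))
  if (total < 1)
    stop("gpcr_value_error: schedule has no frames", call. = FALSE)
  structure(list(segments = segments, interp_frames = interp_frames,
                 noise_sd = noise_sd, seed = seed,
                 frame_interval = frame_interval),
            class = "trajectory_schedule")
}

#' Generate a synthetic frame series with known ground truth
#'
#' Held segments repeat the state geometry; transitions between segments
#' of different states are linear Cartesian interpolations over
#' `interp_frames` frames; i.i.d. Gaussian noise is then added to every
#' coordinate.  Identical seeds give bit-identical output.
#'
#' @param p a [bundle_params()].
#' @param sched a [trajectory_schedule()].
#' @return list with `frames` (a `gpcr_frames`) and `truth` (data frame:
#'   frame, time_ns, state, toggle; plus attribute `transitions`, the
#'   scheduled transition midpoint frame indices).
#' @export
generate_trajectory <- function(p = bundle_params(), sched) {
  stopifnot(inherits(sched, "trajectory_schedule"))
  states <- list(A = build_bundle(p, "A"), I = build_bundle(p, "I"))
  xyz_state <- lapply(states, function(s) as.numeric(t(coords(s))))
  toggle_of <- c(A = "active", I = "inactive")

  rows <- list(); labels <- character(0); toggles <- character(0)
  transitions <- integer(0)
  segs <- sched$segments
  for (j in seq_along(segs)) {
    st <- segs[[j]]$state
    if (j > 1 && segs[[j - 1]]$state != st && sched$interp_frames > 0) {
      from <- xyz_state[[segs[[j - 1]]$state]]
      to <- xyz_state[[st]]
      k <- sched$interp_frames
      for (m in seq_len(k)) {
        w <- m / (k + 1)
        rows[[length(rows) + 1]] <- (1 - w) * from + w * to
        labels <- c(labels, "transition")
        toggles <- c(toggles,
                     toggle_of[[if (w < 0.5) segs[[j - 1]]$state else st]])
      }
      transitions <- c(transitions,
                       length(rows) - sched$interp_frames / 2)
    } else if (j > 1 && segs[[j - 1]]$state != st) {
      transitions <- c(transitions, length(rows) + 1L)
    }
    for (m in seq_len(segs[[j]]$frames)) {
      rows[[length(rows) + 1]] <- xyz_state[[st]]
      labels <- c(labels, st)
      toggles <- c(toggles, toggle_of[[st]])
    }
  }
  xyz <- do.call(rbind, rows)
  if (sched$noise_sd > 0) {
    set.seed(sched$seed)
    xyz <- xyz + stats::rnorm(length(xyz), sd = sched$noise_sd)
  }
  times <- seq_len(nrow(xyz)) * sched$frame_interval
  fs <- frame_series(states$A, xyz, times)
  fs$topology$id <- "synthetic_trajectory"
  truth <- data.frame(frame = seq_len(nrow(xyz)), time_ns = times,
                      state = labels, toggle = toggles,
                      stringsAsFactors = FALSE)
  attr(truth, "transitions") <- transitions
  list(frames = fs, truth = truth)
}

#' Generate posed toggle-configuration frames with chi jitter
#'
#' Builds frames at the canonical geometry of each requested twin-toggle
#' configuration, with Gaussian jitter applied directly to the toggle chi
#' angles (and, for `sliding`, TM6 posed halfway along its slide path).
#' Used to test classifier recovery against known labels.
#'
#' @param p a [bundle_params()].
#' @param labels configurations to generate, from `active`, `inactive`,
#'   `reversed_inactive`, `pushed`, `sliding`.
#' @param n_per_label frames per configuration.
#' @param chi_sd angular jitter standard deviation, degrees.
#' @param seed RNG seed.
#' @return list with `structures` (list of `gpcr_structure`) and `labels`
#'   (character vector of generating configurations).
#' @export
generate_toggle_frames <- function(p = bundle_params(),
                                   labels = c("active", "inactive",
                                              "reversed_inactive", "pushed",
                                              "sliding"),
                                   n_per_label = 10, chi_sd = 0, seed = 1) {
  set.seed(seed)
  chiA <- p$chi$A; chiI <- p$chi$I
  pose <- list(
    active = list(state = "A", frac = NULL,
                  chi = c(chi1_336 = chiA[["chi1_336"]],
                          chi2_648 = chiA[["chi2_648"]])),
    inactive = list(state = "I", frac = NULL,
                    chi = c(chi1_336 = chiI[["chi1_336"]],
                            chi2_648 = chiI[["chi2_648"]])),
    reversed_inactive = list(state = "A", frac = NULL,
                             chi = c(chi1_336 = chiI[["chi1_336"]],
                                     chi2_648 = chiI[["chi2_648"]])),
    pushed = list(state = "A", frac = NULL,
                  chi = c(chi1_336 = chiA[["chi1_336"]],
                          chi2_648 = chiI[["chi2_648"]] + 120)),
    sliding = list(state = "A", frac = 0.5,
                   chi = c(chi1_336 = chiA[["chi1_336"]],
                           chi2_648 = chiA[["chi2_648"]] - 70)))
  bad <- setdiff(labels, names(pose))
  if (length(bad))
    stop("gpcr_value_error: unknown toggle labels: ",
         paste(bad, collapse = ","), call. = FALSE)
  # one full build per pose; per-frame variation touches only the two
  # toggle side chains, so jittered frames are cheap
  base_of <- lapply(pose[unique(labels)], function(po)
    build_bundle(p, po$state, chi_override = po$chi,
                 tm6_fraction = po$frac, check = FALSE))
  structures <- list(); out_labels <- character(0)
  for (lab in labels) {
    po <- pose[[lab]]
    for (m in seq_len(n_per_label)) {
      jit <- if (chi_sd > 0) stats::rnorm(2, sd = chi_sd) else c(0, 0)
      st <- base_of[[lab]]
      st <- .set_sidechain_chis(st, 200, po$chi[["chi1_336"]] + jit[1],
                                p$chi_other[["chi2"]])
      st <- .set_sidechain_chis(st, 356, p$chi_other[["chi1"]],
                                po$chi[["chi2_648"]] + jit[2])
      st$id <- sprintf("toggle_%s_%03d", lab, m)
      structures[[length(structures) + 1]] <- st
      out_labels <- c(out_labels, lab)
    }
  }
  list(structures = structures, labels = out_labels)
}

#' Two-residue probe for contact-score unit checks
#'
#' Two residues on one chain, far apart in sequence, whose closest
#' heavy-atom pair is exactly `d` Angstrom apart; additional atoms (if
#' requested) are placed strictly farther away.
#'
#' @param d closest heavy-atom distance, Angstrom.
#' @param extra_a,extra_b additional atoms per residue beyond the closest
#'   pair.
#' @return a `gpcr_structure` with residues 1 and 50 (chain A).
#' @export
make_two_residue_probe <- function(d, extra_a = 0, extra_b = 0) {
  stopifnot(d > 0, extra_a >= 0, extra_b >= 0)
  mk <- function(resseq, x0, dir, n_extra) {
    elety <- c("CB", if (n_extra > 0) paste0("C", seq_len(n_extra) + 1, "X"))
    data.frame(chain = "A", resseq = resseq, icode = "", resname = "UNK",
               elety = elety, elesy = "C",
               x = x0 + dir * 3 * (seq_len(n_extra + 1) - 1),
               y = 0, z = 0, stringsAsFactors = FALSE)
  }
  gpcr_structure(rbind(mk(1, 0, -1, extra_a), mk(50, d, 1, extra_b)),
                 id = "two_residue_probe")
}
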