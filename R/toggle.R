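# Twin toggle switch classification.
#
# The F3.36/W6.48 pair is observed per frame as (chi1 of 3.36, chi2 of
# 6.48, whether the two ring centroids have swapped order along the
# reference axis, and how far the 6.48 CA has slid from its active-state
# position), then classified into the configurations seen in the CB1
# trajectories: active, inactive, reversed-inactive, pushed, sliding.

#' Observe the toggle-switch state of one frame
#'
#' The frame is TM3-aligned onto the inactive reference.  `pos_reversed`
#' compares the order of the 3.36 and 6.48 side-chain positions along the
#' reference axis (the inactive reference's 6.48-to-3.36 direction),
#' anchoring each side chain at its CB atom so the feature tracks where
#' the residue sits rather than which rotamer it adopts: when the frame's
#' positions project in swapped order the side chains have exchanged
#' places, as in the active structure.
#' `ca_slide_648` is the displacement of the frame's 6.48 CA from its
#' position in the active reference (both TM3-aligned onto the inactive
#' reference) — the slide of the toggle tryptophan's main chain toward
#' the inactive state.
#'
#' @param frame a `gpcr_structure`.
#' @param map a [bw_map()] resolving "3.36" and "6.48".
#' @param inactive_ref,active_ref reference `gpcr_structure`s.
#' @param tm3_range `c(start, end)` residue numbers of TM3.
#' @param chain chain id.
#' @return object of class `toggle_observation`: list with `chi1_336`,
#'   `chi2_648` (degrees), `pos_reversed` (logical), `ca_slide_648`
#'   (Angstrom).
#' @export
observe_toggle <- function(frame, map, inactive_ref, active_ref, tm3_range,
                           chain = "A") {
  r336 <- resolve_label(frame, map, "3.36")
  r648 <- resolve_label(frame, map, "6.48")
  if (toupper(r336$resname) %in% c("ALA", "GLY") ||
      toupper(r648$resname) %in% c("ALA", "GLY"))
    stop(structure(class = c("gpcr_mutant_error", "error", "condition"),
                   list(message = paste(
                     "toggle residue mutated to Ala/Gly (classifier",
                     "inapplicable to the double mutant)"), call = NULL)))
  chi1 <- chi_angles(r336)$chi1
  chi2 <- chi_angles(r648)$chi2

  # TM3 alignment of frame and active reference onto the inactive reference
  pr_f <- pair_ca(inactive_ref, frame, tm3_range, chain, what = "TM3 alignment")
  xf_f <- superpose(pr_f$b, pr_f$a)
  pr_a <- pair_ca(inactive_ref, active_ref, tm3_range, chain,
                  what = "TM3 alignment")
  xf_a <- superpose(pr_a$b, pr_a$a)

  # side-chain positions are anchored at CB so the swap feature reflects
  # where each residue sits, independent of its rotamer
  cb336_i <- residue_atom_xyz(resolve_label(inactive_ref, map, "3.36"), "CB")
  cb648_i <- residue_atom_xyz(resolve_label(inactive_ref, map, "6.48"), "CB")
  axis <- .unit(cb336_i - cb648_i)
  cb336_f <- apply_transform(xf_f, residue_atom_xyz(r336, "CB"))
  cb648_f <- apply_transform(xf_f, residue_atom_xyz(r648, "CB"))
  pos_reversed <- sum((cb336_f - cb648_f) * axis) < 0

  ca_f <- apply_transform(xf_f, residue_atom_xyz(r648, "CA"))
  ca_a <- apply_transform(xf_a,
    residue_atom_xyz(resolve_label(active_ref, map, "6.48"), "CA"))
  slide <- atom_distance(ca_f, ca_a)

  structure(list(chi1_336 = chi1, chi2_648 = chi2,
                 pos_reversed = pos_reversed, ca_slide_648 = slide),
            class = "toggle_observation")
}

#' Classification geometry for the twin toggle switch
#'
#' @param centroids named list of `c(chi1, chi2)` degree pairs for labels
#'   `active`, `inactive`, `pushed` (chi1 refers to 3.36, chi2 to 6.48).
#' @param window angular half-width of each centroid's square (L-infinity)
#'   acceptance region on the chi torus, degrees.
#' @param slide_threshold main-chain slide (Angstrom) above which an
#'   active-chi1 / shifted-chi2 observation is called `sliding`.
#' @return object of class `centroid_table`.
#' @export
centroid_table <- function(centroids, window = 40, slide_threshold = 2.0) {
  stopifnot(window > 0, slide_threshold >= 0)
  need <- c("active", "inactive", "pushed")
  if (!all(need %in% names(centroids)))
    stop("gpcr_config_error: centroid table needs labels ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(centroids = centroids, window = window,
                 slide_threshold = slide_threshold),
            class = "centroid_table")
}

#' Default centroid table measured from the reference structures
#'
#' Active and inactive chi centroids are measured directly from the
#' reference structures rather than hard-coded; the `pushed` centroid is
#' the inactive chi2 rotamer of W6.48 displaced by +120 degrees (the
#' novel rotamer region), with the active chi1 of F3.36.
#'
#' @param active_ref,inactive_ref reference `gpcr_structure`s.
#' @param map a [bw_map()].
#' @param window,slide_threshold see [centroid_table()].
#' @return a `centroid_table`.
#' @export
default_centroid_table <- function(active_ref, inactive_ref, map,
                                   window = 40, slide_threshold = 2.0) {
  chi_of <- function(s) {
    c(chi_angles(resolve_label(s, map, "3.36"))$chi1,
      chi_angles(resolve_label(s, map, "6.48"))$chi2)
  }
  a <- chi_of(active_ref); i <- chi_of(inactive_ref)
  centroid_table(list(active = a, inactive = i,
                      pushed = c(a[1], wrap_angle(i[2] + 120))),
                 window = window, slide_threshold = slide_threshold)
}

#' Classify a toggle observation
#'
#' Decision rule: the observation's (chi1, chi2) is matched to the
#' nearest centroid within the angular window under the L-infinity torus
#' metric.  A match to `inactive` splits on the positional feature:
#' swapped positions give `reversed_inactive`, unswapped give `inactive`.
#' When no centroid matches but chi1 is still active-like and the 6.48
#' main chain has slid beyond the threshold, the configuration is
#' `sliding`.  Anything else is `unassigned`; the rule is total and
#' deterministic.
#'
#' @param obs a `toggle_observation` (or list with the same fields).
#' @param table a [centroid_table()].
#' @return one of `"active"`, `"inactive"`, `"reversed_inactive"`,
#'   `"pushed"`, `"sliding"`, `"unassigned"`.
#' @export
classify_toggle <- function(obs, table) {
  stopifnot(inherits(table, "centroid_table"))
  chi <- c(obs$chi1_336, obs$chi2_648)
  dist_to <- vapply(table$centroids, function(ct)
    max(angle_diff(chi[1], ct[1]), angle_diff(chi[2], ct[2])), numeric(1))
  within <- dist_to <= table$window
  if (any(within)) {
    lab <- names(dist_to)[within][which.min(dist_to[within])]
    if (lab == "inactive")
      return(if (isTRUE(obs$pos_reversed)) "reversed_inactive" else "inactive")
    return(lab)
  }
  chi1_active <- angle_diff(chi[1], table$centroids$active[1]) <= table$window
  if (chi1_active && !is.na(obs$ca_slide_648) &&
      obs$ca_slide_648 > table$slide_threshold)
    return("sliding")
  "unassigned"
}

#' Classify every frame of a series
#'
#' @param fs a `gpcr_frames` (or list of `gpcr_structure`s).
#' @param map a [bw_map()].
#' @param inactive_ref,active_ref reference structures.
#' @param tm3_range TM3 residue range.
#' @param table a [centroid_table()]; default measured from the references.
#' @param chain chain id.
#' @return data frame: time_ns (or frame), chi1_deg, chi2_deg,
#'   pos_reversed, ca_slide_A, label.
#' @export
classify_frames <- function(fs, map, inactive_ref, active_ref, tm3_range,
                            table = default_centroid_table(active_ref,
                                                           inactive_ref, map),
                            chain = "A") {
  structures <- if (inherits(fs, "gpcr_frames"))
    lapply(seq_len(n_frames(fs)), function(i) frame_structure(fs, i))
  else fs
  times <- if (inherits(fs, "gpcr_frames")) fs$times
           else seq_along(structures)
  rows <- lapply(seq_along(structures), function(i) {
    obs <- observe_toggle(structures[[i]], map, inactive_ref, active_ref,
                          tm3_range, chain)
    data.frame(time_ns = times[i], chi1_deg = obs$chi1_336,
               chi2_deg = obs$chi2_648, pos_reversed = obs$pos_reversed,
               ca_slide_A = obs$ca_slide_648,
               label = classify_toggle(obs, table),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of frames in the "active" configuration
#'
#' Pools all frames across runs (a per-run average is available with
#' `per_run_average = TRUE`).  Near 1 for full agonists, around 0.85 for
#' partial agonist / neutral antagonist / apo, and 0 for inverse
#' agonists in the CB1 study design.
#'
#' @param labels character vector of per-frame configuration labels, or a
#'   list of such vectors (one per run).
#' @param per_run_average average the per-run ratios instead of pooling
#'   by frame count.
#' @return fraction in `[0, 1]`.
#' @export
active_ratio <- function(labels, per_run_average = FALSE) {
  runs <- if (is.list(labels)) labels else list(labels)
  if (!length(runs) || !sum(lengths(runs)))
    stop("gpcr_value_error: no frames to summarize", call. = FALSE)
  if (per_run_average)
    mean(vapply(runs, function(r) mean(r == "active"), numeric(1)))
  else {
    all_labels <- unlist(runs, use.names = FALSE)
    mean(all_labels == "active")
  }
}

#' Maximal constant-label dwell segments
#'
#' @param labels per-frame labels.
#' @param times per-frame times (ns), aligned with `labels`.
#' @return data frame: label, start_ns, end_ns, frames.
#' @export
dwell_segments <- function(labels, times) {
  if (length(labels) != length(times))
    stop("gpcr_value_error: labels and times lengths differ", call. = FALSE)
  if (!length(labels))
    stop("gpcr_value_error: empty input", call. = FALSE)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  data.frame(label = r$values, start_ns = times[starts],
             end_ns = times[ends], frames = r$lengths,
             stringsAsFactors = FALSE)
}
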