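# Activation-state indicators.
#
# Each indicator is a named distance between two endpoints, an endpoint
# being either a named atom of a generically-numbered residue or the
# centroid of a side-chain benzene ring.  Reference values measured on the
# inactive and active structures, where known, are attached to the spec so
# frames can be called active-like / inactive-like / intermediate.

#' Define a distance indicator
#'
#' @param name indicator name.
#' @param label_a,label_b generic-number labels of the two endpoint residues.
#' @param mode_a,mode_b `"atom"` or `"ring"`.
#' @param atom_a,atom_b atom names (used when mode is `"atom"`).  Tyr's
#'   hydroxyl oxygen ("O-eta") is the PDB atom `OH`.
#' @param ref_inactive,ref_active reference distances in Angstrom, or `NA`
#'   when not measurable.
#' @param optional_labels labels whose absence from a structure yields a
#'   flagged `NA` value rather than an error (the unresolved N-terminal
#'   residue case).
#' @return object of class `indicator_spec`.
#' @export
indicator_spec <- function(name, label_a, label_b,
                           mode_a = "atom", mode_b = "atom",
                           atom_a = "CA", atom_b = "CA",
                           ref_inactive = NA_real_, ref_active = NA_real_,
                           optional_labels = character(0)) {
  stopifnot(mode_a %in% c("atom", "ring"), mode_b %in% c("atom", "ring"))
  if (!is.na(ref_inactive) && ref_inactive <= 0)
    stop("gpcr_value_error: reference distances must be positive", call. = FALSE)
  if (!is.na(ref_active) && ref_active <= 0)
    stop("gpcr_value_error: reference distances must be positive", call. = FALSE)
  structure(list(name = name,
                 a = list(label = label_a, mode = mode_a, atom = atom_a),
                 b = list(label = label_b, mode = mode_b, atom = atom_b),
                 ref_inactive = ref_inactive, ref_active = ref_active,
                 optional_labels = optional_labels),
            class = "indicator_spec")
}

#' The six CB1 activation indicators
#'
#' Distances tracking the cytoplasmic part (Y5.58-Y7.53 hydroxyl-oxygen
#' distance for the TM7 distortion; TM3-TM6 CA distance at 3.50/6.34 for
#' the cytoplasmic splay), the orthosteric pocket (TM2-TM1 and TM2-TM7,
#' from the 2.61 ring-tip CZ to backbone carbonyl O atoms at 1.36 / 7.36)
#' and the N-terminus insertion (ring-centroid distances N-term to 3.25
#' and N-term to ECL2).  Reference values for CB1: Y5.58-Y7.53 10.5 A
#' inactive / 3.4 A active; TM3-TM6 8.2 A inactive / 13.8 A active.  The
#' N-terminal indicators carry no active-state reference because the
#' N-terminal phenylalanine is unresolved in the active structure.
#'
#' @return named list of six [indicator_spec()] objects.
#' @export
builtin_cb1_indicator_set <- function() {
  specs <- list(
    indicator_spec("Y5.58-Y7.53", "5.58", "7.53",
                   atom_a = "OH", atom_b = "OH",
                   ref_inactive = 10.5, ref_active = 3.4),
    indicator_spec("TM3-TM6", "3.50", "6.34",
                   atom_a = "CA", atom_b = "CA",
                   ref_inactive = 8.2, ref_active = 13.8),
    indicator_spec("TM2-TM1", "2.61", "1.36",
                   atom_a = "CZ", atom_b = "O"),
    indicator_spec("TM2-TM7", "2.61", "7.36",
                   atom_a = "CZ", atom_b = "O"),
    indicator_spec("NT-F3.25", "N-term", "3.25",
                   mode_a = "ring", mode_b = "ring",
                   optional_labels = "N-term"),
    indicator_spec("NT-ECL2", "N-term", "ECL2",
                   mode_a = "ring", mode_b = "ring",
                   optional_labels = "N-term"))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Resolve one endpoint to a point; NULL when an optional label is absent.
.endpoint_point <- function(s, ep, map, optional_labels) {
  res <- tryCatch(resolve_label(s, map, ep$label),
                  gpcr_lookup_error = function(e) {
                    if (ep$label %in% optional_labels) return(NULL)
                    stop(e)
                  })
  if (is.null(res)) return(NULL)
  if (ep$mode == "ring") ring_centroid(res)
  else residue_atom_xyz(res, ep$atom)
}

#' Evaluate an indicator on a structure
#'
#' @param s a `gpcr_structure`.
#' @param spec an [indicator_spec()].
#' @param map a [bw_map()].
#' @return distance in Angstrom; `NA` with attribute `missing_endpoint`
#'   when an optional endpoint residue is absent.
#' @export
evaluate_indicator <- function(s, spec, map) {
  pa <- .endpoint_point(s, spec$a, map, spec$optional_labels)
  pb <- .endpoint_point(s, spec$b, map, spec$optional_labels)
  if (is.null(pa) || is.null(pb)) {
    miss <- c(if (is.null(pa)) spec$a$label, if (is.null(pb)) spec$b$label)
    return(structure(NA_real_, missing_endpoint = miss))
  }
  atom_distance(pa, pb)
}

# Precompute atom-row indices of an endpoint on a frame topology so a
# whole series can be evaluated without re-resolving labels per frame.
.endpoint_rows <- function(topo, ep, map, optional_labels) {
  res <- tryCatch(resolve_label(topo, map, ep$label),
                  gpcr_lookup_error = function(e) {
                    if (ep$label %in% optional_labels) return(NULL)
                    stop(e)
                  })
  if (is.null(res)) return(NULL)
  names_needed <- if (ep$mode == "ring") ring_atom_names(res$resname)
                  else .resolve_atom_alias(ep$atom)
  key <- residue_keys(topo)
  rk <- paste(res$chain, res$resseq, res$icode, sep = "/")
  rows <- which(key == rk & topo$atom$elety %in% names_needed)
  if (length(rows) != length(names_needed))
    stop(structure(class = c("gpcr_missing_atom_error", "error", "condition"),
                   list(message = sprintf(
                     "indicator endpoint %s: missing atom(s) %s", ep$label,
                     paste(setdiff(names_needed, topo$atom$elety[rows]),
                           collapse = ",")), call = NULL)))
  rows
}

#' Evaluate indicators over a frame series
#'
#' @param fs a `gpcr_frames`.
#' @param specs list of [indicator_spec()] (default the CB1 set).
#' @param map a [bw_map()].
#' @return data frame with columns `time_ns`, `indicator`, `value_A`
#'   (one row per frame per indicator), class `indicator_series`.
#' @export
indicator_series <- function(fs, specs = builtin_cb1_indicator_set(), map) {
  out <- lapply(specs, function(spec) {
    ra <- .endpoint_rows(fs$topology, spec$a, map, spec$optional_labels)
    rb <- .endpoint_rows(fs$topology, spec$b, map, spec$optional_labels)
    if (is.null(ra) || is.null(rb)) {
      v <- rep(NA_real_, n_frames(fs))
    } else {
      point <- function(rows, i) {
        m <- matrix(fs$xyz[i, bio3d::atom2xyz(rows)], ncol = 3, byrow = TRUE)
        colMeans(m)
      }
      v <- vapply(seq_len(n_frames(fs)),
                  function(i) atom_distance(point(ra, i), point(rb, i)),
                  numeric(1))
    }
    data.frame(time_ns = fs$times, indicator = spec$name, value_A = v,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(time_ns = numeric(0), indicator = character(0),
                         value_A = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("indicator_series", "data.frame")
  res
}

#' Call per-frame activation state from an indicator trace
#'
#' A frame is `active-like` when the value is within `tolerance` of the
#' active reference, `inactive-like` when within `tolerance` of the
#' inactive reference (the nearer reference wins when both match; an
#' exact tie is `intermediate`), and `intermediate` otherwise.
#'
#' @param values numeric indicator values (Angstrom).
#' @param spec an [indicator_spec()] carrying both references.
#' @param tolerance matching half-width in Angstrom (default 1.0).
#' @return character vector of per-frame labels.
#' @export
call_state <- function(values, spec, tolerance = 1.0) {
  if (is.na(spec$ref_active) || is.na(spec$ref_inactive))
    stop("gpcr_config_error: indicator '", spec$name,
         "' lacks reference values for state calling", call. = FALSE)
  da <- abs(values - spec$ref_active)
  di <- abs(values - spec$ref_inactive)
  lab <- rep("intermediate", length(values))
  lab[da <= tolerance & (da < di | di > tolerance)] <- "active-like"
  lab[di <= tolerance & (di < da | da > tolerance)] <- "inactive-like"
  lab
}

#' TM3-aligned displacement of the 6.48 CA atom between two structures
#'
#' Superposes the active structure onto the inactive one using the TM3 CA
#' atoms and reports how far the toggle tryptophan's CA moved — the
#' "slide" of TM6 against TM3 upon activation (6.8 A between the CB1
#' inactive and active structures).
#'
#' @param inactive,active `gpcr_structure` objects.
#' @param map a [bw_map()] resolving "6.48".
#' @param tm3_range `c(start, end)` residue numbers of TM3.
#' @param chain chain id (default "A").
#' @return displacement in Angstrom.
#' @export
toggle_ca_displacement <- function(inactive, active, map, tm3_range,
                                   chain = "A") {
  pr <- pair_ca(inactive, active, tm3_range, chain, strict = TRUE,
                what = "TM3 alignment")
  xf <- superpose(pr$b, pr$a)   # active -> inactive frame
  ca_i <- residue_atom_xyz(resolve_label(inactive, map, "6.48"), "CA")
  ca_a <- residue_atom_xyz(resolve_label(active, map, "6.48"), "CA")
  atom_distance(apply_transform(xf, ca_a), ca_i)
}

#' Per-frame minimized CA RMSD to a reference structure
#'
#' @param fs a `gpcr_frames`.
#' @param reference a `gpcr_structure`.
#' @param ranges list of `c(start, end)` residue ranges (the CB1 analysis
#'   uses 106-306 and 335-411, skipping the third intracellular loop).
#' @param chain chain id.
#' @return data frame `time_ns`, `indicator`, `value_A` with indicator
#'   `"RMSD"` tagged by the reference structure id.
#' @export
overall_rmsd_trace <- function(fs, reference, ranges, chain = "A") {
  topo <- fs$topology
  at <- topo$atom
  keep <- at$chain == chain & at$elety == "CA" & at$icode == "" &
    Reduce(`|`, lapply(ranges, function(r) at$resseq >= r[1] & at$resseq <= r[2]))
  res_t <- at$resseq[keep]
  rt <- reference$atom
  keep_r <- rt$chain == chain & rt$elety == "CA" & rt$icode == "" &
    rt$resseq %in% res_t
  res_r <- rt$resseq[keep_r]
  if (!setequal(res_t, res_r))
    stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                   list(message = sprintf(
                     "RMSD trace: unpaired residues %s",
                     paste(union(setdiff(res_t, res_r), setdiff(res_r, res_t)),
                           collapse = ",")), call = NULL)))
  rows_t <- which(keep)[order(res_t)]
  ref_xyz <- as.matrix(rt[keep_r, c("x", "y", "z")])[order(res_r), ]
  v <- vapply(seq_len(n_frames(fs)), function(i) {
    m <- matrix(fs$xyz[i, bio3d::atom2xyz(rows_t)], ncol = 3, byrow = TRUE)
    superpose(m, ref_xyz)$rmsd
  }, numeric(1))
  data.frame(time_ns = fs$times,
             indicator = paste0("RMSD:", reference$id),
             value_A = v, stringsAsFactors = FALSE)
}

#' Write an indicator series to TSV
#' @param series data frame from [indicator_series()].
#' @param path output file.
#' @export
write_indicator_tsv <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
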