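# Coordinate data model.
#
# A `gpcr_structure` is a light wrapper around a flat atom table:
#   chain, resseq, icode, resname, elety (PDB atom name), elesy (element),
#   x, y, z (Angstrom), hydrogen (logical flag).
# Hydrogens are retained on read but flagged; all scoring and geometry
# downstream uses heavy atoms unless asked otherwise.

.atom_cols <- c("chain", "resseq", "icode", "resname", "elety", "elesy",
                "x", "y", "z", "hydrogen")

#' Construct a structure from an atom table
#'
#' @param atom data frame with columns chain, resseq, icode, resname,
#'   elety, elesy, x, y, z (hydrogen flag added if absent).
#' @param id identifier string.
#' @return object of class `gpcr_structure`.
#' @export
gpcr_structure <- function(atom, id = "structure") {
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  if (is.null(atom$icode)) atom$icode <- ""
  atom$icode[is.na(atom$icode)] <- ""
  if (is.null(atom$elesy) || all(is.na(atom$elesy)))
    atom$elesy <- .guess_element(atom$elety)
  if (is.null(atom$hydrogen))
    atom$hydrogen <- toupper(atom$elesy) == "H"
  missing_cols <- setdiff(.atom_cols, names(atom))
  if (length(missing_cols))
    stop("gpcr_format_error: atom table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("gpcr_format_error: non-finite coordinates", call. = FALSE)
  if (any(!nzchar(atom$elety)))
    stop("gpcr_format_error: empty atom name", call. = FALSE)
  atom <- atom[, .atom_cols]
  rownames(atom) <- NULL
  # atom names unique within each residue
  key <- paste(atom$chain, atom$resseq, atom$icode, atom$elety)
  if (anyDuplicated(key))
    stop("gpcr_format_error: duplicate atom name within a residue: ",
         key[duplicated(key)][1], call. = FALSE)
  structure(list(id = id, atom = atom), class = "gpcr_structure")
}

.guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety))
  two <- toupper(substr(nm, 1, 2))
  el <- toupper(substr(nm, 1, 1))
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  el
}

#' @export
print.gpcr_structure <- function(x, ...) {
  cat(sprintf("gpcr_structure '%s': %d atoms, %d residues, chains: %s\n",
              x$id, nrow(x$atom), length(unique(residue_keys(x))),
              paste(unique(x$atom$chain), collapse = ",")))
  invisible(x)
}

#' Per-atom residue keys "chain/resseq/icode"
#' @param s a `gpcr_structure`.
#' @return character vector, one entry per atom.
#' @export
residue_keys <- function(s) {
  paste(s$atom$chain, s$atom$resseq, s$atom$icode, sep = "/")
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s a `gpcr_structure`.
#' @param heavy_only drop hydrogens first.
#' @return numeric matrix.
#' @export
coords <- function(s, heavy_only = FALSE) {
  a <- s$atom
  if (heavy_only) a <- a[!a$hydrogen, ]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Replace the coordinates of a structure
#' @param s a `gpcr_structure`.
#' @param xyz n x 3 matrix matching the atom count.
#' @return the updated structure.
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(s$atom))
    stop("gpcr_topology_error: coordinate count does not match atom count",
         call. = FALSE)
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

#' Extract one residue
#'
#' @param s a `gpcr_structure`.
#' @param chain chain identifier.
#' @param resseq residue number.
#' @param icode insertion code ("" by default; part of the residue key).
#' @return object of class `gpcr_residue`: list with chain, resseq, icode,
#'   resname and the residue's atom table.
#' @export
get_residue <- function(s, chain, resseq, icode = "") {
  sel <- s$atom$chain == chain & s$atom$resseq == resseq & s$atom$icode == icode
  if (!any(sel))
    stop(structure(class = c("gpcr_lookup_error", "error", "condition"),
                   list(message = sprintf("residue %s%d%s not found in '%s'",
                                          chain, resseq, icode, s$id),
                        call = NULL)))
  a <- s$atom[sel, ]
  structure(list(chain = chain, resseq = resseq, icode = icode,
                 resname = a$resname[1], atom = a),
            class = "gpcr_residue")
}

#' Coordinates of a named atom in a residue
#'
#' @param res a `gpcr_residue`.
#' @param name PDB atom name.  The alias "OH1"/"OEta" handling: Tyr's
#'   hydroxyl oxygen is the PDB atom `OH` (the "O-eta" atom of the
#'   indicator definitions).
#' @param required error (class `gpcr_missing_atom_error`) if absent;
#'   otherwise return `NULL`.
#' @return numeric 3-vector or `NULL`.
#' @export
residue_atom_xyz <- function(res, name, required = TRUE) {
  name <- .resolve_atom_alias(name)
  i <- match(name, res$atom$elety)
  if (is.na(i)) {
    if (!required) return(NULL)
    stop(structure(class = c("gpcr_missing_atom_error", "error", "condition"),
                   list(message = sprintf("residue %s %s%d: missing atom %s",
                                          res$resname, res$chain, res$resseq,
                                          name), call = NULL)))
  }
  c(res$atom$x[i], res$atom$y[i], res$atom$z[i])
}

# Documented atom-name aliases: "O-eta" (Tyr hydroxyl) is PDB "OH".
.resolve_atom_alias <- function(name) {
  switch(name, "Oeta" = "OH", "OETA" = "OH", name)
}

# ---- PDB I/O (bio3d behind the surface) --------------------------------

#' Read a PDB file into a structure
#'
#' Parsing is delegated to [bio3d::read.pdb()].  Alternate locations are
#' resolved to a single conformer by highest occupancy (ties keep altloc
#' "A"); hydrogens are kept but flagged.
#'
#' @param path PDB file.
#' @param keep_hetatm retain HETATM records (default FALSE: protein only).
#' @return a `gpcr_structure`.
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path))
    stop("gpcr_io_error: file not found: ", path, call. = FALSE)
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      stop("gpcr_format_error: unparseable PDB file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  keep <- .keep_rows(p$atom, keep_hetatm)
  if (!length(keep))
    stop("gpcr_empty_input_error: no ATOM records in ", path, call. = FALSE)
  .structure_from_bio3d(p$atom[keep, ],
                        id = tools::file_path_sans_ext(basename(path)))
}

.structure_from_bio3d <- function(a, id) {
  atom <- data.frame(chain = a$chain, resseq = a$resno,
                     icode = ifelse(is.na(a$insert), "", a$insert),
                     resname = a$resid, elety = a$elety,
                     elesy = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                                    NA_character_, a$elesy),
                     x = a$x, y = a$y, z = a$z,
                     stringsAsFactors = FALSE)
  gpcr_structure(atom, id = id)
}

# Row indices to keep after record-type filtering and altloc resolution.
# Altloc policy: keep highest occupancy; ties keep altloc "A" (or the
# alphabetically first present).  Deterministic single-conformer geometry.
.keep_rows <- function(a, keep_hetatm = FALSE) {
  rows <- seq_len(nrow(a))
  if (!keep_hetatm) rows <- rows[a$type[rows] == "ATOM"]
  if (!length(rows)) return(integer(0))
  alt <- ifelse(is.na(a$alt[rows]), "", a$alt[rows])
  if (all(alt == "")) return(rows)
  occ <- ifelse(is.na(a$o[rows]), 1, a$o[rows])
  key <- paste(a$chain[rows], a$resno[rows],
               ifelse(is.na(a$insert[rows]), "", a$insert[rows]), a$elety[rows])
  keep <- unlist(lapply(split(seq_along(rows), key), function(idx) {
    if (length(idx) == 1) return(idx)
    o <- occ[idx]
    best <- idx[o == max(o)]
    if (length(best) > 1) best <- best[order(alt[best])][1]
    best[1]
  }), use.names = FALSE)
  rows[sort(keep)]
}

#' Write a structure to a PDB file
#'
#' Round-trips with [read_pdb()] to the PDB 3-decimal coordinate grid.
#'
#' @param s a `gpcr_structure`.
#' @param path output file.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "gpcr_structure"))
  if (nrow(s$atom) == 0)
    stop("gpcr_empty_input_error: refusing to write an empty structure",
         call. = FALSE)
  xyz <- coords(s)
  if (any(abs(xyz) > 9999.999))
    stop("gpcr_value_error: coordinate out of PDB fixed-width range",
         call. = FALSE)
  a <- s$atom
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = a$resseq, chain = a$chain, resid = a$resname,
                   elety = a$elety, insert = ifelse(nzchar(a$icode), a$icode, ""),
                   elesy = a$elesy, o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read a frame series (multi-model PDB or a list of PDB files)
#'
#' All models must share atom count and order.  Frame times are assigned
#' as model index times `frame_interval` (default 1 ns, the analysis
#' snapshot spacing).
#'
#' @param paths one multi-model PDB file, or a character vector of
#'   single-model files in frame order.
#' @param frame_interval time between frames, ns.
#' @return object of class `gpcr_frames`: list with `topology`
#'   (a `gpcr_structure` for frame 1), `xyz` (frames x 3N matrix) and
#'   `times` (ns, strictly increasing).
#' @export
read_frames <- function(paths, frame_interval = 1) {
  stopifnot(length(paths) >= 1, frame_interval > 0)
  if (length(paths) == 1) {
    p <- tryCatch(
      suppressWarnings(bio3d::read.pdb(paths, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e)
        stop("gpcr_topology_error: could not read frames from '", paths, "': ",
             conditionMessage(e), call. = FALSE))
    keep <- .keep_rows(p$atom)
    if (!length(keep))
      stop("gpcr_empty_input_error: no ATOM records in ", paths, call. = FALSE)
    topo <- .structure_from_bio3d(p$atom[keep, ],
                                  id = tools::file_path_sans_ext(basename(paths)))
    xyz <- p$xyz[, bio3d::atom2xyz(keep), drop = FALSE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    frames <- lapply(paths, read_pdb)
    n <- vapply(frames, function(f) nrow(f$atom), integer(1))
    if (length(unique(n)) != 1)
      stop("gpcr_topology_error: inconsistent atom counts across frames: ",
           paste(unique(n), collapse = ", "), call. = FALSE)
    topo <- frames[[1]]
    xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(coords(f)))))
  }
  frame_series(topo, xyz, times = seq_len(nrow(xyz)) * frame_interval)
}

#' Construct a frame series from a topology and coordinate rows
#'
#' @param topology `gpcr_structure` giving atom identities.
#' @param xyz frames x 3N coordinate matrix (bio3d xyz layout).
#' @param times frame times in ns, strictly increasing.
#' @return a `gpcr_frames` object.
#' @export
frame_series <- function(topology, xyz, times) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, nrow = 1) else as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(topology$atom))
    stop("gpcr_topology_error: frame width != 3 x atom count", call. = FALSE)
  if (length(times) != nrow(xyz))
    stop("gpcr_value_error: times length != frame count", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("gpcr_value_error: times must be strictly increasing", call. = FALSE)
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "gpcr_frames")
}

#' Number of frames in a series
#' @param fs a `gpcr_frames`.
#' @return integer.
#' @export
n_frames <- function(fs) nrow(fs$xyz)

#' Materialize one frame of a series as a structure
#' @param fs a `gpcr_frames`.
#' @param i frame index.
#' @return a `gpcr_structure`.
#' @export
frame_structure <- function(fs, i) {
  stopifnot(i >= 1, i <= n_frames(fs))
  s <- set_coords(fs$topology, matrix(fs$xyz[i, ], ncol = 3, byrow = TRUE))
  s$id <- sprintf("%s/frame%d", fs$topology$id, i)
  s
}

#' Write a frame series as a multi-model PDB
#' @param fs a `gpcr_frames`.
#' @param path output file.
#' @export
write_frames <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_len(n_frames(fs))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    write_pdb(frame_structure(fs, i), tmp)
    lines <- readLines(tmp)
    writeLines(lines[grepl("^(ATOM|HETATM|TER)", lines)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.gpcr_frames <- function(x, ...) {
  cat(sprintf("gpcr_frames: %d frames x %d atoms, t = %g..%g ns\n",
              n_frames(x), nrow(x$topology$atom),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# ---- generic numbering and TM segments ---------------------------------

#' Construct a generic-numbering (Ballesteros-Weinstein) map
#'
#' Maps labels such as "3.36", "6.48", "N-term", "ECL2" to (chain, resseq).
#'
#' @param label character vector of labels.
#' @param chain chain ids.
#' @param resseq residue numbers.
#' @return object of class `bw_map` (data frame).
#' @export
bw_map <- function(label, chain, resseq) {
  if (anyDuplicated(label))
    stop("gpcr_value_error: duplicate generic-number labels", call. = FALSE)
  structure(data.frame(label = as.character(label), chain = as.character(chain),
                       resseq = as.integer(resseq), stringsAsFactors = FALSE),
            class = c("bw_map", "data.frame"))
}

#' Read a generic-number map from TSV (columns: label, chain, resseq)
#' @param path TSV file with header.
#' @return a `bw_map`.
#' @export
read_bw_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "chain", "resseq")
  if (!all(need %in% names(d)))
    stop("gpcr_format_error: map TSV needs columns label, chain, resseq",
         call. = FALSE)
  bw_map(d$label, d$chain, d$resseq)
}

#' Resolve a generic-number label to a residue of a structure
#'
#' @param s a `gpcr_structure`.
#' @param map a `bw_map`.
#' @param label e.g. "3.36".
#' @return a `gpcr_residue`.
#' @export
resolve_label <- function(s, map, label) {
  i <- match(label, map$label)
  if (is.na(i))
    stop(structure(class = c("gpcr_lookup_error", "error", "condition"),
                   list(message = sprintf("label '%s' not in generic-number map",
                                          label), call = NULL)))
  tryCatch(get_residue(s, map$chain[i], map$resseq[i]),
           gpcr_lookup_error = function(e)
             stop(structure(class = c("gpcr_lookup_error", "error", "condition"),
                            list(message = sprintf(
                              "label '%s' maps to %s%d, absent from '%s'",
                              label, map$chain[i], map$resseq[i], s$id),
                              call = NULL))))
}

#' Construct a TM-segment table
#'
#' @param segment "TM1".."TM7" labels.
#' @param chain chain ids.
#' @param start,end inclusive residue-number ranges.
#' @return object of class `tm_segments` (data frame, 7 rows).
#' @export
tm_segments <- function(segment, chain, start, end) {
  d <- data.frame(segment = as.character(segment), chain = as.character(chain),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  if (nrow(d) != 7 || !setequal(d$segment, paste0("TM", 1:7)))
    stop("gpcr_value_error: TM segment table must contain exactly TM1..TM7",
         call. = FALSE)
  if (any(d$end - d$start + 1 < 4))
    stop("gpcr_value_error: each TM segment needs >= 4 residues", call. = FALSE)
  d <- d[order(d$segment), ]
  for (ch in unique(d$chain)) {
    dd <- d[d$chain == ch, ]
    dd <- dd[order(dd$start), ]
    if (any(dd$start[-1] <= dd$end[-nrow(dd)]))
      stop("gpcr_value_error: TM segment ranges overlap", call. = FALSE)
  }
  rownames(d) <- d$segment
  structure(d, class = c("tm_segments", "data.frame"))
}

#' Read a TM-segment table from TSV (columns: segment, chain, start, end)
#' @param path TSV file with header.
#' @return a `tm_segments`.
#' @export
read_tm_segments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("segment", "chain", "start", "end")
  if (!all(need %in% names(d)))
    stop("gpcr_format_error: segment TSV needs columns segment, chain, start, end",
         call. = FALSE)
  tm_segments(d$segment, d$chain, d$start, d$end)
}

# Paired CA coordinate matrices for residues of `rng` (c(start, end)) on
# `chain`, present in both structures.  strict -> error listing missing.
pair_ca <- function(a, b, rng, chain, strict = TRUE, what = "selection") {
  res <- seq.int(rng[1], rng[2])
  get_ca <- function(s) {
    at <- s$atom
    sel <- at$chain == chain & at$elety == "CA" & at$resseq %in% res &
      at$icode == ""
    at <- at[sel, ]
    at[match(res, at$resseq), c("x", "y", "z")]
  }
  ca_a <- get_ca(a); ca_b <- get_ca(b)
  ok <- stats::complete.cases(ca_a) & stats::complete.cases(ca_b)
  if (strict && !all(ok)) {
    miss <- res[!ok]
    stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                   list(message = sprintf(
                     "%s: unpaired residues on chain %s: %s", what, chain,
                     paste(miss, collapse = ",")), call = NULL)))
  }
  if (sum(ok) < 3)
    stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                   list(message = sprintf("%s: fewer than 3 paired CA atoms", what),
                        call = NULL)))
  if (!all(ok) && !strict)
    warning(sprintf("%s: dropping %d unpaired residues at segment edges",
                    what, sum(!ok)), call. = FALSE)
  list(a = as.matrix(ca_a[ok, ]), b = as.matrix(ca_b[ok, ]), resseq = res[ok])
}

#' Minimized CA RMSD between two structures over residue ranges
#'
#' Superposes `b` onto `a` using the named atoms of the selected residue
#' ranges (Kabsch) and returns the minimized RMSD.
#'
#' @param a,b `gpcr_structure` objects.
#' @param ranges list of `c(start, end)` residue-number ranges.
#' @param chain chain id (default "A").
#' @param atom atom name used for pairing (default "CA").
#' @return RMSD in Angstrom.
#' @export
rmsd_after_superposition <- function(a, b, ranges, chain = "A", atom = "CA") {
  sel_xyz <- function(s) {
    at <- s$atom
    keep <- at$chain == chain & at$elety == atom & at$icode == "" &
      Reduce(`|`, lapply(ranges, function(r) at$resseq >= r[1] & at$resseq <= r[2]))
    at[keep, c("resseq", "x", "y", "z")]
  }
  xa <- sel_xyz(a); xb <- sel_xyz(b)
  common <- intersect(xa$resseq, xb$resseq)
  only_a <- setdiff(xa$resseq, common); only_b <- setdiff(xb$resseq, common)
  if (length(only_a) || length(only_b))
    stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                   list(message = sprintf(
                     "unmatched residues in selection (a-only: %s; b-only: %s)",
                     paste(only_a, collapse = ","), paste(only_b, collapse = ",")),
                     call = NULL)))
  ma <- as.matrix(xa[match(common, xa$resseq), c("x", "y", "z")])
  mb <- as.matrix(xb[match(common, xb$resseq), c("x", "y", "z")])
  superpose(mb, ma)$rmsd
}
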