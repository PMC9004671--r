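# 7x7 per-helix RMSD matrices.
#
# Two structures are compared by superposing one onto the other using the
# CA atoms of a single TM helix (the alignment helix, one matrix row) and
# then measuring the CA RMSD of each of the seven helices under that one
# transform (the measured helix, one matrix column; no per-column refit).
# Aligning on a helix minimizes its own RMSD, so each diagonal entry is
# the column minimum.

#' 7x7 per-helix RMSD matrix between two structures
#'
#' @param a,b `gpcr_structure`s (reference and comparison structure).
#' @param segs a [tm_segments()] table.  CA pairing is by residue number
#'   within each segment range; residues unresolved in either structure
#'   are dropped symmetrically with a warning.
#' @return object of class `rmsd_matrix`: 7x7 numeric matrix (Angstrom),
#'   rows = alignment helix, columns = measured helix, TM1..TM7 labels.
#' @export
rmsd_matrix_7x7 <- function(a, b, segs) {
  stopifnot(inherits(segs, "tm_segments"))
  helices <- paste0("TM", 1:7)
  pairs <- lapply(helices, function(h) {
    seg <- segs[h, ]
    pr <- tryCatch(
      pair_ca(a, b, c(seg$start, seg$end), seg$chain, strict = FALSE,
              what = h),
      gpcr_pairing_error = function(e)
        stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                       list(message = paste0("helix ", h, ": ",
                                             conditionMessage(e)),
                            call = NULL))))
    if (nrow(pr$a) < 4)
      stop(structure(class = c("gpcr_pairing_error", "error", "condition"),
                     list(message = sprintf("helix %s pairs fewer than 4 CA atoms", h),
                          call = NULL)))
    pr
  })
  names(pairs) <- helices
  m <- matrix(NA_real_, 7, 7, dimnames = list(align = helices,
                                              measure = helices))
  for (r in helices) {
    xf <- superpose(pairs[[r]]$b, pairs[[r]]$a)
    for (j in helices) {
      moved <- apply_transform(xf, pairs[[j]]$b)
      m[r, j] <- .rms(moved, pairs[[j]]$a)
    }
  }
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' Count helix pairs exceeding a movement threshold
#'
#' Summarizes the inter-helical movement pattern of a matrix: receptors
#' like CB1, whose activation moves most helices relative to each other,
#' show many off-diagonal entries above threshold, while receptors whose
#' movement is confined to one helix show few.
#'
#' @param m an `rmsd_matrix`.
#' @param threshold Angstrom.
#' @return list with `count` and `pairs` (data frame: align, measure,
#'   rmsd of the off-diagonal entries above threshold).
#' @export
movement_profile <- function(m, threshold) {
  stopifnot(inherits(m, "rmsd_matrix"))
  idx <- which(m > threshold & row(m) != col(m), arr.ind = TRUE)
  pairs <- data.frame(align = rownames(m)[idx[, 1]],
                      measure = colnames(m)[idx[, 2]],
                      rmsd = m[idx], stringsAsFactors = FALSE)
  list(count = nrow(pairs), pairs = pairs)
}

#' Write an RMSD matrix as TSV (2-decimal Angstrom entries)
#' @param m an `rmsd_matrix`.
#' @param path output file.
#' @export
write_rmsd_matrix <- function(m, path) {
  d <- as.data.frame(round(unclass(m), 2))
  d <- cbind(align = rownames(m), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
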