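# P-I-F connector motif scan.
#
# The proline 5.50 / isoleucine 3.40 / phenylalanine 6.44 microswitch is
# conserved in only part of the class A family; CB1 carries L5.50, V3.40,
# L6.44 (none conserved).  Input is a table of residues observed at the
# three generic positions; fetching those from a database is out of scope.

#' Call P-I-F motif conservation for one receptor
#'
#' @param residues named character: one-letter codes at positions
#'   `"5.50"`, `"3.40"`, `"6.44"` (gap `"-"` allowed, never matches).
#'   Case-insensitive.
#' @param receptor receptor identifier.
#' @return list of class `motif_call`: receptor, res5x50, res3x40,
#'   res6x44, conserved_count (0-3).
#' @export
pif_call <- function(residues, receptor = "receptor") {
  need <- c("5.50", "3.40", "6.44")
  if (!all(need %in% names(residues)) ||
      any(is.na(residues[need])) || any(!nzchar(residues[need])))
    stop("gpcr_value_error: residues at 5.50, 3.40 and 6.44 are all required",
         call. = FALSE)
  obs <- toupper(unname(unlist(residues[need])))
  count <- sum(obs == c("P", "I", "F"))
  structure(list(receptor = receptor, res5x50 = obs[1], res3x40 = obs[2],
                 res6x44 = obs[3], conserved_count = count),
            class = "motif_call")
}

#' Histogram of P-I-F conservation counts
#'
#' @param calls list of `motif_call` objects.
#' @return named integer vector over counts `"0".."3"`, summing to the
#'   number of calls.
#' @export
pif_census <- function(calls) {
  counts <- vapply(calls, `[[`, numeric(1), "conserved_count")
  table(factor(counts, levels = 0:3))
}

#' Read a motif table and call every receptor
#'
#' @param path TSV with header columns receptor, res5x50, res3x40, res6x44.
#' @return list of `motif_call` objects.
#' @export
read_pif_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("receptor", "res5x50", "res3x40", "res6x44")
  if (!all(need %in% names(d)))
    stop("gpcr_format_error: motif TSV needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    pif_call(c("5.50" = d$res5x50[i], "3.40" = d$res3x40[i],
               "6.44" = d$res6x44[i]), receptor = d$receptor[i]))
}
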