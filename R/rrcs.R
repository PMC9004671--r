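# Residue-residue contact score (RRCS).
#
# A distance-based piecewise-linear measure of contact strength summed
# over heavy-atom pairs: a pair closer than d_full contributes 1, a pair
# beyond d_zero contributes 0, and the score falls linearly in between.
# Backbone atoms of sequence-near residue pairs are excluded so the score
# reflects side-chain packing, following the published parameterization
# (d_full 3.23 A, d_zero 4.63 A, separation cutoff 4, backbone N/CA/C/O).

#' RRCS parameters
#'
#' @param d_full distance at and below which an atom pair scores 1, Angstrom.
#' @param d_zero distance at and above which an atom pair scores 0, Angstrom.
#' @param near_seq_sep sequence-separation cutoff (same chain) at or below
#'   which backbone atoms are excluded from scoring.
#' @param excluded_backbone_atoms atom names excluded for near-sequence pairs.
#' @return list of class `rrcs_params`.
#' @export
rrcs_params <- function(d_full = 3.23, d_zero = 4.63, near_seq_sep = 4,
                        excluded_backbone_atoms = c("N", "CA", "C", "O")) {
  if (!(d_full > 0 && d_zero > d_full))
    stop("gpcr_value_error: need 0 < d_full < d_zero", call. = FALSE)
  if (near_seq_sep < 0)
    stop("gpcr_value_error: near_seq_sep must be >= 0", call. = FALSE)
  structure(list(d_full = d_full, d_zero = d_zero,
                 near_seq_sep = near_seq_sep,
                 excluded_backbone_atoms = excluded_backbone_atoms),
            class = "rrcs_params")
}

#' Contact score of one residue pair
#'
#' @param s a `gpcr_structure`.
#' @param res_a,res_b `gpcr_residue`s (distinct).
#' @param params an [rrcs_params()].
#' @return nonnegative score; symmetric in the residue order.
#' @export
rrcs_pair <- function(s, res_a, res_b, params = rrcs_params()) {
  if (res_a$chain == res_b$chain && res_a$resseq == res_b$resseq &&
      res_a$icode == res_b$icode)
    stop("gpcr_value_error: RRCS of a residue with itself", call. = FALSE)
  aa <- res_a$atom[!res_a$atom$hydrogen, ]
  ab <- res_b$atom[!res_b$atom$hydrogen, ]
  near <- res_a$chain == res_b$chain &&
    abs(res_a$resseq - res_b$resseq) <= params$near_seq_sep
  if (near) {
    aa <- aa[!aa$elety %in% params$excluded_backbone_atoms, ]
    ab <- ab[!ab$elety %in% params$excluded_backbone_atoms, ]
  }
  if (!nrow(aa) || !nrow(ab)) return(0)
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  sc <- (params$d_zero - d) / (params$d_zero - params$d_full)
  sum(pmin(1, pmax(0, sc)))
}

#' |delta RRCS| of a labeled residue pair between two activation states
#'
#' The absolute difference of the pair's contact score in the inactive
#' and active structures; large when the pair's interaction changes upon
#' activation (the twin-toggle signature at 3.36/6.48).
#'
#' @param inactive,active `gpcr_structure`s.
#' @param map a [bw_map()] (or list of two maps, inactive and active).
#' @param pair_labels generic-number labels of the pair (default the
#'   toggle pair 3.36 / 6.48).
#' @param params an [rrcs_params()].
#' @return list with `rrcs_inactive`, `rrcs_active`, `value` (= |delta|).
#' @export
delta_rrcs <- function(inactive, active, map,
                       pair_labels = c("3.36", "6.48"),
                       params = rrcs_params()) {
  maps <- if (inherits(map, "bw_map")) list(map, map) else map
  score <- function(s, m) {
    rrcs_pair(s, resolve_label(s, m, pair_labels[1]),
              resolve_label(s, m, pair_labels[2]), params)
  }
  ri <- score(inactive, maps[[1]])
  ra <- score(active, maps[[2]])
  list(rrcs_inactive = ri, rrcs_active = ra, value = abs(ri - ra))
}

#' Rank receptors by |delta RRCS| of a residue pair
#'
#' @param entries list of `list(id, inactive, active, map)` entries.
#' @param pair_labels pair of generic-number labels.
#' @param params an [rrcs_params()].
#' @return data frame ordered by descending `abs_delta` (ties broken by
#'   receptor id, lexicographic): receptor, rrcs_inactive, rrcs_active,
#'   abs_delta, rank.
#' @export
rank_receptors <- function(entries, pair_labels = c("3.36", "6.48"),
                           params = rrcs_params()) {
  if (!length(entries))
    stop("gpcr_value_error: no receptors to rank", call. = FALSE)
  rows <- lapply(entries, function(e) {
    d <- delta_rrcs(e$inactive, e$active, e$map, pair_labels, params)
    data.frame(receptor = e$id, rrcs_inactive = d$rrcs_inactive,
               rrcs_active = d$rrcs_active, abs_delta = d$value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abs_delta, out$receptor), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
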