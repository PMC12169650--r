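# Protein-DNA contact statistics: generic heavy-atom contact counting, the
# two specific contact coordinates used for minor-groove binders (QGR motif
# vs minor-groove acceptors, Trp NE1 vs deoxyribose), bound-state
# classification and 2D contact densities.

# resolve an atom selection on an atom table. sel is a list with optional
# fields: chain, resno (vector), elety (vector), resid (vector).
resolve_selection <- function(atoms, sel, name = "selection") {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
  if (!is.null(sel$resid)) keep <- keep & atoms$resid %in% sel$resid
  if (!is.null(sel$elety)) keep <- keep & atoms$elety %in% sel$elety
  keep <- keep & !grepl("^H", atoms$elety)  # heavy atoms only
  if (!any(keep)) stop("empty atom selection: ", name)
  which(keep)
}

#' Count heavy-atom contacts between two selections
#'
#' Number of (a, b) atom pairs with distance strictly below the cutoff.
#' Symmetric in the two selections.
#'
#' @param structure A `duplex_structure` (possibly with protein chains).
#' @param group_a,group_b Selections: lists with any of `chain`, `resno`,
#'   `resid`, `elety`.
#' @param cutoff Distance cutoff in Angstrom (default 4.5, strict `<`).
#' @return Integer contact count.
#' @export
count_contacts <- function(structure, group_a, group_b, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  at <- structure$atoms
  ia <- resolve_selection(at, group_a, "group_a")
  ib <- resolve_selection(at, group_b, "group_b")
  xa <- as.matrix(at[ia, c("x", "y", "z")])
  xb <- as.matrix(at[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sum(d2 < cutoff^2)
}

# minor-groove acceptor selection of the DNA (purine N3, pyrimidine O2,
# sugar O4') as row indices
minor_acceptor_indices <- function(atoms) {
  dna <- atoms$resid %in% c("DA", "DT", "DG", "DC")
  pur <- atoms$resid %in% c("DA", "DG")
  which(dna & ((pur & atoms$elety == "N3") |
                 (!pur & atoms$elety == "O2") |
                 atoms$elety == "O4'"))
}

#' QGR-motif / minor-groove contact count
#'
#' Counts heavy-atom contacts between all atoms of protein residues
#' 112-114 (the Gln-Gly-Arg minor-groove binding motif) and the DNA
#' minor-groove acceptor atoms (purine N3, pyrimidine O2, sugar O4').
#'
#' @param structure A protein-DNA `duplex_structure`.
#' @param protein_chain Protein chain id (default `"P"`).
#' @param qgr_resno Residue numbers of the motif (default 112:114).
#' @param cutoff Contact cutoff, Angstrom (default 4.5).
#' @return Integer count (`C_minor-QGR`).
#' @export
qgr_minor_contacts <- function(structure, protein_chain = "P",
                               qgr_resno = 112:114, cutoff = 4.5) {
  at <- structure$atoms
  if (!any(at$chain == protein_chain & at$resno %in% qgr_resno))
    stop("missing QGR residues ", paste(qgr_resno, collapse = ","),
         " on chain ", protein_chain)
  acc <- minor_acceptor_indices(at)
  if (length(acc) == 0) stop("no minor-groove acceptor atoms found")
  count_contacts(structure,
                 group_a = list(chain = protein_chain, resno = qgr_resno),
                 group_b = list(elety = unique(at$elety[acc]),
                                resid = c("DA", "DT", "DG", "DC")),
                 cutoff = cutoff)
}

#' Trp NE1 / deoxyribose contact count
#'
#' Counts contacts between the NE1 atom of the tryptophan residue (default
#' 109) and the sugar atoms C1'-C5', O4' of all nucleotides.
#'
#' @inheritParams qgr_minor_contacts
#' @param trp_resno Tryptophan residue number (default 109).
#' @return Integer count (`C_sugar-Trp`).
#' @export
trp_sugar_contacts <- function(structure, protein_chain = "P",
                               trp_resno = 109, cutoff = 4.5) {
  at <- structure$atoms
  if (!any(at$chain == protein_chain & at$resno == trp_resno &
             at$elety == "NE1"))
    stop("missing NE1 atom of residue ", trp_resno, " on chain ",
         protein_chain)
  count_contacts(structure,
                 group_a = list(chain = protein_chain, resno = trp_resno,
                                elety = "NE1"),
                 group_b = list(resid = c("DA", "DT", "DG", "DC"),
                                elety = sugar_atom_names),
                 cutoff = cutoff)
}

#' Bound-state classification from the two contact coordinates
#'
#' A frame counts as minor-groove bound when the QGR contact count exceeds
#' 25 and the Trp-sugar count is at least 2.
#'
#' @param c_minor_qgr,c_sugar_trp Integer contact counts (vectorized).
#' @param qgr_threshold QGR count must be strictly greater (default 25).
#' @param trp_min Minimum Trp-sugar contacts (default 2).
#' @return Logical vector.
#' @export
is_bound_state <- function(c_minor_qgr, c_sugar_trp,
                           qgr_threshold = 25, trp_min = 2) {
  c_minor_qgr > qgr_threshold & c_sugar_trp >= trp_min
}

#' Per-frame contact series over an ensemble
#'
#' @param ensemble A `dna_ensemble` whose topology includes the protein
#'   probe chain.
#' @param ... Passed to [qgr_minor_contacts()] / [trp_sugar_contacts()].
#' @return data.frame: `frame`, `time_ns`, `c_minor_qgr`, `c_sugar_trp`,
#'   `bound`.
#' @export
contact_series <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "dna_ensemble"))
  nf <- n_frames(ensemble)
  qgr <- integer(nf)
  trp <- integer(nf)
  for (m in seq_len(nf)) {
    fr <- ensemble_frame(ensemble, m)
    qgr[m] <- qgr_minor_contacts(fr, ...)
    trp[m] <- trp_sugar_contacts(fr, ...)
  }
  data.frame(frame = seq_len(nf), time_ns = ensemble$times,
             c_minor_qgr = qgr, c_sugar_trp = trp,
             bound = is_bound_state(qgr, trp))
}

#' 2D contact probability density
#'
#' Normalized joint histogram of the two contact coordinates over integer
#' bins; probabilities sum to one exactly.
#'
#' @param series data.frame from [contact_series()] (or any data.frame with
#'   `c_minor_qgr`, `c_sugar_trp`), or a `dna_ensemble`.
#' @return `list(qgr_bins, trp_bins, density)`; `density` is a matrix with
#'   rows indexed by the QGR count and columns by the Trp-sugar count.
#' @export
contact_density_2d <- function(series) {
  if (inherits(series, "dna_ensemble")) series <- contact_series(series)
  if (nrow(series) == 0) stop("empty contact series")
  qv <- series$c_minor_qgr
  tv <- series$c_sugar_trp
  qb <- min(qv):max(qv)
  tb <- min(tv):max(tv)
  dens <- table(factor(qv, levels = qb), factor(tv, levels = tb))
  dens <- unclass(dens) / nrow(series)
  list(qgr_bins = qb, trp_bins = tb, density = dens)
}
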