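# Backbone/sugar conformation descriptors and per-position fraction
# profiles over ensembles: the A-like vs B-like classification surface
# (North/South pucker, anti/high-anti glycosidic torsion).

#' Glycosidic torsion angle chi
#'
#' chi = O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines, with the
#' usual dihedral sign convention; degrees in (-180, 180].
#'
#' @param residue Coordinate matrix with rownames, or a `duplex_structure`
#'   with `chain`/`resno`.
#' @param base Base type; inferred when `residue` is a structure.
#' @param chain,resno Residue address when `residue` is a structure.
#' @return chi in degrees.
#' @export
chi_angle <- function(residue, base = NULL, chain = NULL, resno = NULL) {
  if (inherits(residue, "duplex_structure")) {
    stopifnot(!is.null(chain), !is.null(resno))
    sub <- residue$atoms[residue$atoms$chain == chain &
                           residue$atoms$resno == resno, ]
    base <- resid_to_base(sub$resid[1])
    residue <- residue_xyz(residue, chain, resno)
  }
  stopifnot(!is.null(base))
  gly <- glycosidic_atoms(base)
  need <- c("O4'", "C1'", gly["n"], gly["ref"])
  missing <- setdiff(need, rownames(residue))
  if (length(missing) > 0)
    stop("chi_angle: missing atom(s): ", paste(missing, collapse = ", "))
  dihedral(residue["O4'", ], residue["C1'", ],
           residue[gly[["n"]], ], residue[gly[["ref"]], ])
}

#' Classify the glycosidic torsion
#'
#' Half-open decision intervals (configurable): anti for chi in
#' `[-180, -120)`, high-anti for `[-120, -60)`, syn for `[0, 90)`, other
#' otherwise. The defaults place canonical A-DNA (chi ~ -160) in anti and
#' canonical B-DNA (chi ~ -100) in high-anti.
#'
#' @param chi Glycosidic torsion, degrees in (-180, 180].
#' @param boundaries Named list overriding the class boundaries
#'   (`anti`, `high_anti`, `syn`, each `c(lo, hi)` with lo inclusive).
#' @return Character vector of class labels.
#' @export
classify_chi <- function(chi, boundaries = NULL) {
  b <- list(anti = c(-180, -120), high_anti = c(-120, -60), syn = c(0, 90))
  if (!is.null(boundaries)) b[names(boundaries)] <- boundaries
  out <- rep("other", length(chi))
  out[chi >= b$anti[1] & chi < b$anti[2]] <- "anti"
  out[chi >= b$high_anti[1] & chi < b$high_anti[2]] <- "high-anti"
  out[chi >= b$syn[1] & chi < b$syn[2]] <- "syn"
  out
}

#' Per-position North/anti fraction profiles over an ensemble
#'
#' For each base-pair position, the fraction of frames classified North
#' (sugar pseudorotation) and anti (glycosidic torsion). By default the two
#' paired residues are pooled, giving one value per base pair; set
#' `pool_strands = FALSE` for per-strand profiles.
#'
#' @param ensemble A `dna_ensemble`.
#' @param pool_strands Pool Watson and Crick residues of a pair (default
#'   `TRUE`).
#' @param chi_boundaries Passed to [classify_chi()].
#' @return data.frame: `position`, (`strand`,) `fraction_north`,
#'   `fraction_anti`, `n_frames`.
#' @export
fraction_profiles <- function(ensemble, pool_strands = TRUE,
                              chi_boundaries = NULL) {
  stopifnot(inherits(ensemble, "dna_ensemble"))
  nf <- n_frames(ensemble)
  if (nf == 0) stop("empty ensemble")
  topo <- ensemble$topology
  pairs <- topo$pairs
  if (is.null(pairs)) stop("ensemble topology has no pairing")
  chains <- topo$strand_chains
  L <- nrow(pairs)
  north <- array(0L, c(L, 2))  # counts, cols = watson, crick
  anti <- array(0L, c(L, 2))
  for (m in seq_len(nf)) {
    fr <- ensemble_frame(ensemble, m)
    for (i in seq_len(L)) {
      for (s in 1:2) {
        rn <- pairs[i, s]
        res <- residue_xyz(fr, chains[s], rn)
        P <- pseudorotation(res)["P"]
        base <- resid_to_base(
          fr$atoms$resid[fr$atoms$chain == chains[s] &
                           fr$atoms$resno == rn][1])
        chi <- chi_angle(res, base = base)
        if (classify_pucker(P) == "North") north[i, s] <- north[i, s] + 1L
        if (classify_chi(chi, chi_boundaries) == "anti")
          anti[i, s] <- anti[i, s] + 1L
      }
    }
  }
  if (pool_strands) {
    data.frame(position = seq_len(L),
               fraction_north = rowSums(north) / (2 * nf),
               fraction_anti = rowSums(anti) / (2 * nf),
               n_frames = nf)
  } else {
    data.frame(position = rep(seq_len(L), 2),
               strand = rep(c("W", "C"), each = L),
               fraction_north = c(north[, 1], north[, 2]) / nf,
               fraction_anti = c(anti[, 1], anti[, 2]) / nf,
               n_frames = nf)
  }
}
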