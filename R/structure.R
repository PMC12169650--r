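# Structure model: atom tables, duplexes, ensembles, PDB I/O and pairing.
#
# Atoms live in a plain data.frame with columns
#   elety (PDB atom name), resid (3-letter-ish residue name, e.g. "DA"),
#   chain (single letter; "A" Watson strand, "B" Crick strand by
#   convention), resno (1-based, 5'->3' within each DNA strand), elesy
#   (element symbol), x, y, z (Angstrom).
# A duplex_structure wraps the atom table with strand/pairing metadata; a
# dna_ensemble shares one topology across frames.

new_duplex_structure <- function(atoms, sequence = NULL, pairs = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "chain", "resno", "x", "y", "z") %in%
                  names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elety))) stop("empty atom name")
  dna <- atoms[atoms$resid %in% c("DA", "DT", "DG", "DC"), ]
  chains <- unique(dna$chain)
  seqs <- lapply(chains, function(ch) {
    sub <- dna[dna$chain == ch, ]
    resid_to_base(sub$resid[match(sort(unique(sub$resno)), sub$resno)])
  })
  names(seqs) <- chains
  obj <- structure(list(atoms = atoms, strand_chains = chains,
                        sequences = seqs, pairs = pairs),
                   class = "duplex_structure")
  if (is.null(pairs) && length(chains) == 2 &&
      length(seqs[[1]]) == length(seqs[[2]])) {
    obj$pairs <- tryCatch(pair_strands(obj), error = function(e) NULL)
  }
  obj
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat("duplex_structure:", nrow(x$atoms), "atoms\n")
  for (ch in x$strand_chains)
    cat(sprintf("  strand %s: 5'-%s-3' (%d nt)\n", ch,
                paste(x$sequences[[ch]], collapse = ""),
                length(x$sequences[[ch]])))
  prot <- setdiff(unique(x$atoms$chain), x$strand_chains)
  if (length(prot) > 0)
    cat("  non-DNA chain(s):", paste(prot, collapse = ", "), "\n")
  invisible(x)
}

#' Number of base pairs of a duplex
#' @param x A `duplex_structure`.
#' @return Integer base-pair count.
#' @export
duplex_length <- function(x) {
  stopifnot(inherits(x, "duplex_structure"))
  length(x$sequences[[x$strand_chains[1]]])
}

#' Coordinates of one residue
#'
#' Returns the coordinate matrix (rownames = atom names) of a residue,
#' optionally restricted to named atoms, erroring on any that are missing.
#'
#' @param structure A `duplex_structure` (or its atom data.frame).
#' @param chain Chain id.
#' @param resno Residue number within the chain.
#' @param atoms Optional atom names to select, in order.
#' @return Numeric matrix, one row per atom.
#' @export
residue_xyz <- function(structure, chain, resno, atoms = NULL) {
  at <- if (inherits(structure, "duplex_structure")) structure$atoms
        else structure
  sub <- at[at$chain == chain & at$resno == resno, ]
  if (nrow(sub) == 0)
    stop(sprintf("no atoms for chain %s residue %d", chain, resno))
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$elety
  if (!is.null(atoms)) {
    missing <- setdiff(atoms, rownames(m))
    if (length(missing) > 0)
      stop(sprintf("chain %s residue %d: missing atom(s) %s",
                   chain, resno, paste(missing, collapse = ", ")))
    m <- m[atoms, , drop = FALSE]
  }
  m
}

# residues lacking the minimum atoms needed for geometry (sugar ring + base
# frame-fitting atoms); returned as a data.frame, never silently dropped.
flag_incomplete_residues <- function(structure) {
  at <- structure$atoms
  dna <- at[at$resid %in% c("DA", "DT", "DG", "DC"), ]
  out <- list()
  for (ch in unique(dna$chain)) {
    for (rn in unique(dna$resno[dna$chain == ch])) {
      sub <- dna[dna$chain == ch & dna$resno == rn, ]
      base <- resid_to_base(sub$resid[1])
      need <- c(sugar_ring_atom_names, base_ring_atoms(base))
      miss <- setdiff(need, sub$elety)
      if (length(miss) > 0)
        out[[length(out) + 1]] <- data.frame(
          chain = ch, resno = rn, base = base,
          missing = paste(miss, collapse = ","))
    }
  }
  if (length(out) == 0)
    data.frame(chain = character(), resno = integer(), base = character(),
               missing = character())
  else do.call(rbind, out)
}

# ---- PDB I/O --------------------------------------------------------------

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records via bio3d. A single-model file yields a
#' `duplex_structure` (protein chains, if any, are retained alongside the
#' DNA); a MODEL/ENDMDL file yields a `dna_ensemble` whose frames share the
#' first model's topology. Residues missing required sugar/base atoms are
#' reported in the `flagged_residues` attribute rather than dropped.
#'
#' @param path Path to a PDB file.
#' @param time_step_ns Frame spacing used to assign ensemble times
#'   (default 1 ns).
#' @return A `duplex_structure` or `dna_ensemble`.
#' @export
read_pdb <- function(path, time_step_ns = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (any(nzchar(a$insert) & !is.na(a$insert)))
    stop("insertion codes are not supported: ", path)
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, ]
  atoms <- data.frame(elety = a$elety, resid = a$resid, chain = a$chain,
                      resno = a$resno,
                      elesy = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                                     substr(gsub("[^A-Za-z].*", "", a$elety),
                                            1, 1), a$elesy),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  # renumber DNA residues 1..L per chain preserving file order
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch & atoms$resid %in% c("DA", "DT", "DG", "DC")
    if (any(sel)) {
      rn <- atoms$resno[sel]
      atoms$resno[sel] <- match(rn, unique(rn))
    }
  }
  nmodel <- nrow(pdb$xyz)
  if (is.null(nmodel) || nmodel <= 1) {
    out <- new_duplex_structure(atoms)
    attr(out, "flagged_residues") <- flag_incomplete_residues(out)
    return(out)
  }
  xyz <- array(NA_real_, c(nrow(atoms), 3, nmodel))
  full <- pdb$xyz[, , drop = FALSE]
  keep3 <- rep(keep, each = 3)
  for (m in seq_len(nmodel))
    xyz[, , m] <- matrix(full[m, keep3], ncol = 3, byrow = TRUE)
  atoms$x <- xyz[, 1, 1]; atoms$y <- xyz[, 2, 1]; atoms$z <- xyz[, 3, 1]
  topo <- new_duplex_structure(atoms)
  attr(topo, "flagged_residues") <- flag_incomplete_residues(topo)
  new_dna_ensemble(topo, xyz, times = seq_len(nmodel) * time_step_ns)
}

#' Write a structure or ensemble to PDB
#'
#' Writes PDB v3.3 ATOM records (via bio3d); ensembles become MODEL/ENDMDL
#' blocks. Coordinates round-trip through [read_pdb()] to 1e-3 A (the PDB
#' fixed-point precision).
#'
#' @param structure A `duplex_structure` or `dna_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "dna_ensemble")) {
    at <- structure$topology$atoms
    nf <- dim(structure$xyz)[3]
    xyz <- t(vapply(seq_len(nf),
                    function(m) as.numeric(t(structure$xyz[, , m])),
                    numeric(nrow(at) * 3)))
  } else if (inherits(structure, "duplex_structure")) {
    at <- structure$atoms
    xyz <- matrix(as.numeric(t(as.matrix(at[, c("x", "y", "z")]))), nrow = 1)
  } else stop("write_pdb: unsupported object of class ",
              paste(class(structure), collapse = "/"))
  if (nrow(at) == 0) stop("write_pdb: empty structure")
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, eleno = seq_len(nrow(at)),
                   elety = at$elety, chain = at$chain, elesy = at$elesy)
  invisible(path)
}

# ---- pairing --------------------------------------------------------------

#' Pair the two strands of a duplex
#'
#' The default `"index"` rule pairs Watson residue i with Crick residue
#' L+1-i and checks Watson-Crick complementarity, erroring with the
#' offending index otherwise. The `"geometric"` rule pairs each Watson
#' residue with the Crick residue whose fitted base-frame origin is nearest
#' (Watson-Crick partners have nearly coincident base-frame origins,
#' whereas cross-strand stacked neighbours are a full rise apart) and then
#' requires the assignment to be a complementary bijection.
#'
#' @param duplex A `duplex_structure` with exactly two DNA strands of equal
#'   length.
#' @param rule `"index"` or `"geometric"`.
#' @return Integer matrix with columns `watson`, `crick` (residue numbers).
#' @export
pair_strands <- function(duplex, rule = c("index", "geometric")) {
  rule <- match.arg(rule)
  stopifnot(inherits(duplex, "duplex_structure"))
  chains <- duplex$strand_chains
  if (length(chains) != 2)
    stop("pairing requires exactly two DNA strands, found ", length(chains))
  sw <- duplex$sequences[[chains[1]]]
  sc <- duplex$sequences[[chains[2]]]
  L <- length(sw)
  if (length(sc) != L) stop("strands differ in length")
  if (rule == "index") {
    crick <- L + 1 - seq_len(L)
  } else {
    ow <- t(vapply(seq_len(L), function(i)
      fit_base_frame(duplex, chain = chains[1], resno = i)$o, numeric(3)))
    oc <- t(vapply(seq_len(L), function(i)
      fit_base_frame(duplex, chain = chains[2], resno = i)$o, numeric(3)))
    crick <- vapply(seq_len(L), function(i) {
      d2 <- rowSums(sweep(oc, 2, ow[i, ])^2)
      which.min(d2)
    }, integer(1))
    if (anyDuplicated(crick))
      stop("geometric pairing is not a bijection")
  }
  for (i in seq_len(L)) {
    if (base_complement[sw[i]] != sc[crick[i]])
      stop(sprintf("non-complementary pair at watson index %d: %s-%s",
                   i, sw[i], sc[crick[i]]))
  }
  cbind(watson = seq_len(L), crick = crick)
}

# ---- ensembles ------------------------------------------------------------

new_dna_ensemble <- function(topology, xyz, times) {
  stopifnot(inherits(topology, "duplex_structure"),
            length(dim(xyz)) == 3, dim(xyz)[2] == 3,
            dim(xyz)[1] == nrow(topology$atoms),
            length(times) == dim(xyz)[3])
  if (any(diff(times) <= 0)) stop("ensemble times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = times),
            class = "dna_ensemble")
}

#' @export
print.dna_ensemble <- function(x, ...) {
  cat("dna_ensemble:", dim(x$xyz)[3], "frames x", dim(x$xyz)[1], "atoms,",
      sprintf("t = %.3g..%.3g ns\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A `dna_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[3]

#' Extract one frame of an ensemble as a structure
#' @param ensemble A `dna_ensemble`.
#' @param i Frame index.
#' @return A `duplex_structure` with that frame's coordinates.
#' @export
ensemble_frame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  at <- ensemble$topology$atoms
  at$x <- ensemble$xyz[, 1, i]
  at$y <- ensemble$xyz[, 2, i]
  at$z <- ensemble$xyz[, 3, i]
  out <- ensemble$topology
  out$atoms <- at
  out
}

#' Stack structures sharing one topology into an ensemble
#'
#' @param structures List of `duplex_structure`s with identical atom tables
#'   (up to coordinates).
#' @param times Frame times in ns (default 1, 2, ...).
#' @return A `dna_ensemble`.
#' @export
ensemble_from_structures <- function(structures,
                                     times = seq_along(structures)) {
  stopifnot(length(structures) >= 1)
  ref <- structures[[1]]
  n <- nrow(ref$atoms)
  xyz <- array(NA_real_, c(n, 3, length(structures)))
  for (m in seq_along(structures)) {
    at <- structures[[m]]$atoms
    if (nrow(at) != n || any(at$elety != ref$atoms$elety))
      stop("structures do not share a topology (frame ", m, ")")
    xyz[, , m] <- as.matrix(at[, c("x", "y", "z")])
  }
  new_dna_ensemble(ref, xyz, times)
}
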