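# Synthetic duplex builder: place standard bases by rigid-base parameters,
# graft deoxyribose rings with requested pucker and glycosidic torsion, and
# bridge consecutive sugars with phosphates. The builder is the exact
# inverse of the frame-fitting extractor for everything expressed through
# base frames, which is what makes build -> extract identity tests possible.

canonical_forms <- list(
  B = list(step = c(tilt = 0, roll = 0, twist = 36.0,
                    shift = 0, slide = 0, rise = 3.38),
           pair = c(buckle = 0, propeller = 0, opening = 0,
                    shear = 0, stretch = 0, stagger = 0),
           sugar = c(P = 162, nu_max = 38, chi = -100)),
  A = list(step = c(tilt = 0, roll = 8.0, twist = 32.7,
                    shift = 0, slide = -1.5, rise = 2.56),
           pair = c(buckle = 0, propeller = 0, opening = 0,
                    shear = 0, stretch = 0, stagger = 0),
           sugar = c(P = 18, nu_max = 38, chi = -160))
)

#' Canonical A-/B-form parameter sets
#'
#' Fixture constants used as builder targets: B-form twist 36 deg, rise
#' 3.38 A, slide 0, roll 0, sugar P 162 deg, chi -100 deg; A-form twist
#' 32.7 deg, rise 2.56 A, slide -1.5 A, roll 8 deg, P 18 deg, chi -160 deg.
#'
#' @param form `"A"` or `"B"`.
#' @return `list(step, pair, sugar)` of named parameter vectors.
#' @export
canonical_form_spec <- function(form = c("B", "A")) {
  canonical_forms[[match.arg(form)]]
}

.template_cache <- new.env(parent = emptyenv())

# rotate rows of m about the axis through `point` along unit vector `axis`
.rotate_about <- function(m, point, axis, angle) {
  R <- rot_axis(axis, angle)
  sweep(sweep(m, 2, point) %*% t(R), 2, point, "+")
}

.ring_normal <- function(ring) {
  ctr <- colMeans(ring)
  n <- c(0, 0, 0)
  idx <- c(seq_len(nrow(ring)), 1)
  for (k in seq_len(nrow(ring)))
    n <- n + cross3(ring[idx[k], ] - ctr, ring[idx[k + 1], ] - ctr)
  unitv(n)
}

# Full heavy-atom template of one nucleotide (no phosphate) in the standard
# base frame: base atoms + sugar ring + C5', O3', O5'. The facial choices
# (base and C5' on one ring face, O3' on the other) reproduce the
# beta-D-deoxyribose arrangement.
residue_template <- function(base, P, nu_max, chi) {
  key <- sprintf("%s_%.3f_%.3f_%.3f", base, P %% 360, nu_max, chi)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  std <- std_base_coords[[base]]
  gly <- glycosidic_atoms(base)
  ring <- build_sugar_ring(P, nu_max)
  nrm <- .ring_normal(ring)
  # glycosidic direction at C1' (remaining tetrahedral slot, base-side face)
  # facial choices (glycosidic slot, C5' and O3' faces) follow the
  # beta-D-deoxyribose arrangement; fixed by requiring a continuous
  # backbone (short O3'(i)..O5'(i+1) bridges) and the B-DNA cross-strand
  # phosphate pattern (narrow minor / wide major groove) on ideal fibers
  dirs <- tetra_directions(ring["C1'", ], ring["O4'", ], ring["C2'", ])
  d_g <- if (sum(dirs[1, ] * nrm) < 0) dirs[1, ] else dirs[2, ]
  c1_t <- std["C1'", ]
  u <- unitv(std[gly["n"], ] - c1_t)
  ax <- cross3(d_g, u)
  R0 <- if (vnorm(ax) < 1e-9) {
    if (sum(d_g * u) > 0) diag(3) else rot_axis(c(u[2], -u[1], 0), pi)
  } else rot_axis(ax, acos(clamp1(sum(d_g * u))))
  ringp <- sweep(sweep(ring, 2, ring["C1'", ]) %*% t(R0), 2, c1_t, "+")
  # set chi = dihedral(O4', C1', N, ref) by rotation about the C1'-N axis
  nref <- std[gly["ref"], ]
  npos <- std[gly["n"], ]
  cur <- dihedral(ringp["O4'", ], ringp["C1'", ], npos, nref)
  for (delta in c(chi - cur, -2 * (chi - cur))) {
    ringp <- .rotate_about(ringp, c1_t, u, deg2rad(delta))
    cur <- dihedral(ringp["O4'", ], ringp["C1'", ], npos, nref)
    if (abs((cur - chi + 180) %% 360 - 180) < 1e-6) break
  }
  nrm2 <- .ring_normal(ringp)
  pick <- function(center, n1, n2, up) {
    d <- tetra_directions(center, n1, n2)
    s <- c(sum(d[1, ] * nrm2), sum(d[2, ] * nrm2))
    if (up) d[which.max(s), ] else d[which.min(s), ]
  }
  c5 <- ringp["C4'", ] + 1.51 * pick(ringp["C4'", ], ringp["C3'", ],
                                     ringp["O4'", ], up = FALSE)
  o3 <- ringp["C3'", ] + 1.42 * pick(ringp["C3'", ], ringp["C2'", ],
                                     ringp["C4'", ], up = TRUE)
  v <- unitv(c5 - ringp["C4'", ])
  axp <- unitv(cross3(v, nrm2))
  o5 <- c5 + 1.44 * as.numeric(rot_axis(axp, deg2rad(109.5)) %*% (-v))
  base_only <- std[setdiff(rownames(std), "C1'"), , drop = FALSE]
  tmpl <- rbind("O5'" = o5, "C5'" = c5,
                ringp[c("C4'", "O4'", "C3'"), ],
                "O3'" = o3,
                ringp[c("C2'", "C1'"), ],
                base_only)
  .template_cache[[key]] <- tmpl
  tmpl
}

.place_template <- function(tmpl, frame) {
  sweep(tmpl %*% t(frame$R), 2, frame$o, "+")
}

.elesy_from_name <- function(elety) substr(gsub("[^A-Za-z].*", "", elety), 1, 1)

.expand_param_matrix <- function(p, nrow_needed, names6, what) {
  if (is.null(p)) p <- rep(0, 6)
  if (is.vector(p) && length(p) == 6) p <- matrix(p, nrow_needed, 6,
                                                  byrow = TRUE)
  p <- as.matrix(p)
  if (nrow(p) != nrow_needed || ncol(p) != 6)
    stop(sprintf("%s: expected %d x 6 parameters, got %d x %d",
                 what, nrow_needed, nrow(p), ncol(p)))
  colnames(p) <- names6
  p
}

#' Build a DNA duplex from rigid-base parameters
#'
#' Places standard-geometry bases by composing base-pair frames from the
#' given step parameters and splitting each pair frame by the pair
#' parameters; deoxyribose rings with the requested pseudorotation phase,
#' amplitude and glycosidic torsion are grafted onto every base and
#' phosphates are placed on the C3'(i)-C5'(i+1) bridge. Because bases are
#' placed exactly by frames, extracting rigid-base parameters from the
#' result reproduces the inputs to numerical precision.
#'
#' @param sequence Watson-strand sequence 5'->3', string or character vector
#'   over A, C, G, T.
#' @param step_params (L-1) x 6 matrix (tilt, roll, twist, shift, slide,
#'   rise) or a length-6 vector recycled to all steps; default canonical
#'   B-form.
#' @param pair_params L x 6 matrix (buckle, propeller, opening, shear,
#'   stretch, stagger) or length-6 vector; default all zero.
#' @param sugar Per-residue sugar spec: either `c(P, nu_max, chi)` recycled
#'   to all 2L residues, or a data.frame with columns `strand` ("W"/"C"),
#'   `resno` (strand 5'->3' index), `P`, `nu_max`, `chi`.
#' @param origin Frame of the first base pair (default identity at the
#'   origin).
#' @return A `duplex_structure`; the generating parameters are attached as
#'   attribute `"build_params"`.
#' @export
build_duplex <- function(sequence, step_params = NULL, pair_params = NULL,
                         sugar = NULL, origin = new_frame()) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (!all(sequence %in% c("A", "C", "G", "T")))
    stop("sequence must be over A, C, G, T")
  L <- length(sequence)
  if (L < 2) stop("need at least 2 base pairs")
  bform <- canonical_forms$B
  if (is.null(step_params)) step_params <- bform$step
  step_params <- .expand_param_matrix(step_params, L - 1, param_names_step,
                                      "step_params")
  pair_params <- .expand_param_matrix(pair_params, L, param_names_pair,
                                      "pair_params")
  if (is.null(sugar)) sugar <- bform$sugar
  if (is.numeric(sugar) && length(sugar) == 3) {
    sugar <- data.frame(strand = rep(c("W", "C"), each = L),
                        resno = rep(seq_len(L), 2),
                        P = unname(sugar[1]), nu_max = unname(sugar[2]),
                        chi = unname(sugar[3]))
  }
  stopifnot(is.data.frame(sugar),
            all(c("strand", "resno", "P", "nu_max", "chi") %in% names(sugar)))
  sugar_of <- function(strand, resno) {
    row <- sugar[sugar$strand == strand & sugar$resno == resno, ]
    if (nrow(row) != 1)
      stop(sprintf("sugar spec missing for strand %s residue %d",
                   strand, resno))
    row
  }
  # chain of pair frames
  pair_frames <- vector("list", L)
  pair_frames[[1]] <- origin
  for (i in seq_len(L - 1)) {
    pair_frames[[i + 1]] <-
      params_to_frames(pair_frames[[i]], step_params[i, 1:3],
                       step_params[i, 4:6])$f2
  }
  res_list <- list()
  for (i in seq_len(L)) {
    sp <- split_mid_frame(pair_frames[[i]], pair_params[i, ])
    fw <- sp$f2                 # Watson base frame
    fc <- flip_frame(sp$f1)     # actual Crick base frame
    bw <- sequence[i]
    bc <- base_complement[bw]
    jw <- i           # Watson strand index
    jc <- L + 1 - i   # Crick strand index (5'->3' on its own strand)
    sgw <- sugar_of("W", jw)
    sgc <- sugar_of("C", jc)
    tw <- residue_template(bw, sgw$P, sgw$nu_max, sgw$chi)
    tc <- residue_template(bc, sgc$P, sgc$nu_max, sgc$chi)
    res_list[[paste0("A", jw)]] <-
      list(chain = "A", resno = jw, base = bw, xyz = .place_template(tw, fw))
    res_list[[paste0("B", jc)]] <-
      list(chain = "B", resno = jc, base = bc, xyz = .place_template(tc, fc))
  }
  # phosphate bridges (strand-wise, residue i >= 2)
  rows <- list()
  for (ch in c("A", "B")) {
    for (j in seq_len(L)) {
      r <- res_list[[paste0(ch, j)]]
      xyz <- r$xyz
      if (j >= 2) {
        prev <- res_list[[paste0(ch, j - 1)]]$xyz
        pxyz <- (prev["O3'", ] + xyz["O5'", ]) / 2
        xyz <- rbind(P = pxyz, xyz)
      }
      rows[[length(rows) + 1]] <- data.frame(
        elety = rownames(xyz), resid = base_to_resid(r$base),
        chain = ch, resno = j, elesy = .elesy_from_name(rownames(xyz)),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  atoms <- do.call(rbind, rows)
  out <- new_duplex_structure(atoms)
  attr(out, "build_params") <- list(sequence = sequence,
                                    step = step_params, pair = pair_params,
                                    sugar = sugar)
  out
}

#' Build an ideal A- or B-form duplex
#'
#' Convenience wrapper around [build_duplex()] with the canonical form
#' parameters of [canonical_form_spec()].
#'
#' @param sequence Watson-strand sequence 5'->3'.
#' @param form `"B"` (default) or `"A"`.
#' @return A `duplex_structure`.
#' @export
build_form_duplex <- function(sequence, form = c("B", "A")) {
  spec <- canonical_form_spec(match.arg(form))
  build_duplex(sequence, step_params = spec$step, pair_params = spec$pair,
               sugar = spec$sugar)
}
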