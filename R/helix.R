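# Helix-level geometry: groove widths, local helical axis, curvature/bend
# magnitude and direction relative to the minor groove.

#' Phosphate-distance groove width
#'
#' Refined cross-strand P-P distance minus the conventional 5.8 A
#' van-der-Waals correction (two phosphate group radii).
#'
#' @param pp_distance Cross-strand P-P distance, Angstrom.
#' @return Groove width, Angstrom.
#' @export
pp_groove_width <- function(pp_distance) pp_distance - 5.8

#' Minor and major groove width profile of a duplex
#'
#' At step i the minor-groove width is the minimum cross-strand distance
#' between the Watson phosphate of pair i+1 and the Crick phosphates of
#' pairs j in the minor offset window (default j in i-2, i-3), minus 5.8 A;
#' the major groove uses j in i+2, i+3. Positions whose phosphates fall
#' outside the molecule are reported as NA, not zero.
#'
#' @param duplex A `duplex_structure`.
#' @param minor_offsets,major_offsets Integer offsets defining the
#'   cross-strand windows.
#' @return data.frame: `position`, `minor_width`, `major_width` (Angstrom).
#' @export
groove_widths <- function(duplex, minor_offsets = c(-2, -3),
                          major_offsets = c(2, 3)) {
  stopifnot(inherits(duplex, "duplex_structure"))
  pairs <- duplex$pairs
  chains <- duplex$strand_chains
  L <- nrow(pairs)
  p_at <- function(chain, resno) {
    sub <- duplex$atoms[duplex$atoms$chain == chain &
                          duplex$atoms$resno == resno &
                          duplex$atoms$elety == "P", ]
    if (nrow(sub) == 0) return(NULL)
    as.numeric(sub[1, c("x", "y", "z")])
  }
  pw <- lapply(seq_len(L), function(i) p_at(chains[1], pairs[i, 1]))
  pc <- lapply(seq_len(L), function(i) p_at(chains[2], pairs[i, 2]))
  width_at <- function(i, offsets) {
    a <- if (i + 1 <= L) pw[[i + 1]] else NULL
    if (is.null(a)) return(NA_real_)
    ds <- c()
    for (off in offsets) {
      j <- i + off
      if (j >= 1 && j <= L && !is.null(pc[[j]]))
        ds <- c(ds, vnorm(a - pc[[j]]))
    }
    if (length(ds) == 0) return(NA_real_)
    pp_groove_width(min(ds))
  }
  data.frame(position = seq_len(L - 1),
             minor_width = vapply(seq_len(L - 1), width_at, numeric(1),
                                  offsets = minor_offsets),
             major_width = vapply(seq_len(L - 1), width_at, numeric(1),
                                  offsets = major_offsets))
}

#' Local helical axis along a duplex
#'
#' The local axis direction at step i is the normalized average of the
#' base-pair frame z-axes over a sliding window of `window` steps
#' (`window + 1` pairs), anchored at the mid-step origin. For an ideal
#' straight fiber all axis vectors are parallel; phased bending (e.g.
#' uniform roll without twist) turns the axis by a constant angle per step.
#'
#' @param duplex A `duplex_structure`, or the result of
#'   [rigid_base_parameters()].
#' @param window Window size in steps (default 3).
#' @return data.frame: `step`, axis components `ax`, `ay`, `az`, and axis
#'   anchor point `px`, `py`, `pz`.
#' @export
helical_axis <- function(duplex, window = 3) {
  rb <- if (inherits(duplex, "duplex_structure"))
    rigid_base_parameters(duplex) else duplex
  pf <- rb$pair_frames
  L <- length(pf)
  if (window + 1 > L)
    stop(sprintf("window of %d steps needs %d pairs, have %d",
                 window, window + 1, L))
  nsteps <- L - 1
  out <- lapply(seq_len(nsteps - window + 1), function(s) {
    idx <- s:(s + window)  # pairs spanned by the window of steps
    zs <- vapply(pf[idx], function(f) f$R[, 3], numeric(3))
    axis <- unitv(rowMeans(zs))
    mid <- (pf[[s]]$o + pf[[min(s + window, L)]]$o) / 2
    c(axis, mid)
  })
  m <- do.call(rbind, out)
  data.frame(step = seq_len(nrow(m)), ax = m[, 1], ay = m[, 2], az = m[, 3],
             px = m[, 4], py = m[, 5], pz = m[, 6])
}

#' Bend magnitude and direction of a duplex
#'
#' `total_bend` is the angle between the local helical axes fitted to the
#' first and last `window` steps. `bend_direction` is the signed angle,
#' about the central pair's z-axis, from the central pair's minor-groove
#' vector (the -y axis of the pair frame) to the projection of the axis
#' change into the central pair plane; 0 means bending straight into the
#' minor groove. Per-step bend magnitudes sqrt(roll^2 + tilt^2) are
#' included. For an ensemble, per-frame descriptors are summarized by mean
#' and SD.
#'
#' @param x A `duplex_structure` or `dna_ensemble`.
#' @param window Axis window in steps (default 3).
#' @return For a structure: `list(total_bend, bend_direction, per_step)`.
#'   For an ensemble: `list(per_frame, total_bend_mean, total_bend_sd)`.
#' @export
bend_descriptor <- function(x, window = 3) {
  if (inherits(x, "dna_ensemble")) {
    vals <- vapply(seq_len(n_frames(x)), function(m)
      bend_descriptor(ensemble_frame(x, m), window)$total_bend, numeric(1))
    return(list(per_frame = vals, total_bend_mean = mean(vals),
                total_bend_sd = stats::sd(vals)))
  }
  rb <- rigid_base_parameters(x)
  ax <- helical_axis(rb, window)
  a1 <- as.numeric(ax[1, c("ax", "ay", "az")])
  a2 <- as.numeric(ax[nrow(ax), c("ax", "ay", "az")])
  total_bend <- rad2deg(acos(clamp1(sum(a1 * a2))))
  L <- length(rb$pair_frames)
  centre <- rb$pair_frames[[ceiling(L / 2)]]
  zc <- centre$R[, 3]
  minor_vec <- -centre$R[, 2]
  dvec <- a2 - a1
  proj <- dvec - sum(dvec * zc) * zc
  bend_direction <- if (vnorm(proj) < 1e-9) NA_real_ else
    rad2deg(signed_angle(minor_vec, unitv(proj), zc))
  per_step <- sqrt(rb$step$roll^2 + rb$step$tilt^2)
  list(total_bend = total_bend, bend_direction = bend_direction,
       per_step = data.frame(position = rb$step$position,
                             bend = per_step))
}
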