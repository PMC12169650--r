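# Metadynamics over a twist coordinate: Gaussian hill generation by an
# overdamped Langevin walker, PLUMED-HILLS-dialect I/O, free-energy
# reconstruction as the negative accumulated bias, the windowed averaging
# protocol, convergence diagnostics and run pruning.
#
# Units: the collective variable is the central-step twist. Hill centers
# and widths are stored in radians (as deposited), times in ps; grids and
# reported profiles are in degrees, free energies in kJ/mol. kT at 300 K
# is 2.494 kJ/mol.

KT_KJMOL <- 2.494

#' Analytic collective-variable potentials for the hill generator
#'
#' `"flat"` is zero everywhere; `"double_well"` is a quartic with minima at
#' `minima` (degrees) and barrier `barrier` kJ/mol between them;
#' `"harmonic"` is `0.5 * k * (s - s0)^2`.
#'
#' @param type Potential type.
#' @param minima Two well positions, degrees (double_well).
#' @param barrier Barrier height, kJ/mol (double_well).
#' @param s0 Minimum position, degrees (harmonic).
#' @param k Force constant, kJ/mol/deg^2 (harmonic).
#' @return Function `U(s_deg) -> kJ/mol`.
#' @export
make_potential <- function(type = c("flat", "double_well", "harmonic"),
                           minima = c(25, 45), barrier = 5, s0 = 35,
                           k = 0.05) {
  type <- match.arg(type)
  switch(type,
    flat = function(s) rep(0, length(s)),
    double_well = {
      m1 <- minima[1]; m2 <- minima[2]
      function(s) barrier * 16 * ((s - m1) * (s - m2))^2 / (m2 - m1)^4
    },
    harmonic = function(s) 0.5 * k * (s - s0)^2)
}

#' Generate metadynamics hill deposits on a model potential
#'
#' An overdamped Langevin walker (Euler-Maruyama, kT = 2.494 kJ/mol,
#' reflective walls at the bias boundaries) moves on `potential` plus the
#' accumulated Gaussian bias; one hill is deposited at the walker position
#' every `stride_ps`. The default hill shape follows the standard
#' twist-metadynamics setup: width 0.04 rad, height 0.1 kJ/mol, deposited
#' every 4 ps, bias confined to [10, 60] degrees.
#'
#' @param potential Function `U(s_deg)` in kJ/mol (see [make_potential()]).
#' @param duration_ns Total biased time, ns (0 gives an empty record list).
#' @param sigma Hill width, radians (default 0.04).
#' @param height Hill height, kJ/mol (default 0.1).
#' @param stride_ps Deposition stride, ps (default 4).
#' @param boundaries Bias interval in degrees (default `c(10, 60)`); the
#'   bias force is zero outside and the walker is reflected at the walls.
#' @param seed RNG seed.
#' @param dt_ps Integration time step, ps (default 0.1).
#' @param diffusion Walker diffusion coefficient, deg^2/ns (default 1e4,
#'   fast enough that a flat-potential walker traverses the interval well
#'   before 10 ns and the accumulated bias self-heals between deposits).
#' @param max_drift Per-step drift cap, degrees (default 2; only active on
#'   the steep outer walls of confining potentials, where plain
#'   Euler-Maruyama would overshoot).
#' @param s_start Starting position, degrees (default interval midpoint).
#' @return `list(hills, cv)`: `hills` is a data.frame (`time_ps`, `cv_rad`,
#'   `sigma_rad`, `height`), `cv` the walker time series (`time_ps`,
#'   `twist_deg`).
#' @export
generate_hills <- function(potential, duration_ns, sigma = 0.04,
                           height = 0.1, stride_ps = 4,
                           boundaries = c(10, 60), seed = 1, dt_ps = 0.1,
                           diffusion = 1e4, max_drift = 2,
                           s_start = mean(boundaries)) {
  stopifnot(sigma > 0, height > 0, stride_ps > 0, dt_ps > 0,
            boundaries[2] > boundaries[1])
  empty <- data.frame(time_ps = numeric(0), cv_rad = numeric(0),
                      sigma_rad = numeric(0), height = numeric(0))
  if (duration_ns <= 0)
    return(list(hills = empty,
                cv = data.frame(time_ps = numeric(0),
                                twist_deg = numeric(0))))
  set.seed(seed)
  lo <- boundaries[1]; hi <- boundaries[2]
  sigma_deg <- rad2deg(sigma)
  # bias and bias force kept on a fine grid, updated per deposit
  dg <- 0.05
  grid <- seq(lo, hi, by = dg)
  fbias <- numeric(length(grid))
  mob <- diffusion / KT_KJMOL          # deg^2 / ns / (kJ/mol)
  dt_ns <- dt_ps / 1000
  noise_sd <- sqrt(2 * diffusion * dt_ns)
  eps <- 0.01
  n_steps <- round(duration_ns * 1000 / dt_ps)
  stride_steps <- max(1, round(stride_ps / dt_ps))
  s <- s_start
  n_hills_max <- floor(n_steps / stride_steps)
  h_time <- numeric(n_hills_max); h_cv <- numeric(n_hills_max)
  cv_t <- numeric(n_hills_max); cv_s <- numeric(n_hills_max)
  nh <- 0L
  noise <- stats::rnorm(n_steps, 0, noise_sd)
  for (step in seq_len(n_steps)) {
    fpot <- -(potential(s + eps) - potential(s - eps)) / (2 * eps)
    fb <- fbias[round((s - lo) / dg) + 1]
    drift <- mob * (fpot + fb) * dt_ns
    if (abs(drift) > max_drift) drift <- sign(drift) * max_drift
    s <- s + drift + noise[step]
    if (s < lo) s <- 2 * lo - s
    if (s > hi) s <- 2 * hi - s
    if (step %% stride_steps == 0) {
      nh <- nh + 1L
      t_ps <- step * dt_ps
      h_time[nh] <- t_ps
      h_cv[nh] <- s
      cv_t[nh] <- t_ps
      cv_s[nh] <- s
      dev <- grid - s
      g <- height * exp(-dev^2 / (2 * sigma_deg^2))
      fbias <- fbias + dev / sigma_deg^2 * g  # -d(bias)/ds
    }
  }
  list(hills = data.frame(time_ps = h_time[1:nh],
                          cv_rad = deg2rad(h_cv[1:nh]),
                          sigma_rad = sigma, height = height),
       cv = data.frame(time_ps = cv_t[1:nh], twist_deg = cv_s[1:nh]))
}

#' Write hill records in the PLUMED HILLS text dialect
#'
#' Columns: time (ps), twist (rad), sigma_twist (rad), height (kJ/mol),
#' biasf; header line `#! FIELDS ...`.
#'
#' @param hills data.frame as produced by [generate_hills()]`$hills`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time twist sigma_twist height biasf", con)
  if (nrow(hills) > 0) {
    lines <- sprintf("%14.3f %20.16f %12.6f %12.6f %12.6f",
                     hills$time_ps, hills$cv_rad, hills$sigma_rad,
                     hills$height, 1)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a PLUMED-HILLS-dialect file
#'
#' Whitespace-delimited text with a `#! FIELDS` header naming at least
#' time, a collective-variable column, its sigma, and height. A biasfactor
#' column is parsed but well-tempered rescaling is not supported; values
#' other than 1 trigger a warning and the heights are used as deposited.
#'
#' @param path File path.
#' @return data.frame (`time_ps`, `cv_rad`, `sigma_rad`, `height`).
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#!\\s*FIELDS", lines)
  if (length(hdr_idx) == 0)
    stop("no '#! FIELDS' header line in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[hdr_idx[1]]),
                     "\\s+")[[1]]
  data_idx <- setdiff(seq_along(lines), grep("^#", lines))
  data_idx <- data_idx[nzchar(trimws(lines[data_idx]))]
  if (length(data_idx) == 0) {
    return(data.frame(time_ps = numeric(0), cv_rad = numeric(0),
                      sigma_rad = numeric(0), height = numeric(0)))
  }
  vals <- utils::read.table(text = lines[data_idx])
  if (ncol(vals) != length(fields))
    stop("column count does not match FIELDS header in ", path)
  names(vals) <- fields
  cvcol <- setdiff(fields, c("time", "height", "biasf",
                             grep("^sigma", fields, value = TRUE)))
  if (length(cvcol) != 1 || !"time" %in% fields || !"height" %in% fields ||
        length(grep("^sigma", fields)) != 1)
    stop("missing required column(s) among time/<cv>/sigma_<cv>/height in ",
         path)
  tm <- vals[["time"]]
  if (any(diff(tm) < 0)) {
    bad <- which(diff(tm) < 0)[1] + 1
    stop(sprintf("non-monotone time at data line %d of %s", bad, path))
  }
  if ("biasf" %in% fields && any(vals[["biasf"]] != 1))
    warning("biasfactor column present: well-tempered rescaling is not ",
            "supported; heights used as deposited")
  data.frame(time_ps = tm, cv_rad = vals[[cvcol]],
             sigma_rad = vals[[grep("^sigma", fields, value = TRUE)]],
             height = vals[["height"]])
}

#' Reconstruct a free-energy profile from hill deposits
#'
#' `F(s) = -sum_k h_k exp(-(s - s_k)^2 / (2 sigma_k^2))`, shifted so the
#' minimum over the grid is zero. The bias (and hence the estimate) is
#' defined only inside the boundaries.
#'
#' @param hills Hill data.frame (`time_ps`, `cv_rad`, `sigma_rad`,
#'   `height`).
#' @param grid Evaluation grid in degrees (default 0.25 deg spacing over
#'   the boundaries).
#' @param boundaries Bias interval, degrees.
#' @param align Shift minimum to zero (default TRUE).
#' @return data.frame: `twist_deg`, `F_kJmol`.
#' @export
reconstruct_fes <- function(hills, grid = NULL, boundaries = c(10, 60),
                            align = TRUE) {
  if (is.null(grid)) grid <- seq(boundaries[1], boundaries[2], by = 0.25)
  if (any(grid < boundaries[1] - 1e-9 | grid > boundaries[2] + 1e-9))
    stop("grid must lie within the bias boundaries")
  g_rad <- deg2rad(grid)
  if (nrow(hills) == 0) {
    F <- rep(0, length(grid))
  } else {
    dev <- outer(g_rad, hills$cv_rad, "-")
    E <- exp(-dev^2 / (2 * rep(hills$sigma_rad, each = length(g_rad))^2))
    F <- -as.numeric(E %*% hills$height)
  }
  if (align) F <- F - min(F)
  data.frame(twist_deg = grid, F_kJmol = F)
}

#' Windowed averaging of metadynamics profiles
#'
#' Reconstructs one sub-profile from all hills deposited up to each
#' checkpoint (`every_ns` apart, default 2 ns, within `window`, default 10
#' to 50 ns), min-aligns each sub-profile to zero, and returns the
#' pointwise mean and standard deviation.
#'
#' @param hills Hill data.frame.
#' @param every_ns Checkpoint spacing, ns.
#' @param window `c(start, end)` of the averaging window, ns.
#' @param grid,boundaries As in [reconstruct_fes()].
#' @return An object of class `fes_profile`: list with `profile`
#'   (data.frame `twist_deg`, `F_kJmol`, `F_sd`), `window`,
#'   `n_subprofiles`.
#' @export
windowed_profiles <- function(hills, every_ns = 2, window = c(10, 50),
                              grid = NULL, boundaries = c(10, 60)) {
  if (is.null(grid)) grid <- seq(boundaries[1], boundaries[2], by = 0.25)
  span_ns <- if (nrow(hills) == 0) 0 else max(hills$time_ps) / 1000
  if (span_ns < window[2])
    stop(sprintf("hills span %.1f ns but the averaging window ends at %g ns",
                 span_ns, window[2]))
  checkpoints <- seq(window[1], window[2], by = every_ns)
  g_rad <- deg2rad(grid)
  ord <- order(hills$time_ps)
  hills <- hills[ord, ]
  # incremental accumulation: add each chunk of hills once
  Fs <- matrix(NA_real_, length(grid), length(checkpoints))
  acc <- rep(0, length(grid))
  prev_t <- -Inf
  for (k in seq_along(checkpoints)) {
    t_ps <- checkpoints[k] * 1000
    sel <- hills$time_ps > prev_t & hills$time_ps <= t_ps
    if (any(sel)) {
      dev <- outer(g_rad, hills$cv_rad[sel], "-")
      E <- exp(-dev^2 /
                 (2 * rep(hills$sigma_rad[sel], each = length(g_rad))^2))
      acc <- acc + as.numeric(E %*% hills$height[sel])
    }
    Fk <- -acc
    Fs[, k] <- Fk - min(Fk)
    prev_t <- t_ps
  }
  F_sd <- if (ncol(Fs) > 1) apply(Fs, 1, stats::sd) else rep(0, nrow(Fs))
  prof <- data.frame(twist_deg = grid, F_kJmol = rowMeans(Fs),
                     F_sd = F_sd)
  prof$F_kJmol <- prof$F_kJmol - min(prof$F_kJmol)
  structure(list(profile = prof, window = window,
                 n_subprofiles = length(checkpoints)),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  mw <- fes_minimum_and_width(x)
  cat(sprintf(
    "fes_profile: %d points, window %g-%g ns (%d sub-profiles)\n",
    nrow(x$profile), x$window[1], x$window[2], x$n_subprofiles))
  cat(sprintf("  minimum at %.2f deg, valley width %.2f deg at kT\n",
              mw["s_min"], mw["width"]))
  invisible(x)
}

#' @export
plot.fes_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$twist_deg, p$F_kJmol, type = "l", xlab = "twist (deg)",
                 ylab = "F (kJ/mol)", ...)
  graphics::polygon(c(p$twist_deg, rev(p$twist_deg)),
                    c(p$F_kJmol - p$F_sd, rev(p$F_kJmol + p$F_sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(p$twist_deg, p$F_kJmol)
  invisible(x)
}

.profile_df <- function(profile) {
  if (inherits(profile, "fes_profile")) profile$profile else profile
}

#' Free-energy minimum and valley width
#'
#' Returns the grid position of the global minimum of a (min-aligned)
#' profile and the width of the connected region around it with
#' `F <= level` (default kT = 2.494 kJ/mol), with linear interpolation at
#' the crossings. A minimum on the boundary, or a valley reaching it, is
#' flagged via the `"flagged"` attribute.
#'
#' @param profile An `fes_profile` or a data.frame (`twist_deg`,
#'   `F_kJmol`).
#' @param level Contour level, kJ/mol.
#' @return Named vector `c(s_min, width)` in degrees.
#' @export
fes_minimum_and_width <- function(profile, level = KT_KJMOL) {
  p <- .profile_df(profile)
  F <- p$F_kJmol - min(p$F_kJmol)
  s <- p$twist_deg
  i0 <- which.min(F)
  flagged <- i0 == 1 || i0 == length(F)
  il <- i0
  while (il > 1 && F[il - 1] <= level) il <- il - 1
  ir <- i0
  while (ir < length(F) && F[ir + 1] <= level) ir <- ir + 1
  s_left <- if (il == 1) {
    flagged <- TRUE
    s[1]
  } else s[il] - (s[il] - s[il - 1]) * (level - F[il]) / (F[il - 1] - F[il])
  s_right <- if (ir == length(F)) {
    flagged <- TRUE
    s[ir]
  } else s[ir] + (s[ir + 1] - s[ir]) * (level - F[ir]) / (F[ir + 1] - F[ir])
  out <- c(s_min = s[i0], width = s_right - s_left)
  attr(out, "flagged") <- flagged
  out
}

#' Local minima of a free-energy profile
#'
#' Interior grid points that are the minimum of their neighbourhood
#' (radius `radius` degrees), ordered by increasing free energy.
#'
#' @param profile An `fes_profile` or profile data.frame.
#' @param radius Neighbourhood radius, degrees (default 3).
#' @return data.frame: `twist_deg`, `F_kJmol`.
#' @export
fes_local_minima <- function(profile, radius = 3) {
  p <- .profile_df(profile)
  s <- p$twist_deg
  F <- p$F_kJmol
  n <- length(s)
  keep <- logical(n)
  for (i in 2:(n - 1)) {
    nb <- which(abs(s - s[i]) <= radius)
    keep[i] <- F[i] == min(F[nb]) && i == nb[which.min(F[nb])]
  }
  out <- p[keep, c("twist_deg", "F_kJmol")]
  out[order(out$F_kJmol), ]
}

#' Free-diffusion diagnostics of a biased run
#'
#' Reports the covered fraction of the biasing interval, the number of
#' boundary-to-boundary traversals, the time of the first traversal, and a
#' pass flag (at least one traversal before `deadline_ns`).
#'
#' @param cv data.frame (`time_ps`, `twist_deg`).
#' @param boundaries Bias interval, degrees.
#' @param margin How close to a wall counts as reaching it, degrees
#'   (default 2.5, about one hill width).
#' @param deadline_ns Deadline for the first traversal (default 10 ns).
#' @return `list(coverage, n_traversals, first_traversal_ns, pass)`.
#' @export
free_diffusion_check <- function(cv, boundaries = c(10, 60), margin = 2.5,
                                 deadline_ns = 10) {
  if (nrow(cv) == 0) stop("empty collective-variable series")
  lo <- boundaries[1]; hi <- boundaries[2]
  coverage <- (max(cv$twist_deg) - min(cv$twist_deg)) / (hi - lo)
  at <- ifelse(cv$twist_deg <= lo + margin, -1L,
               ifelse(cv$twist_deg >= hi - margin, 1L, 0L))
  n_trav <- 0L
  first_ns <- NA_real_
  state <- 0L
  for (i in seq_along(at)) {
    if (at[i] != 0 && at[i] != state) {
      if (state != 0) {
        n_trav <- n_trav + 1L
        if (is.na(first_ns)) first_ns <- cv$time_ps[i] / 1000
      }
      state <- at[i]
    }
  }
  list(coverage = coverage, n_traversals = n_trav,
       first_traversal_ns = first_ns,
       pass = n_trav >= 1 && !is.na(first_ns) && first_ns <= deadline_ns)
}

#' Base-pair opening of a duplex frame
#'
#' A pair is "open" in a frame when every Watson-Crick donor-acceptor
#' heavy-atom distance exceeds 3.5 Angstrom.
#'
#' @param frame A `duplex_structure`.
#' @param pair_index Base-pair position(s) (default all).
#' @param cutoff Distance threshold, Angstrom.
#' @return Logical vector: TRUE if the pair is intact.
#' @export
base_pair_intact <- function(frame, pair_index = NULL, cutoff = 3.5) {
  stopifnot(inherits(frame, "duplex_structure"))
  pairs <- frame$pairs
  chains <- frame$strand_chains
  if (is.null(pair_index)) pair_index <- seq_len(nrow(pairs))
  vapply(pair_index, function(i) {
    wres <- residue_xyz(frame, chains[1], pairs[i, 1])
    cres <- residue_xyz(frame, chains[2], pairs[i, 2])
    wb <- frame$sequences[[chains[1]]][pairs[i, 1]]
    any(vapply(wc_hbond_atoms(wb), function(ab) {
      ok <- ab[1] %in% rownames(wres) && ab[2] %in% rownames(cres)
      ok && vnorm(wres[ab[1], ] - cres[ab[2], ]) <= cutoff
    }, logical(1)))
  }, logical(1))
}

#' Prune metadynamics runs with unrecovered base-pair opening
#'
#' A run is excluded from profile averaging when more than one of the
#' monitored (central) base pairs opens and never re-forms: a pair counts
#' as unrecovered when it is open at every frame from its first opening to
#' the end of the run. The decision is a pure function of the pairing time
#' series.
#'
#' @param intact Logical matrix, frames x pairs; TRUE = pair intact.
#' @return `list(include, n_unrecovered, unrecovered)` where `unrecovered`
#'   is a logical vector per pair.
#' @export
prune_opened <- function(intact) {
  intact <- as.matrix(intact)
  unrec <- apply(intact, 2, function(col) {
    if (all(col)) return(FALSE)
    first <- which(!col)[1]
    all(!col[first:length(col)])
  })
  list(include = sum(unrec) <= 1, n_unrecovered = sum(unrec),
       unrecovered = unrec)
}
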