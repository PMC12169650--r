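# Synthetic ensemble and probe-complex generators: perturbed duplex
# ensembles with controlled per-step parameter fluctuations and neighbour
# twist coupling, and geometric pseudo-protein probes used to create
# contact fixtures with exactly known counts.

#' Specification of a perturbed duplex ensemble
#'
#' @param n_frames Number of frames.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param step_sd Length-6 fluctuation SDs for (tilt, roll, twist, shift,
#'   slide, rise), degrees/Angstrom. Default small B-DNA-like thermal
#'   fluctuations.
#' @param pair_sd Length-6 SDs for (buckle, propeller, opening, shear,
#'   stretch, stagger).
#' @param rho Target Pearson correlation between adjacent step twists
#'   (default 0; `|rho| < 1` and the implied tridiagonal covariance must be
#'   positive definite).
#' @param time_step_ns Frame spacing in ns.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_frames, seed,
                          step_sd = c(3, 4, 4, 0.4, 0.4, 0.2),
                          pair_sd = c(6, 6, 3, 0.2, 0.1, 0.2),
                          rho = 0, time_step_ns = 0.1) {
  stopifnot(n_frames >= 1, length(step_sd) == 6, length(pair_sd) == 6,
            all(step_sd >= 0), all(pair_sd >= 0), abs(rho) < 1)
  structure(list(n_frames = n_frames, seed = seed, step_sd = step_sd,
                 pair_sd = pair_sd, rho = rho, time_step_ns = time_step_ns),
            class = "ensemble_spec")
}

# draw n x m twist deviations with tridiagonal adjacent correlation rho
.sample_coupled <- function(n, m, sd, rho) {
  C <- diag(m)
  if (m > 1) {
    C[cbind(1:(m - 1), 2:m)] <- rho
    C[cbind(2:m, 1:(m - 1))] <- rho
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("requested twist coupling rho = ", rho,
         " gives a non-positive-definite covariance"))
  matrix(stats::rnorm(n * m), n, m) %*% ch * sd
}

#' Sample a perturbed duplex ensemble
#'
#' Per-frame step and pair parameters are drawn around the duplex spec
#' means: all parameters are independent Gaussians with the requested SDs,
#' except the step twists which share a multivariate normal with the
#' requested adjacent-step correlation `rho`. Coordinates are rebuilt per
#' frame with [build_duplex()], so extraction recovers the sampled
#' parameters exactly. Bit-reproducible under a fixed seed.
#'
#' @param duplex_spec List with `sequence` and optionally `step`, `pair`,
#'   `sugar` mean parameters (defaults: canonical B-form).
#' @param spec An [ensemble_spec()].
#' @return A `dna_ensemble`; the sampled parameter arrays are attached as
#'   attribute `"truth"` (frames x positions x 6 arrays `step`, `pair`).
#' @export
sample_ensemble <- function(duplex_spec, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  seq_chr <- duplex_spec$sequence
  if (length(seq_chr) == 1) seq_chr <- strsplit(seq_chr, "")[[1]]
  L <- length(seq_chr)
  bform <- canonical_forms$B
  step_mean <- .expand_param_matrix(duplex_spec$step %||% bform$step,
                                    L - 1, param_names_step, "step means")
  pair_mean <- .expand_param_matrix(duplex_spec$pair %||% bform$pair,
                                    L, param_names_pair, "pair means")
  sugar <- duplex_spec$sugar %||% bform$sugar
  set.seed(spec$seed)
  nf <- spec$n_frames
  step_arr <- array(NA_real_, c(nf, L - 1, 6),
                    dimnames = list(NULL, NULL, param_names_step))
  pair_arr <- array(NA_real_, c(nf, L, 6),
                    dimnames = list(NULL, NULL, param_names_pair))
  for (k in 1:6) {
    if (param_names_step[k] == "twist") {
      dev <- .sample_coupled(nf, L - 1, spec$step_sd[k], spec$rho)
    } else {
      dev <- matrix(stats::rnorm(nf * (L - 1), 0, spec$step_sd[k]),
                    nf, L - 1)
    }
    step_arr[, , k] <- sweep(dev, 2, step_mean[, k], "+")
    pair_arr[, , k] <- sweep(
      matrix(stats::rnorm(nf * L, 0, spec$pair_sd[k]), nf, L),
      2, pair_mean[, k], "+")
  }
  frames <- vector("list", nf)
  for (m in seq_len(nf)) {
    frames[[m]] <- build_duplex(seq_chr,
                                step_params = step_arr[m, , , drop = TRUE],
                                pair_params = pair_arr[m, , , drop = TRUE],
                                sugar = sugar)
  }
  ens <- ensemble_from_structures(frames,
                                  times = seq_len(nf) * spec$time_step_ns)
  attr(ens, "truth") <- list(step = step_arr, pair = pair_arr)
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic quasi-uniform directions on the sphere (Fibonacci lattice)
.fibonacci_directions <- function(n = 500) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Attach a geometric pseudo-protein probe to a duplex
#'
#' Places labelled pseudo-atoms (e.g. a Trp NE1, QGR motif heavy atoms) at
#' exact distances from named DNA atoms, producing contact-test fixtures
#' with brute-force-checkable counts. Each probe row anchors one atom at
#' `distance` Angstrom from the target DNA atom; the direction is either
#' supplied (`dx,dy,dz`) or chosen deterministically as the direction
#' maximizing clearance from all other DNA heavy atoms.
#'
#' @param duplex A `duplex_structure`.
#' @param probe_spec data.frame with columns `elety`, `resid`, `resno`,
#'   `target_chain`, `target_resno`, `target_elety`, `distance`, optional
#'   `dx`, `dy`, `dz`.
#' @param chain Chain id for the probe atoms (default "P").
#' @return A `duplex_structure` including the probe chain.
#' @export
build_probe_complex <- function(duplex, probe_spec, chain = "P") {
  stopifnot(inherits(duplex, "duplex_structure"),
            all(c("elety", "resid", "resno", "target_chain", "target_resno",
                  "target_elety", "distance") %in% names(probe_spec)))
  at <- duplex$atoms
  dna_xyz <- as.matrix(at[, c("x", "y", "z")])
  rows <- list()
  for (r in seq_len(nrow(probe_spec))) {
    ps <- probe_spec[r, ]
    if (ps$distance <= 0) stop("infeasible probe distance at row ", r)
    anchor <- residue_xyz(duplex, ps$target_chain, ps$target_resno,
                          ps$target_elety)[1, ]
    if (all(c("dx", "dy", "dz") %in% names(ps)) &&
          !any(is.na(c(ps$dx, ps$dy, ps$dz)))) {
      dir <- unitv(c(ps$dx, ps$dy, ps$dz))
    } else {
      dirs <- .fibonacci_directions(500)
      best <- -Inf
      dir <- dirs[1, ]
      for (k in seq_len(nrow(dirs))) {
        p <- anchor + ps$distance * dirs[k, ]
        clear <- min(sqrt(rowSums(sweep(dna_xyz, 2, p)^2)))
        if (clear > best) {
          best <- clear
          dir <- dirs[k, ]
        }
      }
    }
    p <- anchor + ps$distance * dir
    rows[[r]] <- data.frame(elety = ps$elety, resid = ps$resid,
                            chain = chain, resno = ps$resno,
                            elesy = .elesy_from_name(ps$elety),
                            x = p[1], y = p[2], z = p[3],
                            stringsAsFactors = FALSE)
  }
  out <- duplex
  out$atoms <- rbind(at, do.call(rbind, rows))
  out
}

#' Brute-force all-pairs contact count (test oracle)
#'
#' Plain O(n^2) double loop over two coordinate sets; used as the
#' independent reference for [count_contacts()].
#'
#' @param xa,xb Coordinate matrices (n x 3).
#' @param cutoff Cutoff, Angstrom (strict `<`).
#' @return Integer count.
#' @export
brute_force_contacts <- function(xa, xb, cutoff = 4.5) {
  n <- 0L
  for (i in seq_len(nrow(xa)))
    for (j in seq_len(nrow(xb)))
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < cutoff) n <- n + 1L
  n
}
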