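# Frame fitting and duplex-level rigid-base parameter extraction.

#' Fit a standard-base frame to an observed residue
#'
#' Least-squares (Kabsch) superposition of the embedded standard base onto
#' the observed base ring heavy atoms; reflections are corrected to proper
#' rotations. The residue's frame is the image of the standard frame under
#' the fitted transform.
#'
#' @param residue Coordinate matrix with base-atom rownames, or a
#'   `duplex_structure` together with `chain`/`resno`.
#' @param base Base type "A", "C", "G" or "T"; inferred from the structure
#'   when `residue` is a `duplex_structure`.
#' @param chain,resno Residue address when `residue` is a structure.
#' @return `list(R, o)` frame (rotation matrix, origin) with the fit RMSD as
#'   attribute `"rmsd"`.
#' @export
fit_base_frame <- function(residue, base = NULL, chain = NULL, resno = NULL) {
  if (inherits(residue, "duplex_structure")) {
    stopifnot(!is.null(chain), !is.null(resno))
    sub <- residue$atoms[residue$atoms$chain == chain &
                           residue$atoms$resno == resno, ]
    base <- resid_to_base(sub$resid[1])
    residue <- residue_xyz(residue, chain, resno)
  }
  stopifnot(!is.null(base))
  ring <- base_ring_atoms(base)
  have <- intersect(ring, rownames(residue))
  if (length(have) < 3)
    stop("fit_base_frame: fewer than 3 matched base ring atoms")
  std <- std_base_coords[[base]][have, , drop = FALSE]
  obs <- residue[have, , drop = FALSE]
  fit <- kabsch_fit(std, obs)
  fitted <- sweep(std %*% t(fit$R), 2, fit$t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - obs)^2)))
  f <- new_frame(fit$R, fit$t)
  attr(f, "rmsd") <- rmsd
  f
}

# base frames of every residue: list(watson = list of frames, crick = ...)
duplex_base_frames <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_structure"))
  pairs <- duplex$pairs
  if (is.null(pairs)) stop("duplex has no pairing")
  chains <- duplex$strand_chains
  L <- nrow(pairs)
  watson <- lapply(seq_len(L), function(i)
    fit_base_frame(duplex, chain = chains[1], resno = pairs[i, 1]))
  crick <- lapply(seq_len(L), function(i)
    fit_base_frame(duplex, chain = chains[2], resno = pairs[i, 2]))
  list(watson = watson, crick = crick)
}

#' Rigid-base parameters of a duplex
#'
#' Fits base frames to every residue and returns all six base-pair
#' parameters per pair and six base-step parameters per step.
#'
#' @param duplex A `duplex_structure`.
#' @return `list(pair, step, pair_frames)`: data.frames of parameters
#'   (column `position` plus the six descriptors) and the list of base-pair
#'   frames.
#' @export
rigid_base_parameters <- function(duplex) {
  frames <- duplex_base_frames(duplex)
  L <- length(frames$watson)
  pair_frames <- vector("list", L)
  pair_mat <- matrix(NA_real_, L, 6, dimnames = list(NULL, param_names_pair))
  for (i in seq_len(L)) {
    pp <- pair_parameters(frames$watson[[i]], frames$crick[[i]])
    pair_mat[i, ] <- pp$params
    pair_frames[[i]] <- pp$frame
  }
  step_mat <- matrix(NA_real_, L - 1, 6,
                     dimnames = list(NULL, param_names_step))
  for (i in seq_len(L - 1)) {
    step_mat[i, ] <- step_parameters(pair_frames[[i]],
                                     pair_frames[[i + 1]])$params
  }
  list(pair = data.frame(position = seq_len(L), pair_mat),
       step = data.frame(position = seq_len(L - 1), step_mat),
       pair_frames = pair_frames)
}

#' Rigid-base parameter time series over an ensemble
#'
#' Extracts the twelve rigid-base descriptors for every frame of an
#' ensemble and summarizes them per position.
#'
#' @param ensemble A `dna_ensemble` of duplex structures.
#' @return `list(step, pair, summary)`: `step` and `pair` are 3-d arrays
#'   (frame x position x parameter); `summary` is a data.frame of mean and
#'   SD per kind/position/parameter.
#' @export
parameter_timeseries <- function(ensemble) {
  stopifnot(inherits(ensemble, "dna_ensemble"))
  nf <- n_frames(ensemble)
  if (nf == 0) stop("empty ensemble")
  first <- rigid_base_parameters(ensemble_frame(ensemble, 1))
  L <- nrow(first$pair)
  pair_arr <- array(NA_real_, c(nf, L, 6),
                    dimnames = list(NULL, NULL, param_names_pair))
  step_arr <- array(NA_real_, c(nf, L - 1, 6),
                    dimnames = list(NULL, NULL, param_names_step))
  pair_arr[1, , ] <- as.matrix(first$pair[, param_names_pair])
  step_arr[1, , ] <- as.matrix(first$step[, param_names_step])
  if (nf > 1) {
    for (m in 2:nf) {
      res <- rigid_base_parameters(ensemble_frame(ensemble, m))
      pair_arr[m, , ] <- as.matrix(res$pair[, param_names_pair])
      step_arr[m, , ] <- as.matrix(res$step[, param_names_step])
    }
  }
  summarize <- function(arr, kind) {
    do.call(rbind, lapply(seq_len(dim(arr)[3]), function(k) {
      data.frame(kind = kind, parameter = dimnames(arr)[[3]][k],
                 position = seq_len(dim(arr)[2]),
                 mean = apply(arr[, , k, drop = FALSE], 2, mean),
                 sd = apply(arr[, , k, drop = FALSE], 2, stats::sd))
    }))
  }
  list(step = step_arr, pair = pair_arr,
       summary = rbind(summarize(step_arr, "step"),
                       summarize(pair_arr, "pair")))
}

#' Correlation between adjacent base-step twists
#'
#' Pools all (twist_i, twist_(i+1)) pairs across frames and interior steps
#' and returns their Pearson correlation; with minor-groove binding the
#' paper-scale analyses find this anticorrelation strengthened.
#'
#' @param ts Result of [parameter_timeseries()] (or a frames x steps twist
#'   matrix).
#' @return Pearson correlation coefficient.
#' @export
adjacent_step_correlation <- function(ts) {
  tw <- if (is.list(ts)) ts$step[, , "twist"] else ts
  if (is.null(dim(tw)) || ncol(tw) < 2)
    stop("need at least two steps for an adjacent-twist correlation")
  a <- as.numeric(tw[, -ncol(tw)])
  b <- as.numeric(tw[, -1])
  stats::cor(a, b)
}
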