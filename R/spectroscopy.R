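# Binding and time-resolved spectroscopy: inner-filter correction,
# Hill-isotherm fitting of quenching titrations, Gibbs free energy of
# dissociation, and IRF-reconvolution multi-exponential lifetime fitting.

R_KCAL <- 1.98720e-3  # kcal / (mol K)

#' Inner-filter correction of fluorescence intensities
#'
#' `F_corr = F_obs * exp((A_ex + A_em) / 2)` with A the absorbances at the
#' excitation and emission wavelengths.
#'
#' @param F_obs Observed intensities (a.u.).
#' @param A_ex,A_em Absorbances (dimensionless, >= 0).
#' @return Corrected intensities.
#' @export
inner_filter_correct <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0)) stop("negative absorbance")
  F_obs * exp((A_ex + A_em) / 2)
}

#' Generate a synthetic quenching titration
#'
#' `F(c) = F0 - (F0 - F_inf) * c^n / (K^n + c^n)` plus Gaussian noise.
#'
#' @param K Half-saturation constant, nM.
#' @param n Hill coefficient.
#' @param F0,F_inf Initial and saturating intensities (a.u.).
#' @param concentrations Ligand concentrations, nM (> 0).
#' @param noise_sd Gaussian noise SD on F (a.u.), default 0.
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return data.frame: `concentration`, `F_obs`, `A_ex`, `A_em` (the
#'   absorbance columns default to 0 = no inner-filter effect).
#' @export
generate_titration <- function(K, n, F0 = 100, F_inf = 10, concentrations,
                               noise_sd = 0, seed = 1) {
  stopifnot(K > 0, n > 0, all(concentrations > 0))
  theta <- concentrations^n / (K^n + concentrations^n)
  Fv <- F0 - (F0 - F_inf) * theta
  if (noise_sd > 0) {
    set.seed(seed)
    Fv <- Fv + stats::rnorm(length(Fv), 0, noise_sd)
  }
  data.frame(concentration = concentrations, F_obs = Fv, A_ex = 0, A_em = 0)
}

#' Fit a quenching titration to the Hill equation
#'
#' The bound fraction is defined from quenching as
#' `theta = (F0 - F) / (F0 - F_inf)`; the isotherm
#' `theta = c^n / (K^n + c^n)` is fitted by least squares on theta versus
#' log10 concentration. `F0`/`F_inf` are co-fitted by default or may be
#' supplied. Standard errors come from the fit covariance; optional seeded
#' bootstrap confidence intervals resample residuals.
#'
#' @param titration data.frame with `concentration` (nM, increasing) and
#'   `F_obs`; optional `A_ex`, `A_em` trigger inner-filter correction.
#' @param F0,F_inf Optional fixed endpoint intensities.
#' @param n_boot Number of bootstrap replicates for CIs (0 = none).
#' @param seed Bootstrap seed.
#' @param temperature Kelvin, for the reported free energy (default 298).
#' @return Object of class `hill_fit`: list with `K` (nM), `n`, `K_se`,
#'   `n_se`, `theta` (fitted fraction per point), `delta_G` (kcal/mol,
#'   1 M standard state), `F0`, `F_inf`, and optionally `K_ci`, `n_ci`.
#' @export
hill_fit <- function(titration, F0 = NULL, F_inf = NULL, n_boot = 0,
                     seed = 1, temperature = 298) {
  stopifnot(all(c("concentration", "F_obs") %in% names(titration)))
  conc <- titration$concentration
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  if (length(conc) < 5) stop("need at least 5 titration points")
  Fv <- titration$F_obs
  if (all(c("A_ex", "A_em") %in% names(titration)))
    Fv <- inner_filter_correct(Fv, titration$A_ex, titration$A_em)
  lc <- log10(conc)
  fixed_ends <- !is.null(F0) && !is.null(F_inf)
  if (fixed_ends) {
    theta_obs <- (F0 - Fv) / (F0 - F_inf)
    if (any(theta_obs < -0.05 | theta_obs > 1.05))
      warning("normalized theta outside [-0.05, 1.05]")
    start <- list(logK = stats::approx(theta_obs, lc, xout = 0.5,
                                       ties = "ordered")$y, n = 1)
    if (is.na(start$logK)) start$logK <- mean(lc)
    fit <- minpack.lm::nlsLM(
      theta_obs ~ 1 / (1 + 10^(n * (logK - lc))),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    f0_0 <- max(Fv); finf_0 <- min(Fv)
    th0 <- (f0_0 - Fv) / max(f0_0 - finf_0, 1e-12)
    lk0 <- stats::approx(th0, lc, xout = 0.5, ties = "ordered")$y
    if (is.na(lk0)) lk0 <- mean(lc)
    fit <- minpack.lm::nlsLM(
      Fv ~ f0 - (f0 - finf) / (1 + 10^(n * (logK - lc))),
      start = list(f0 = f0_0, finf = finf_0, logK = lk0, n = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  if (!fit$convInfo$isConv)
    stop("Hill fit did not converge: ", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  K <- 10^cf[["logK"]]
  n_hill <- cf[["n"]]
  K_se <- n_se <- NA_real_
  if (!is.null(vc)) {
    K_se <- K * log(10) * sqrt(vc["logK", "logK"])  # delta method
    n_se <- sqrt(vc["n", "n"])
  }
  if (!fixed_ends) {
    F0 <- cf[["f0"]]
    F_inf <- cf[["finf"]]
  }
  theta_fit <- 1 / (1 + 10^(n_hill * (cf[["logK"]] - lc)))
  out <- list(K = K, n = n_hill, K_se = K_se, n_se = n_se,
              F0 = F0, F_inf = F_inf, theta = theta_fit,
              delta_G = delta_g(K * 1e-9, temperature),
              temperature = temperature, fit = fit)
  if (n_boot > 0) {
    set.seed(seed)
    resid <- (if (fixed_ends) (F0 - Fv) / (F0 - F_inf) else Fv) -
      stats::fitted(fit)
    sims <- matrix(NA_real_, n_boot, 2)
    yhat <- stats::fitted(fit)
    for (b in seq_len(n_boot)) {
      yb <- yhat + sample(resid, replace = TRUE)
      fb <- tryCatch({
        if (fixed_ends) {
          minpack.lm::nlsLM(yb ~ 1 / (1 + 10^(n * (logK - lc))),
                            start = list(logK = cf[["logK"]],
                                         n = n_hill))
        } else {
          minpack.lm::nlsLM(yb ~ f0 - (f0 - finf) /
                              (1 + 10^(n * (logK - lc))),
                            start = as.list(cf))
        }
      }, error = function(e) NULL)
      if (!is.null(fb))
        sims[b, ] <- c(10^stats::coef(fb)[["logK"]],
                       stats::coef(fb)[["n"]])
    }
    out$K_ci <- stats::quantile(sims[, 1], c(0.025, 0.975), na.rm = TRUE)
    out$n_ci <- stats::quantile(sims[, 2], c(0.025, 0.975), na.rm = TRUE)
  }
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: K = %.4g nM (se %.3g), n = %.3f (se %.3g)\n",
              x$K, x$K_se, x$n, x$n_se))
  cat(sprintf("  delta G (%g K, 1 M standard state) = %.2f kcal/mol\n",
              x$temperature, x$delta_G))
  invisible(x)
}

#' Gibbs free energy of dissociation from K_D
#'
#' `delta G = -RT ln(1/K_D)` with `R = 1.98720e-3` kcal/(mol K) and K_D on
#' the 1 M standard state, i.e. a K_D below 1 M gives a negative delta G.
#'
#' @param K_D_molar Dissociation constant in mol/L (> 0).
#' @param temperature Kelvin (default 298).
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g(1.57e4 * 1e-9)  # -6.55 kcal/mol
#' @export
delta_g <- function(K_D_molar, temperature = 298) {
  if (any(K_D_molar <= 0)) stop("K_D must be positive")
  -R_KCAL * temperature * log(1 / K_D_molar)
}

# ---- time-resolved fluorescence -------------------------------------------

# discrete causal convolution of a multi-exponential decay with an IRF on
# the channel grid; both generator and fitter use this model function.
decay_model <- function(t, amplitudes, lifetimes, irf) {
  dt <- t[2] - t[1]
  dec <- rowSums(vapply(seq_along(lifetimes), function(i)
    amplitudes[i] * exp(-t / lifetimes[i]), numeric(length(t))))
  n <- length(t)
  # causal convolution: out[k] = sum_j irf[j] * dec[k - j + 1]
  out <- stats::convolve(c(irf, rep(0, n)), rev(c(dec, rep(0, n))),
                         type = "open")[seq_len(n)]
  out * dt
}

gaussian_irf <- function(t, fwhm_ns, t0_ns = 0) {
  sd <- max(fwhm_ns / (2 * sqrt(2 * log(2))), 1e-9)
  irf <- stats::dnorm(t, mean = t0_ns, sd = sd)
  s <- sum(irf) * (t[2] - t[1])
  if (s <= 0) {
    irf <- numeric(length(t))
    irf[which.min(abs(t - t0_ns))] <- 1 / (t[2] - t[1])
    return(irf)
  }
  irf / s
}

#' Generate a synthetic TCSPC decay histogram
#'
#' A multi-exponential decay `I(t) = sum_i alpha_i exp(-t / tau_i)` is
#' convolved with a Gaussian instrument response function, scaled to the
#' requested total counts, and optionally Poisson-sampled per channel.
#'
#' @param amplitudes Pre-exponential factors (>= 0, at least one > 0).
#' @param lifetimes Lifetimes tau_i, ns (> 0).
#' @param irf_fwhm_ns IRF full width at half maximum, ns (default 1).
#' @param irf_t0_ns IRF peak position, ns (default 2).
#' @param dt_ns Channel width, ns.
#' @param n_channels Number of channels.
#' @param total_counts Total expected counts (0 gives an all-zero
#'   histogram).
#' @param noise Poisson-sample the channels (default TRUE).
#' @param seed RNG seed.
#' @return data.frame: `time_ns`, `counts`; the IRF vector is attached as
#'   attribute `"irf"`.
#' @export
generate_decay <- function(amplitudes, lifetimes, irf_fwhm_ns = 1,
                           irf_t0_ns = 2, dt_ns = 0.05, n_channels = 1024,
                           total_counts = 1e6, noise = TRUE, seed = 1) {
  stopifnot(all(lifetimes > 0), all(amplitudes >= 0), any(amplitudes > 0),
            dt_ns > 0, n_channels > 0)
  t <- (seq_len(n_channels) - 1) * dt_ns
  irf <- gaussian_irf(t, irf_fwhm_ns, irf_t0_ns)
  model <- decay_model(t, amplitudes, lifetimes, irf)
  model[model < 0] <- 0
  counts <- if (total_counts > 0) model / sum(model) * total_counts
            else numeric(n_channels)
  if (noise && total_counts > 0) {
    set.seed(seed)
    counts <- stats::rpois(n_channels, counts)
  }
  out <- data.frame(time_ns = t, counts = counts)
  attr(out, "irf") <- irf
  out
}

#' IRF-reconvolution multi-exponential decay fit
#'
#' Fits `I(t) = sum_i alpha_i exp(-t / tau_i)` numerically convolved with
#' the instrument response function by weighted least squares (weights
#' `1 / max(counts, 1)`, the Poisson approximation). Amplitudes and
#' lifetimes are constrained positive via a log transform. Components are
#' returned sorted by lifetime.
#'
#' @param decay data.frame (`time_ns`, `counts`).
#' @param irf IRF vector on the same channel grid (normalized); defaults to
#'   the `"irf"` attribute of `decay`.
#' @param n_components Number of exponentials (1-3).
#' @param start Optional list with `amplitudes`, `lifetimes` start values.
#' @return Object of class `decay_fit`: `amplitudes`, `lifetimes` (ns),
#'   `tau_se`, `chisq_red`, `fitted`, `residuals` (standardized).
#' @export
fit_decay <- function(decay, irf = attr(decay, "irf"), n_components = 1,
                      start = NULL) {
  stopifnot(all(decay$counts >= 0))
  if (n_components > 3)
    stop("more than 3 decay components are not identifiable here")
  t <- decay$time_ns
  y <- decay$counts
  if (is.null(irf)) stop("an IRF on the decay channel grid is required")
  w <- 1 / pmax(y, 1)
  if (is.null(start)) {
    # moment-based spread of initial lifetimes around the mean delay
    pk <- which.max(y)
    tail_t <- t[pk:length(t)] - t[pk]
    tail_y <- y[pk:length(y)]
    tbar <- max(sum(tail_t * tail_y) / max(sum(tail_y), 1e-12), 0.1)
    taus <- tbar * 2^(seq(-(n_components - 1) / 2,
                          (n_components - 1) / 2, length.out = n_components))
    amps <- rep(max(y), n_components)
    start <- list(amplitudes = amps, lifetimes = taus)
  }
  par0 <- c(log(start$amplitudes), log(start$lifetimes))
  resid_fn <- function(par) {
    a <- exp(par[seq_len(n_components)])
    tau <- exp(par[n_components + seq_len(n_components)])
    sqrt(w) * (decay_model(t, a, tau, irf) - y)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 10000,
                              ftol = 1e-14, ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5)
    stop("decay fit did not converge: ", fit$message)
  a <- exp(fit$par[seq_len(n_components)])
  tau <- exp(fit$par[n_components + seq_len(n_components)])
  ord <- order(tau)
  a <- a[ord]
  tau <- tau[ord]
  fitted <- decay_model(t, a, tau, irf)
  dof <- length(y) - 2 * n_components
  chisq_red <- sum(w * (fitted - y)^2) / dof
  tau_se <- rep(NA_real_, n_components)
  cv <- tryCatch(solve(fit$hessian) * 2 * fit$deviance / dof,
                 error = function(e) NULL)
  if (!is.null(cv)) {
    idx <- (n_components + seq_len(n_components))[ord]
    tau_se <- tau * sqrt(pmax(diag(cv)[idx], 0))
  }
  structure(list(amplitudes = a, lifetimes = tau, tau_se = tau_se,
                 chisq_red = chisq_red, fitted = fitted,
                 residuals = sqrt(w) * (y - fitted)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  comps <- paste(sprintf("alpha=%.3g tau=%.3g ns", x$amplitudes,
                         x$lifetimes), collapse = "; ")
  cat("decay_fit:", comps, sprintf("(chisq_red %.3f)\n", x$chisq_red))
  invisible(x)
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' `sum(alpha_i tau_i) / sum(alpha_i)`; invariant to amplitude rescaling.
#'
#' @param fit A `decay_fit` (or list with `amplitudes`, `lifetimes`).
#' @return Mean lifetime, ns.
#' @export
mean_lifetime <- function(fit) {
  sum(fit$amplitudes * fit$lifetimes) / sum(fit$amplitudes)
}
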