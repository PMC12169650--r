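test_that("extraction after building reproduces the requested parameters", {
  d <- build_duplex(apt_sequence,
                    step_params = c(0, 0, 36, 0, 0, 3.38),
                    pair_params = rep(0, 6))
  rb <- rigid_base_parameters(d)
  expect_equal_tol(as.matrix(rb$step[, -1]),
                   matrix(c(0, 0, 36, 0, 0, 3.38), 11, 6, byrow = TRUE),
                   1e-6)
  expect_equal_tol(as.matrix(rb$pair[, -1]), matrix(0, 12, 6), 1e-6)
})

test_that("A-form spec builds to A-form step parameters", {
  d <- build_form_duplex(gpc_sequence, "A")
  rb <- rigid_base_parameters(d)
  expect_equal_tol(rb$step$twist, rep(32.7, 11), 1e-6)
  expect_equal_tol(rb$step$rise, rep(2.56, 11), 1e-6)
  expect_equal_tol(rb$step$slide, rep(-1.5, 11), 1e-6)
})

test_that("random in-range parameters round trip through build/extract", {
  set.seed(7)
  L <- 12
  sp <- cbind(stats::runif(L - 1, -10, 10), stats::runif(L - 1, -10, 10),
              stats::runif(L - 1, 25, 45), stats::runif(L - 1, -1, 1),
              stats::runif(L - 1, -2, 1), stats::runif(L - 1, 2.8, 4))
  pp <- cbind(stats::runif(L, -12, 12), stats::runif(L, -15, 5),
              stats::runif(L, -5, 5), stats::runif(L, -0.5, 0.5),
              stats::runif(L, -0.3, 0.3), stats::runif(L, -0.5, 0.5))
  d <- build_duplex(apt_sequence, step_params = sp, pair_params = pp)
  rb <- rigid_base_parameters(d)
  expect_equal_tol(as.matrix(rb$step[, -1]), sp, 1e-6)
  expect_equal_tol(as.matrix(rb$pair[, -1]), pp, 1e-6)
})

test_that("builder sugars realize the requested pucker and chi", {
  d <- build_duplex(apt_sequence, sugar = c(18, 38, -160))
  for (i in c(1, 5, 9)) {
    ps <- pseudorotation(duplexform:::residue_xyz(d, "A", i))
    expect_lt(abs(ps["P"] - 18), 5)
    expect_lt(abs(chi_angle(d, chain = "A", resno = i) - (-160)), 2)
  }
  ps_c <- pseudorotation(duplexform:::residue_xyz(d, "B", 4))
  expect_lt(abs(ps_c["P"] - 18), 5)
  # C2'-endo request lands in the C2'-endo band
  db <- build_duplex("GCGC", sugar = c(162, 38, -100))
  P <- pseudorotation(duplexform:::residue_xyz(db, "A", 2))["P"]
  expect_gte(P, 144)
  expect_lte(P, 180)
})

test_that("parameter list length mismatches are rejected", {
  expect_error(build_duplex("GCGC", step_params = matrix(0, 5, 6)),
               "expected 3 x 6")
  expect_error(build_duplex("GCGC", pair_params = matrix(0, 3, 6)),
               "expected 4 x 6")
  expect_error(build_duplex("GCXC"), "sequence")
})

test_that("ensemble sampling is reproducible and honours the requested
           fluctuations", {
  spec <- ensemble_spec(40, seed = 5, rho = 0)
  ens1 <- sample_ensemble(list(sequence = "GCATAT"), spec)
  ens2 <- sample_ensemble(list(sequence = "GCATAT"), spec)
  expect_identical(ens1$xyz, ens2$xyz)  # bit-for-bit under a fixed seed
  tr <- attr(ens1, "truth")
  expect_equal(dim(tr$step), c(40, 5, 6))
})

test_that("adjacent-twist coupling is recovered from sampled parameters", {
  spec0 <- ensemble_spec(2000, seed = 8, rho = 0)
  tw0 <- attr(sample_ensemble(list(sequence = "GCGCAT"), spec0),
              "truth")$step[, , "twist"]
  r0 <- stats::cor(as.numeric(tw0[, -5]), as.numeric(tw0[, -1]))
  expect_lt(abs(r0), 0.05)
  spec5 <- ensemble_spec(2000, seed = 9, rho = -0.5)
  ens5 <- sample_ensemble(list(sequence = "GCGCAT"), spec5)
  tw5 <- attr(ens5, "truth")$step[, , "twist"]
  r5 <- stats::cor(as.numeric(tw5[, -5]), as.numeric(tw5[, -1]))
  expect_lt(abs(r5 - (-0.5)), 0.05)
  # sample means converge to the spec means (within 3 standard errors)
  m <- mean(tw5)
  se <- stats::sd(tw5) / sqrt(length(tw5))
  expect_lt(abs(m - 36), 3 * se + 1e-12)
  # extraction reproduces the sampled parameters on a slice of frames
  idx <- 1:20
  sl <- duplexform:::new_dna_ensemble(ens5$topology,
                                      ens5$xyz[, , idx, drop = FALSE],
                                      ens5$times[idx])
  ts <- parameter_timeseries(sl)
  expect_equal_tol(ts$step[, , "twist"], tw5[idx, ], 1e-6)
  expect_lt(abs(adjacent_step_correlation(ts) -
                  stats::cor(as.numeric(tw5[idx, -5]),
                             as.numeric(tw5[idx, -1]))), 1e-9)
})

test_that("an unsatisfiable twist coupling is rejected", {
  expect_error(ensemble_spec(10, seed = 1, rho = 1.2))
  spec <- ensemble_spec(5, seed = 1, rho = -0.95)
  expect_error(sample_ensemble(list(sequence = apt_sequence), spec),
               "non-positive-definite")
})

test_that("probe atoms land at the requested distance and far probes make
           no contacts", {
  d <- build_duplex(apt_sequence)
  probe <- data.frame(elety = "NE1", resid = "TRP", resno = 109,
                      target_chain = "A", target_resno = 6,
                      target_elety = "C1'", distance = 4)
  cx <- build_probe_complex(d, probe)
  ne1 <- as.numeric(cx$atoms[cx$atoms$elety == "NE1", c("x", "y", "z")])
  c1 <- duplexform:::residue_xyz(d, "A", 6, "C1'")[1, ]
  expect_equal(sqrt(sum((ne1 - c1)^2)), 4, tolerance = 1e-9)
  far <- probe
  far$distance <- 40
  expect_equal(trp_sugar_contacts(build_probe_complex(d, far)), 0)
  bad <- probe
  bad$distance <- -1
  expect_error(build_probe_complex(d, bad), "infeasible")
})
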