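test_that("dihedral reproduces planar and transformed reference angles", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1)),
               180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)), 0)
  set.seed(4)
  for (k in 1:20) {
    pts <- matrix(stats::rnorm(12), 4, 3)
    a0 <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                   error = function(e) NULL)
    if (is.null(a0)) next
    R <- random_rotation()
    t <- stats::runif(3, -5, 5)
    ptsT <- sweep(pts %*% t(R), 2, t, "+")
    expect_lt(abs(dihedral(ptsT[1, ], ptsT[2, ], ptsT[3, ], ptsT[4, ]) - a0),
              1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("compose and decompose are exact inverses over the physical range", {
  set.seed(11)
  worst <- 0
  for (k in 1:500) {
    f1 <- random_frame()
    p <- random_params()
    comp <- compose_frames(f1, p)
    dec <- duplexform:::frames_to_params(f1, comp$f2)
    err <- max(abs(c(dec$rot, dec$trans) - p))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-9)
})

test_that("a pure 36 degree z-rotation with 3.38 A rise gives canonical B
           step parameters", {
  f1 <- duplexform:::new_frame()
  f2 <- duplexform:::new_frame(duplexform:::rot_z(duplexform:::deg2rad(36)),
                               c(0, 0, 3.38))
  p <- step_parameters(f1, f2)$params
  expect_equal_tol(p, c(0, 0, 36, 0, 0, 3.38), 1e-12)
})

test_that("identical coincident frames give all-zero pair parameters", {
  f <- random_frame()
  fc <- duplexform:::flip_frame(f)  # so that flipping it back matches f
  p <- pair_parameters(f, fc)$params
  expect_equal_tol(p, rep(0, 6), 1e-9)
})

test_that("strand swap negates buckle and shear only", {
  set.seed(21)
  for (k in 1:20) {
    fw <- random_frame()
    fc <- duplexform:::new_frame(random_rotation() %*% diag(c(1, -1, -1)),
                                 fw$o + stats::runif(3, -0.5, 0.5))
    p1 <- pair_parameters(fw, fc)$params
    p2 <- pair_parameters(fc, fw)$params
    expect_equal_tol(p2[c("buckle", "shear")], -p1[c("buckle", "shear")],
                     1e-9)
    expect_equal_tol(p2[c("propeller", "opening", "stretch", "stagger")],
                     p1[c("propeller", "opening", "stretch", "stagger")],
                     1e-9)
  }
})

test_that("all twelve parameters are invariant under global rigid motion", {
  set.seed(31)
  d <- build_duplex(apt_sequence,
                    step_params = c(2, 5, 34, 0.3, -0.8, 3.3),
                    pair_params = c(4, -12, 2, 0.2, 0.05, 0.1))
  rb <- rigid_base_parameters(d)
  dT <- rigid_transform(d, random_rotation(), stats::runif(3, -20, 20))
  rbT <- rigid_base_parameters(dT)
  expect_equal_tol(as.matrix(rbT$step[, -1]), as.matrix(rb$step[, -1]),
                   1e-9)
  expect_equal_tol(as.matrix(rbT$pair[, -1]), as.matrix(rb$pair[, -1]),
                   1e-9)
})

test_that("near-antiparallel frames raise a degenerate-hinge error", {
  f1 <- duplexform:::new_frame()
  f2 <- duplexform:::new_frame(
    duplexform:::rot_y(duplexform:::deg2rad(179.5)), c(0, 0, 1))
  expect_error(step_parameters(f1, f2), "degenerate")
})

test_that("fit_base_frame recovers an exactly placed standard base", {
  set.seed(41)
  for (base in c("A", "C", "G", "T")) {
    f <- random_frame()
    std <- duplexform:::std_base_coords[[base]]
    placed <- sweep(std %*% t(f$R), 2, f$o, "+")
    fit <- fit_base_frame(placed, base = base)
    expect_equal_tol(fit$R, f$R, 1e-9)
    expect_equal_tol(fit$o, f$o, 1e-9)
    expect_lt(attr(fit, "rmsd"), 1e-9)
  }
})

test_that("frame fitting tolerates small coordinate noise (orientation
           within 1 degree)", {
  set.seed(51)
  angs <- vapply(1:50, function(k) {
    f <- random_frame()
    std <- duplexform:::std_base_coords[["G"]]
    placed <- sweep(std %*% t(f$R), 2, f$o, "+") +
      matrix(stats::rnorm(length(std), 0, 0.05), nrow(std), 3)
    fit <- fit_base_frame(placed, base = "G")
    rel <- t(fit$R) %*% f$R
    acos(duplexform:::clamp1((sum(diag(rel)) - 1) / 2)) * 180 / pi
  }, numeric(1))
  # the two out-of-plane axes are the weakly constrained ones: per axis the
  # angular error is ~ sigma / sqrt(sum of squared in-plane radii) ~ 0.6
  # degrees for a guanine ring, so ~1.2 degrees total in expectation
  expect_lt(mean(angs), 1.5)
  expect_lt(stats::median(angs), 1.2)
})

test_that("parameter time series over a zero-fluctuation ensemble has zero
           SD and the spec mean", {
  spec <- ensemble_spec(3, seed = 1, step_sd = rep(0, 6),
                        pair_sd = rep(0, 6))
  ens <- sample_ensemble(list(sequence = "GCGCAT",
                              step = c(0, 0, 33.4, 0, 0, 3.38)), spec)
  ts <- parameter_timeseries(ens)
  expect_equal(dim(ts$step)[1], 3)
  sm <- ts$summary[ts$summary$kind == "step" &
                     ts$summary$parameter == "twist", ]
  expect_equal_tol(sm$mean, rep(33.4, 5), 1e-6)
  expect_equal_tol(sm$sd, rep(0, 5), 1e-9)
  # identical frames under zero SDs
  expect_equal(ens$xyz[, , 1], ens$xyz[, , 2])
})
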