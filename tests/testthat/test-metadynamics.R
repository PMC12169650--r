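test_that("hill files round trip through the PLUMED dialect", {
  gen <- generate_hills(make_potential("flat"), duration_ns = 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hills(gen$hills, path)
  back <- read_hills(path)
  expect_equal(back$time_ps, gen$hills$time_ps)
  expect_equal(back$cv_rad, gen$hills$cv_rad, tolerance = 1e-12)
  expect_equal(back$sigma_rad, gen$hills$sigma_rad)
  expect_equal(back$height, gen$hills$height)
})

test_that("biasfactor columns are parsed but flagged unsupported; empty
           and malformed files behave as documented", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#! FIELDS time twist sigma_twist height biasf",
               "4.0 0.5 0.04 0.1 10.0",
               "8.0 0.6 0.04 0.1 10.0"), path)
  expect_warning(h <- read_hills(path), "well-tempered")
  expect_equal(nrow(h), 2)
  writeLines("#! FIELDS time twist sigma_twist height biasf", path)
  expect_equal(nrow(read_hills(path)), 0)
  writeLines(c("#! FIELDS time twist sigma_twist height biasf",
               "8.0 0.5 0.04 0.1 1", "4.0 0.6 0.04 0.1 1"), path)
  expect_error(read_hills(path), "non-monotone time at data line 2")
  writeLines(c("4.0 0.5 0.04 0.1"), path)
  expect_error(read_hills(path), "FIELDS")
})

test_that("zero-duration runs give an empty record list", {
  gen <- generate_hills(make_potential("flat"), duration_ns = 0, seed = 1)
  expect_equal(nrow(gen$hills), 0)
})

test_that("reconstruction is the negative Gaussian sum", {
  g <- seq(10, 60, by = 0.25)
  h1 <- data.frame(time_ps = 4, cv_rad = duplexform:::deg2rad(35),
                   sigma_rad = 0.04, height = 0.1)
  f1 <- reconstruct_fes(h1, grid = 35, align = FALSE)
  expect_equal(f1$F_kJmol, -0.1)  # a single hill of the deposited height
  h2 <- rbind(h1, h1)
  f2 <- reconstruct_fes(h2, grid = g, align = FALSE)
  expect_equal(min(f2$F_kJmol), -0.2, tolerance = 1e-12)
  expect_equal(g[which.min(f2$F_kJmol)], 35)
  expect_error(reconstruct_fes(h1, grid = c(5, 35)), "boundaries")
})

test_that("reconstruction matches a direct-summation oracle on random
           hills", {
  set.seed(23)
  n <- 2000
  hills <- data.frame(time_ps = seq_len(n) * 4,
                      cv_rad = stats::runif(n, duplexform:::deg2rad(10),
                                            duplexform:::deg2rad(60)),
                      sigma_rad = stats::runif(n, 0.03, 0.05),
                      height = stats::runif(n, 0.05, 0.2))
  g <- seq(10, 60, by = 0.5)
  fes <- reconstruct_fes(hills, g, align = FALSE)
  oracle <- vapply(g, function(s)
    -sum(hills$height * exp(-(duplexform:::deg2rad(s) - hills$cv_rad)^2 /
                              (2 * hills$sigma_rad^2))), numeric(1))
  expect_lt(max(abs(fes$F_kJmol - oracle)), 1e-12)
})

test_that("windowed averaging min-aligns sub-profiles; a single
           sub-profile has zero SD", {
  gen <- generate_hills(make_potential("harmonic", s0 = 35, k = 0.05),
                        duration_ns = 6, seed = 3)
  one <- windowed_profiles(gen$hills, every_ns = 2, window = c(5, 5))
  expect_equal(one$n_subprofiles, 1)
  expect_equal(max(one$profile$F_sd), 0)
  expect_equal(min(one$profile$F_kJmol), 0)
  # mean of identical min-aligned profiles is the profile itself
  rep3 <- windowed_profiles(gen$hills, every_ns = 2, window = c(6, 6))
  expect_equal(rep3$profile$F_kJmol,
               reconstruct_fes(gen$hills)$F_kJmol, tolerance = 1e-9)
  expect_error(windowed_profiles(gen$hills, window = c(10, 50)),
               "50 ns")
})

test_that("minimum and valley width follow the closed form on a quadratic
           profile; flat profiles are flagged", {
  g <- seq(10, 60, by = 0.05)
  k <- 0.3
  prof <- data.frame(twist_deg = g, F_kJmol = 0.5 * k * (g - 34)^2)
  mw <- fes_minimum_and_width(prof, level = 2.494)
  expect_equal(mw[["s_min"]], 34)
  expect_equal(mw[["width"]], 2 * sqrt(2 * 2.494 / k), tolerance = 1e-3)
  expect_false(attr(mw, "flagged"))
  flat <- data.frame(twist_deg = g, F_kJmol = rep(0, length(g)))
  mwf <- fes_minimum_and_width(flat)
  expect_true(attr(mwf, "flagged"))
  expect_equal(mwf[["width"]], 50)
})

test_that("free-diffusion diagnostics count traversals and coverage", {
  sweep_up <- data.frame(time_ps = seq(0, 4000, by = 40),
                         twist_deg = seq(10, 60, length.out = 101))
  fd <- free_diffusion_check(sweep_up)
  expect_equal(fd$n_traversals, 1)
  expect_true(fd$pass)
  confined <- data.frame(time_ps = seq(0, 4000, by = 40),
                         twist_deg = seq(10, 35, length.out = 101))
  fdc <- free_diffusion_check(confined)
  expect_equal(fdc$coverage, 0.5)
  expect_equal(fdc$n_traversals, 0)
  expect_false(fdc$pass)
  expect_error(free_diffusion_check(sweep_up[0, ]), "empty")
})

test_that("flat-potential walkers reach free diffusion before 10 ns at
           default parameters", {
  for (seed in 1:5) {
    gen <- generate_hills(make_potential("flat"), duration_ns = 11,
                          seed = seed)
    fd <- free_diffusion_check(gen$cv)
    expect_true(fd$pass)
  }
})

test_that("long flat-potential runs accumulate an approximately flat bias
           away from the boundary taper", {
  gen <- generate_hills(make_potential("flat"), duration_ns = 160, seed = 5)
  wp <- windowed_profiles(gen$hills, window = c(10, 150))
  int <- wp$profile[wp$profile$twist_deg >= 20 & wp$profile$twist_deg <= 50, ]
  expect_lt(max(int$F_kJmol) - min(int$F_kJmol), 0.3)  # 3 x hill height
  expect_lt(mean(int$F_sd), 2.494)  # SD small relative to kT
})

test_that("the pruning rule reproduces the three canonical pairing
           histories", {
  nfr <- 100
  intact <- matrix(TRUE, nfr, 4)
  expect_true(prune_opened(intact)$include)
  two_open <- intact
  two_open[40:nfr, 2] <- FALSE   # opens and never recovers
  two_open[40:nfr, 3] <- FALSE
  res <- prune_opened(two_open)
  expect_false(res$include)
  expect_equal(res$n_unrecovered, 2)
  recovered <- intact
  recovered[40:60, 2] <- FALSE   # opens, then re-pairs
  expect_true(prune_opened(recovered)$include)
  # one unrecovered pair alone is not enough to prune
  one_open <- intact
  one_open[40:nfr, 2] <- FALSE
  expect_true(prune_opened(one_open)$include)
  # decision is order-independent across pairs
  expect_equal(prune_opened(two_open[, 4:1])$include,
               prune_opened(two_open)$include)
})

test_that("base-pair opening is detected from Watson-Crick heavy-atom
           distances", {
  d <- build_duplex("GCGCAT")
  expect_true(all(base_pair_intact(d)))
  # pull the Watson base of pair 3 far away
  sel <- d$atoms$chain == "A" & d$atoms$resno == 3
  d$atoms$x[sel] <- d$atoms$x[sel] + 20
  intact <- base_pair_intact(d)
  expect_false(intact[3])
  expect_true(all(intact[-3]))
})
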