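test_that("contact counting is a strict-cutoff pair count, symmetric in
           its arguments", {
  d <- build_duplex("GCGC")
  near <- data.frame(elety = "NE1", resid = "TRP", resno = 109,
                     target_chain = "A", target_resno = 2,
                     target_elety = "C1'", distance = 4.4)
  far <- near
  far$distance <- 4.6
  cx_near <- build_probe_complex(d, near)
  cx_far <- build_probe_complex(d, far)
  ga <- list(chain = "P")
  gb <- list(chain = "A", resno = 2, elety = "C1'")
  expect_equal(count_contacts(cx_near, ga, gb, cutoff = 4.5), 1)
  expect_equal(count_contacts(cx_far, ga, gb, cutoff = 4.5), 0)
  expect_equal(count_contacts(cx_near, gb, ga, cutoff = 4.5),
               count_contacts(cx_near, ga, gb, cutoff = 4.5))
  expect_error(count_contacts(cx_near, list(chain = "Z"), gb), "group_a")
})

test_that("counts equal the all-pairs brute-force oracle on planted
           fixtures", {
  d <- build_duplex(apt_sequence)
  at <- d$atoms
  acc <- duplexform:::minor_acceptor_indices(at)
  # plant QGR pseudo-atoms near distinct minor-groove acceptors
  targets <- at[acc[seq(2, 20, by = 2)], ]
  probe <- data.frame(elety = paste0("Q", seq_len(nrow(targets))),
                      resid = "ARG", resno = 114,
                      target_chain = targets$chain,
                      target_resno = targets$resno,
                      target_elety = targets$elety,
                      distance = 3.5)
  cx <- build_probe_complex(d, probe)
  catoms <- cx$atoms
  xa <- as.matrix(catoms[catoms$chain == "P", c("x", "y", "z")])
  xb <- as.matrix(catoms[duplexform:::minor_acceptor_indices(catoms),
                         c("x", "y", "z")])
  oracle <- brute_force_contacts(xa, xb, 4.5)
  expect_gte(oracle, nrow(targets))  # every planted probe contributes
  expect_equal(qgr_minor_contacts(cx), oracle)
})

test_that("the bound-state rule separates planted bound and unbound
           fixtures", {
  d <- build_duplex(apt_sequence)
  at <- d$atoms
  acc <- duplexform:::minor_acceptor_indices(at)
  targets <- at[acc[3:22], ]
  bound_spec <- rbind(
    data.frame(elety = paste0("Q", 1:20), resid = "ARG", resno = 114,
               target_chain = targets$chain, target_resno = targets$resno,
               target_elety = targets$elety, distance = 3.0),
    data.frame(elety = "NE1", resid = "TRP", resno = 109,
               target_chain = "A", target_resno = 6,
               target_elety = "C2'", distance = 3.2))
  unbound_spec <- bound_spec
  unbound_spec$distance <- 25
  cx_b <- build_probe_complex(d, bound_spec)
  cx_u <- build_probe_complex(d, unbound_spec)
  qb <- qgr_minor_contacts(cx_b)
  tb <- trp_sugar_contacts(cx_b)
  expect_gt(qb, 25)
  expect_gte(tb, 2)
  expect_true(is_bound_state(qb, tb))
  qu <- qgr_minor_contacts(cx_u)
  tu <- trp_sugar_contacts(cx_u)
  expect_equal(qu, 0)
  expect_equal(tu, 0)
  expect_false(is_bound_state(qu, tu))
  # threshold is strict: 26 is bound, 25 is not
  expect_true(is_bound_state(26, 2))
  expect_false(is_bound_state(25, 2))
  expect_false(is_bound_state(26, 1))
})

test_that("missing probe residues or atoms raise informative errors", {
  d <- build_duplex("GCGC")
  expect_error(qgr_minor_contacts(d), "QGR")
  expect_error(trp_sugar_contacts(d), "NE1")
})

test_that("2D contact densities are exact multinomial frequencies", {
  s1 <- data.frame(c_minor_qgr = 7, c_sugar_trp = 2)
  d1 <- contact_density_2d(s1)
  expect_equal(sum(d1$density), 1)
  expect_equal(as.numeric(d1$density), 1)
  s2 <- data.frame(c_minor_qgr = c(7, 30), c_sugar_trp = c(0, 3))
  d2 <- contact_density_2d(s2)
  expect_equal(sum(d2$density), 1)
  expect_equal(sort(as.numeric(d2$density[d2$density > 0])), c(0.5, 0.5))
  set.seed(19)
  q <- sample(24:28, 60, replace = TRUE)
  tr <- sample(0:3, 60, replace = TRUE)
  dd <- contact_density_2d(data.frame(c_minor_qgr = q, c_sugar_trp = tr))
  expect_equal(sum(dd$density), 1)
  for (qq in unique(q)) for (tt in unique(tr)) {
    expect_equal(dd$density[as.character(qq), as.character(tt)],
                 mean(q == qq & tr == tt))
  }
})

test_that("contact series over an ensemble classifies every frame", {
  d <- build_duplex(apt_sequence)
  probe <- data.frame(elety = c("NE1", "QG1"), resid = c("TRP", "GLN"),
                      resno = c(109, 112),
                      target_chain = "A", target_resno = c(6, 6),
                      target_elety = c("C2'", "O4'"), distance = 3.5)
  cx <- build_probe_complex(d, probe)
  ens <- ensemble_from_structures(list(cx, cx))
  cs <- contact_series(ens)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$c_minor_qgr[1], cs$c_minor_qgr[2])
  expect_type(cs$bound, "logical")
})
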