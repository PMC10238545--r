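# Synthetic-data generators: determinism, construction guarantees,
# and statistical self-consistency.

test_that("structure generation is a pure function of its seed", {
  a <- make_two_state_structures(n_residues = 40,
                                 segments = list(c(20, 30)), seed = 9)
  b <- make_two_state_structures(n_residues = 40,
                                 segments = list(c(20, 30)), seed = 9)
  expect_identical(a, b)
  c <- make_two_state_structures(n_residues = 40,
                                 segments = list(c(20, 30)), seed = 10)
  expect_false(identical(a$minor$atoms, c$minor$atoms))
})

test_that("zero displacement request returns the ground state unchanged", {
  st <- make_two_state_structures(n_residues = 40,
                                  segments = list(c(20, 30)),
                                  max_displacement = 0, seed = 2)
  expect_identical(st$ground$atoms, st$minor$atoms)
  expect_equal(max(st$displacement), 0)
})

test_that("requests beyond the cap or sequence are rejected", {
  expect_error(make_two_state_structures(max_displacement = 3.5),
               "cap")
  expect_error(make_two_state_structures(n_residues = 40,
                                         segments = list(c(30, 45))),
               "sequence")
})

test_that("default truth displaces locally, within bounds, chemically regular", {
  tr <- fix_truth166()
  d <- tr$displacement
  expect_gt(max(d), 1.0)
  expect_lt(max(d), 3.0)
  # localized: displaced residues confined to the two target segments
  # plus their blending flanks
  big <- as.integer(names(d))[d > 0.5]
  expect_true(all(big >= 99 & big <= 146))
  expect_gt(sum(d < 0.1), 100)
  # bond-class distances within 1% of the ground geometry
  a <- tr$ground$atoms
  X0 <- as.matrix(a[c("x", "y", "z")])
  Xm <- as.matrix(tr$minor$atoms[c("x", "y", "z")])
  pr <- exstate:::.elastic_pairs(a$resno, a$atom, X0)
  bonds <- pr[pr$k == 200, ]
  dist_m <- sqrt(rowSums((Xm[bonds$i, ] - Xm[bonds$j, ])^2))
  expect_lt(max(abs(dist_m - bonds$d0) / bonds$d0), 0.01)
})

test_that("generated structures pass the same validation as parsed files", {
  tr <- fix_truth60()
  expect_s3_class(structure_model(tr$ground$atoms), "structure_model")
  expect_s3_class(structure_model(tr$minor$atoms), "structure_model")
})

test_that("noise-free one-state RDCs are reproduced exactly by the forward model", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, noise = 0, weights = c(0.7, 0.3),
                           completeness = 1)
  ens <- ensemble_model(list(tr$ground, tr$minor), c(0.7, 0.3))
  for (m in c("pf1", "bicelles")) {
    pred <- ensemble_rdc(ens, tr$tensors[[m]])
    mm <- merge(tab[tab$medium == m, ], pred, by = c("residue", "type"))
    expect_lt(max(abs(mm$value.x - mm$value.y)), 1e-9)
  }
  # switch-region residues are dropped (exchange broadening)
  expect_false(any(tab$residue %in% region_residues(tr$switch_regions)))
})

test_that("stated noise levels give unit reduced chi-square", {
  tr <- fix_truth60()
  ens <- ensemble_model(list(tr$ground, tr$minor), c(0.7, 0.3))
  redchi <- vapply(1:10, function(s) {
    tab <- simulate_rdc_sets(tr, completeness = 1, seed = 5000 + s)
    tot <- 0; n <- 0
    for (m in c("pf1", "bicelles")) {
      pred <- ensemble_rdc(ens, tr$tensors[[m]])
      mm <- merge(tab[tab$medium == m, ], pred,
                  by = c("residue", "type"))
      tot <- tot + sum(((mm$value.x - mm$value.y) / mm$error)^2)
      n <- n + nrow(mm)
    }
    tot / n
  }, numeric(1))
  expect_equal(mean(redchi), 1.0, tolerance = 0.2)
})

test_that("dispersion simulation is deterministic and Arrhenius-consistent", {
  tr <- fix_truth60()
  d1 <- simulate_dispersion(tr)
  d2 <- simulate_dispersion(tr)
  expect_identical(d1, d2)
  expect_equal(sort(unique(d1$temperature)),
               c(293.15, 298.15, 303.15))
  # repeated 100/400/1000 Hz points present as replicates
  expect_equal(sort(unique(d1$nu_cpmg[d1$rep == 2])),
               c(100, 400, 1000))
  # zero shift difference yields flat noise-free profiles
  tr0 <- tr
  tr0$exchange$dw_ppm[] <- 0
  d0 <- simulate_dispersion(tr0, noise = 0)
  for (r in unique(d0$residue)) {
    prof <- d0[d0$residue == r & d0$temperature == 298.15, ]
    expect_lt(diff(range(prof$r2eff)), 1e-9)
  }
})

test_that("spectrum series coalesces on warming and quantifies populations", {
  tr <- fix_truth60()
  sps <- simulate_spectrum_series(tr)
  n_peaks <- vapply(sps, function(sp) {
    y <- sp$intensity
    sum(diff(sign(diff(y))) == -2 & y[2:(length(y) - 1)] >
          0.05 * max(y))
  }, integer(1))
  expect_equal(n_peaks[[1]], 2L)               # cold: resolved states
  expect_equal(n_peaks[[length(sps)]], 1L)     # warm: single average
  # areas at the lowest temperature recover the populations
  fit <- fit_lorentzian_pair(sps[[1]])
  frac <- fit$peaks$area[2] / sum(fit$peaks$area)
  pb_cold <- exstate:::.truth_rates(tr, attr(sps[[1]],
                                             "temperature"))$pb
  expect_equal(frac, pb_cold, tolerance = 0.02)
  expect_identical(simulate_spectrum_series(tr)[[1]]$intensity,
                   sps[[1]]$intensity)
})

test_that("the anisotropic subset drops near-axis orientations only", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, weights = c(1, 0), completeness = 1)
  sub <- anisotropic_rdc_subset(tr, tab, cone = 0.75)
  expect_true(all(sub$type %in% c("NH", "CAHA")))
  expect_lt(nrow(sub), nrow(tab[tab$medium == "pf1" &
                                  tab$type %in% c("NH", "CAHA"), ]))
  bv <- build_bond_vectors(tr$ground, c("NH", "CAHA"))
  z <- tr$tensors$pf1$eigenvectors[, 3]
  ct <- abs(as.matrix(bv[c("vx", "vy", "vz")]) %*% z)[, 1]
  keyed <- setNames(ct, paste(bv$residue, bv$type))
  expect_true(all(keyed[paste(sub$residue, sub$type)] < 0.75))
})
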