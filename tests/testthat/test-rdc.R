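# Bond-vector construction, Saupe tensor fitting, quality factors,
# sparsity correction and ensemble back-calculation.

test_that("bond vectors are unit norm and built with ideal geometry", {
  st <- fix_truth60()$ground
  bv <- build_bond_vectors(st)
  expect_equal(sqrt(bv$vx^2 + bv$vy^2 + bv$vz^2),
               rep(1, nrow(bv)), tolerance = 1e-9)
  # constructed amide H sits on the external bisector: equal angles to
  # CA and to the preceding carbonyl, 1.02 A from N
  res <- 10
  a <- st$atoms
  xyz <- function(r, at) unlist(a[a$resno == r & a$atom == at,
                                  c("x", "y", "z")])
  v <- bv[bv$type == "NH" & bv$residue == res, c("vx", "vy", "vz")]
  H <- xyz(res, "N") + 1.02 * unlist(v)
  ang <- function(p, q, r) {
    u <- p - q; w <- r - q
    acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
  }
  a1 <- ang(H, xyz(res, "N"), xyz(res, "CA"))
  a2 <- ang(H, xyz(res, "N"), xyz(res - 1, "C"))
  expect_equal(a1, a2, tolerance = 1e-6)
  expect_gt(a1, 110)
})

test_that("prolines carry no N-H vector and glycines no CA-HA vector", {
  st <- fix_truth60()$ground
  st$atoms$resname[st$atoms$resno == 20] <- "PRO"
  gly <- st$atoms$resno == 25
  st$atoms$resname[gly] <- "GLY"
  st$atoms <- st$atoms[!(gly & st$atoms$atom == "CB"), ]
  bv <- build_bond_vectors(st)
  expect_false(20 %in% bv$residue[bv$type == "NH"])
  expect_false(20 %in% bv$residue[bv$type == "HNC"])
  expect_false(25 %in% bv$residue[bv$type == "CAHA"])
  expect_true(25 %in% bv$residue[bv$type == "NH"])
})

test_that("back-calculation matches closed forms and the matrix oracle", {
  tn <- tensor_from_params(da = 10, rhombicity = 0)
  vz <- data.frame(residue = 1, type = "NH", vx = 0, vy = 0, vz = 1,
                   scale = 1)
  expect_equal(back_calc_rdc(vz, tn), 20, tolerance = 1e-10)
  magic <- 54.7356103 * pi / 180
  vm <- data.frame(residue = 1, type = "NH", vx = sin(magic), vy = 0,
                   vz = cos(magic), scale = 1)
  expect_equal(back_calc_rdc(vm, tn), 0, tolerance = 1e-6)
  # random tensors and vectors against direct quadratic-form evaluation
  set.seed(3)
  for (i in 1:5) {
    s5 <- rnorm(5)
    tn2 <- alignment_tensor(s5)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    vv <- data.frame(residue = 1, type = "CAHA", vx = v[1], vy = v[2],
                     vz = v[3], scale = rdc_type_scale("CAHA"))
    S <- matrix(c(s5[1], s5[3], s5[4], s5[3], s5[2], s5[5],
                  s5[4], s5[5], -s5[1] - s5[2]), 3, 3)
    expect_equal(back_calc_rdc(vv, tn2),
                 rdc_type_scale("CAHA") * drop(t(v) %*% S %*% v),
                 tolerance = 1e-12)
  }
})

test_that("tensor derivations respect conventions", {
  R <- exstate:::.rot_axis(c(1, 1, 0), 0.8)
  tn <- tensor_from_params(da = -12, rhombicity = 0.45, rotation = R)
  expect_equal(sum(diag(tn$matrix)), 0, tolerance = 1e-12)
  expect_equal(tn$da, -12, tolerance = 1e-9)
  expect_equal(tn$rhombicity, 0.45, tolerance = 1e-9)
  ev <- abs(tn$eigenvalues)
  expect_true(ev[1] <= ev[2] && ev[2] <= ev[3])
  expect_error(tensor_from_params(10, 0.8), "rhombicity")
})

test_that("SVD fit recovers a known tensor exactly and is rotation invariant", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, noise = 0, weights = c(1, 0),
                           completeness = 1)
  pf1 <- tab[tab$medium == "pf1", ]
  bv <- build_bond_vectors(tr$ground)
  fit <- svd_fit_tensor(bv, pf1)
  expect_equal(fit$tensor$da, tr$tensors$pf1$da, tolerance = 1e-8)
  expect_equal(fit$tensor$rhombicity, tr$tensors$pf1$rhombicity,
               tolerance = 1e-8)
  expect_equal(fit$quality$q, 0, tolerance = 1e-7)
  expect_equal(sum(diag(fit$tensor$matrix)), 0, tolerance = 1e-12)

  # rotating the structure does not change Da or rhombicity
  rot <- exstate:::.rot_axis(c(1, 2, 3), 0.7)
  st2 <- tr$ground
  st2$atoms[c("x", "y", "z")] <-
    as.matrix(st2$atoms[c("x", "y", "z")]) %*% t(rot)
  fit2 <- svd_fit_tensor(build_bond_vectors(st2), pf1)
  expect_equal(fit2$tensor$da, fit$tensor$da, tolerance = 1e-9)
  expect_equal(fit2$tensor$rhombicity, fit$tensor$rhombicity,
               tolerance = 1e-9)
})

test_that("SVD solution is the weighted least-squares optimum", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, weights = c(1, 0), completeness = 1)
  pf1 <- tab[tab$medium == "pf1" & tab$type == "NH", ]
  bv <- build_bond_vectors(tr$ground, "NH")
  fit <- svd_fit_tensor(bv, pf1)
  chi2 <- function(s5) {
    tn <- alignment_tensor(s5)
    m <- merge(bv, pf1, by = c("residue", "type"))
    sum(((m$value - back_calc_rdc(m, tn)) / m$error)^2)
  }
  base <- chi2(fit$tensor$s5)
  set.seed(8)
  for (i in 1:20)
    expect_gte(chi2(fit$tensor$s5 + rnorm(5, 0, 0.2)), base)
})

test_that("rank-deficient orientation sampling is rejected", {
  bv <- data.frame(residue = 1:6, type = "NH", vx = 1, vy = 0, vz = 0,
                   scale = 1)
  obs <- data.frame(residue = 1:6, type = "NH", medium = "m",
                    value = 1, error = 0.5)
  expect_error(svd_fit_tensor(bv, obs), "degenerate|rank")
})

test_that("quality factors follow their definitions", {
  q0 <- quality_factors(c(1, 2, 3), c(1, 2, 3), da = 10,
                        rhombicity = 0.2)
  expect_equal(q0$rmsd, 0); expect_equal(q0$q, 0); expect_equal(q0$r, 0)
  q1 <- quality_factors(c(1, 2, 3), c(0, 0, 0), 10, 0.2)
  expect_equal(q1$q, 1)
  # five-point worked example, every factor from its printed formula
  obs <- c(4.0, -2.5, 7.2, 0.5, -6.1)
  calc <- c(3.2, -2.0, 8.0, 1.5, -5.0)
  qf <- quality_factors(obs, calc, da = 8, rhombicity = 0.3)
  rmsd <- sqrt(mean((obs - calc)^2))
  expect_equal(qf$rmsd, rmsd)
  expect_equal(qf$q, rmsd / sqrt(mean(obs^2)))
  expect_equal(qf$r, rmsd / sqrt(2 * 64 * (4 + 3 * 0.09) / 5))
  expect_error(quality_factors(numeric(0), numeric(0), 1, 0), "empty")
})

test_that("densely sampled data needs no magnitude correction", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, weights = c(1, 0), completeness = 1)
  ct <- correct_tensor_magnitude(tr$ground,
                                 tab[tab$medium == "pf1", ])
  expect_lt(abs(ct$scale - 1), 0.02 + 1e-9)
})

test_that("sparse anisotropic data against an imperfect reference is corrected upward", {
  tr <- fix_truth166()
  tab <- simulate_rdc_sets(tr, weights = c(1, 0), completeness = 1)
  sub <- anisotropic_rdc_subset(tr, tab)
  ref <- perturb_structure(tr$ground, 0.08, seed = 105)
  ct <- suppressWarnings(correct_tensor_magnitude(ref, sub))
  da_true <- abs(tr$tensors$pf1$da)
  da_svd <- mean(abs(vapply(ct$svd_fits,
                            function(f) f$tensor$da, 1)))
  da_cor <- mean(abs(vapply(ct$tensors, function(t) t$da, 1)))
  expect_lt(da_svd, da_true)            # SVD underestimates
  expect_gt(ct$scale, 1)                # correction is upward
  expect_lt(abs(da_cor - da_true), abs(da_svd - da_true))
})

test_that("magnitude correction validates its inputs", {
  tr <- fix_truth60()
  tab <- simulate_rdc_sets(tr, completeness = 1)
  expect_error(correct_tensor_magnitude(tr$ground, tab),
               "single alignment medium")
  one <- tab[tab$medium == "pf1" & tab$type == "NH", ]
  expect_error(correct_tensor_magnitude(tr$ground, one),
               "at least two RDC types")
})

test_that("ensemble predictions are exact weighted sums", {
  tr <- fix_truth60()
  tn <- tr$tensors$pf1
  e10 <- ensemble_model(list(tr$ground, tr$minor), c(1, 0))
  single <- back_calc_rdc(build_bond_vectors(tr$ground), tn)
  expect_equal(ensemble_rdc(e10, tn)$value, single, tolerance = 1e-12)
  edup <- ensemble_model(list(tr$ground, tr$ground), c(0.4, 0.6))
  expect_equal(ensemble_rdc(edup, tn)$value, single, tolerance = 1e-12)
  e73 <- ensemble_model(list(tr$ground, tr$minor), c(0.7, 0.3))
  oracle <- 0.7 * single +
    0.3 * back_calc_rdc(build_bond_vectors(tr$minor), tn)
  expect_equal(ensemble_rdc(e73, tn)$value, oracle, tolerance = 1e-12)
  expect_error(ensemble_model(list(tr$ground, tr$minor), c(0.7, 0.31)),
               "sum to 1")
})
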