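# Two-site exchange forward models: exact CPMG solution, numerical
# oracle, lineshapes, rate laws.

nu6 <- c(100, 200, 400, 500, 800, 1000)

test_that("zero shift difference gives a flat population-averaged profile", {
  p <- fix_params(dw_ppm = 0, r2a = 10, r2b = 10)
  expect_equal(r2eff_exact(p, nu6), rep(10, 6), tolerance = 1e-9)
  # unequal intrinsic rates: population average up to the small
  # exchange-narrowing correction of order (dR2/kex)^2
  p2 <- fix_params(dw_ppm = 0, r2a = 10, r2b = 14)
  expect_equal(r2eff_exact(p2, nu6), rep(0.85 * 10 + 0.15 * 14, 6),
               tolerance = 1e-3)
})

test_that("absent minor state reduces to the intrinsic rate", {
  p <- fix_params(pb = 0, r2a = 9.5, r2b = 30)
  expect_equal(r2eff_exact(p, nu6), rep(9.5, 6), tolerance = 1e-9)
})

test_that("very fast exchange approaches the fast-limit closed form", {
  p <- fix_params(kex = 1e6)
  dw <- 2 * pi * 2 * larmor_mhz("13C", 700)
  fast <- 10 + 0.15 * 0.85 * dw^2 / 1e6
  expect_equal(r2eff_numeric(p, c(100, 1000)), rep(fast, 2),
               tolerance = 0.01)
  expect_equal(r2eff_exact(p, c(100, 1000)), rep(fast, 2),
               tolerance = 0.01)
})

test_that("exact solution matches stepwise Bloch-McConnell propagation", {
  set.seed(11)
  worst <- 0
  for (i in 1:30) {
    p <- two_site_params(pb = runif(1, 0.01, 0.4),
                         kex = exp(runif(1, log(100), log(6000))),
                         dw_ppm = runif(1, 0.1, 4),
                         r2a = runif(1, 5, 25), r2b = runif(1, 5, 25))
    d <- abs(r2eff_exact(p, c(100, 400, 1000)) -
               r2eff_numeric(p, c(100, 400, 1000)))
    worst <- max(worst, d)
  }
  expect_lt(worst, 0.1)
})

test_that("numerical oracle agrees with an ODE integration", {
  skip_if_not_installed("deSolve")
  p <- fix_params()
  k1 <- p$pb * p$kex; km1 <- (1 - p$pb) * p$kex
  dw <- 2 * pi * p$dw_ppm * larmor_mhz(p$nucleus, p$field_mhz)
  # real 4-vector (ReA, ImA, ReB, ImB)
  A <- matrix(c(-(p$r2a + k1), 0, k1, 0,
                0, -(p$r2a + k1), 0, k1,
                km1, 0, -(p$r2b + km1), -dw,
                0, km1, dw, -(p$r2b + km1)), 4, 4)
  for (nu in c(100, 500)) {
    n <- 0.02 * nu; tau <- 0.02 / (4 * n)
    v <- c(1 - p$pb, 0, p$pb, 0)
    prop <- function(v, t) {
      deSolve::ode(v, c(0, t), function(tt, y, par) list(A %*% y),
                   NULL, method = "lsoda", rtol = 1e-10,
                   atol = 1e-12)[2, -1]
    }
    conj4 <- function(v) c(v[1], -v[2], v[3], -v[4])
    for (j in seq_len(n))
      v <- prop(conj4(prop(conj4(prop(v, tau)), 2 * tau)), tau)
    mag <- sqrt((v[1] + v[3])^2 + (v[2] + v[4])^2)
    expect_equal(r2eff_numeric(p, nu), unname(-log(mag) / 0.02),
                 tolerance = 1e-6)
  }
})

test_that("state labels can be swapped without changing the observable", {
  kern <- exstate:::.r2eff_kernel
  n <- c(2, 8, 20)
  a <- kern(0.2, 900, 1500, 12, 18, n, 0.02)
  b <- kern(0.8, 900, 1500, 18, 12, n, 0.02)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("echo counts must be integer within tolerance", {
  p <- fix_params()
  expect_error(r2eff_exact(p, 130), "echo count")
  expect_warning(r2eff_exact(p, 100.2), "rounded")
})

test_that("intensity conversion inverts the constant-time relation", {
  expect_equal(intensities_to_r2eff(5, 5), 0)
  expect_equal(intensities_to_r2eff(exp(-0.2) * 7, 7, t_cp = 0.02), 10)
  expect_error(intensities_to_r2eff(-1, 5), "positive")
  r2 <- intensities_to_r2eff(2, 4, t_cp = 0.02, sigma_i = 0.1)
  expect_equal(attr(r2, "sigma"), 0.1 / (2 * 0.02))
})

test_that("Arrhenius law evaluates the closed form and is monotone", {
  law0 <- arrhenius_law(ea_kj = 0, prefactor = 123)
  expect_equal(arrhenius_k(law0, c(280, 300, 320)), rep(123, 3))
  law <- arrhenius_law(ea_kj = 60, prefactor = 1e12)
  expect_equal(arrhenius_k(law, 298.15),
               1e12 * exp(-60000 / (8.314 * 298.15)))
  expect_gt(arrhenius_k(law, 303.15), arrhenius_k(law, 298.15))
  lawr <- arrhenius_law(ea_kj = 45, k_ref = 800)
  expect_equal(arrhenius_k(lawr, 298.15), 800, tolerance = 1e-10)
})

test_that("dispersion is non-increasing in nu in the intermediate-to-fast regime", {
  # in deep slow exchange the exact solution genuinely oscillates with
  # the pulsing rate, so monotonicity is a property of kex >~ dw only
  set.seed(21)
  nus <- c(50, 100, 200, 400, 500, 800, 1000)
  for (i in 1:20) {
    dw_ppm <- runif(1, 0.2, 2)
    dw_rad <- 2 * pi * dw_ppm * larmor_mhz("13C", 700)
    p <- two_site_params(pb = runif(1, 0.02, 0.4),
                         kex = dw_rad * runif(1, 1, 4),
                         dw_ppm = dw_ppm, r2a = 10)
    r2 <- r2eff_exact(p, nus)
    expect_true(all(diff(r2) <= 1e-6))
  }
})

# ---- lineshapes ------------------------------------------------------

slow_grid <- function(dw) seq(-3 * dw, 4 * dw, length.out = 6000)

test_that("slow-exchange lineshape resolves peaks with areas at the populations", {
  dw <- 2000
  sp <- lineshape_1d(c(0.7, 0.3), c(0, dw), c(20, 20), kex = 40,
                     grid = slow_grid(dw))
  fit <- fit_lorentzian_pair(sp)
  frac <- fit$peaks$area[2] / sum(fit$peaks$area)
  expect_equal(frac, 0.3, tolerance = 0.01)
})

test_that("fast-exchange lineshape collapses to the weighted mean position", {
  dw <- 2000
  sp <- lineshape_1d(c(0.7, 0.3), c(0, dw), c(20, 20), kex = 2e5,
                     grid = slow_grid(dw))
  pk <- sp$omega[which.max(sp$intensity)]
  expect_equal(pk, 0.3 * dw,
               tolerance = 2 * diff(sp$omega[1:2]) / (0.3 * dw))
})

test_that("intermediate-exchange lineshape matches a time-domain oracle", {
  dw <- 1200; kex <- 1000
  grid <- seq(-2 * dw, 3 * dw, length.out = 400)
  sp <- lineshape_1d(c(0.65, 0.35), c(0, dw), c(25, 25), kex, grid)
  # time-domain free-induction decay + explicit Fourier integral
  k1 <- 0.35 * kex; km1 <- 0.65 * kex
  A <- matrix(c(complex(real = -(25 + k1)), complex(real = k1),
                complex(real = km1),
                complex(real = -(25 + km1), imaginary = dw)), 2, 2)
  dt <- 2e-5; tt <- seq(0, 0.35, by = dt)
  E <- exstate:::.expm_series(A * dt)
  v <- complex(real = c(0.65, 0.35))
  s <- complex(length(tt))
  for (i in seq_along(tt)) { s[i] <- sum(v); v <- E %*% v }
  oracle <- vapply(grid, function(w) {
    wt <- rep(dt, length(tt)); wt[1] <- dt / 2
    Re(sum(s * exp(-1i * w * tt) * wt))
  }, numeric(1))
  expect_lt(max(abs(sp$intensity - oracle)) / max(sp$intensity), 1e-3)
})

test_that("integrated intensity is conserved across exchange regimes", {
  dw <- 1500
  areas <- vapply(c(50, 1000, 50000), function(kex) {
    spectrum_area(lineshape_1d(c(0.7, 0.3), c(0, dw), c(15, 15), kex,
                               seq(-12 * dw, 13 * dw,
                                   length.out = 40000)))
  }, numeric(1))
  expect_equal(areas / pi, rep(1, 3), tolerance = 0.02)
})

test_that("lineshape validates populations and detailed balance", {
  expect_error(lineshape_1d(c(0.6, 0.3), c(0, 1), c(1, 1), 10, 0:10),
               "sum to 1")
  K <- matrix(c(-5, 5, 10, -10), 2, 2)   # violates balance for 50/50
  expect_error(lineshape_1d(c(0.5, 0.5), c(0, 1), c(1, 1), K,
                            seq(0, 1, 0.1)), "detailed balance")
})

test_that("populations follow from peak areas", {
  expect_equal(populations_from_peaks(70, 30), 0.3)
  expect_equal(populations_from_peaks(1, 0), 0)
  expect_error(populations_from_peaks(0, 0), "zero")
  expect_error(populations_from_peaks(-1, 1), ">= 0")
})
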