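# Forward models of two-site chemical exchange: exact CPMG dispersion,
# a numerical Bloch-McConnell oracle, 1D exchange lineshapes and the
# Arrhenius rate law.

# Gyromagnetic ratios, rad s^-1 T^-1
.GAMMA <- c("1H" = 267.52218744e6,
            "13C" = 67.2828e6,
            "15N" = -27.116e6,
            "31P" = 108.291e6)

#' Larmor frequency of a nucleus at a given spectrometer field
#'
#' The field is stated, as is conventional, as the 1H frequency in MHz
#' (e.g. 700).  The returned value is the absolute Larmor frequency of
#' the requested nucleus in MHz, so that a chemical-shift difference in
#' ppm multiplied by this value gives Hz.
#'
#' @param nucleus one of `"1H"`, `"13C"`, `"15N"`, `"31P"`.
#' @param field_mhz spectrometer field as the 1H frequency in MHz.
#' @return Larmor frequency in MHz (positive).
#' @export
larmor_mhz <- function(nucleus, field_mhz) {
  nucleus <- match.arg(nucleus, names(.GAMMA))
  field_mhz * abs(.GAMMA[[nucleus]] / .GAMMA[["1H"]])
}

#' Two-site exchange parameters
#'
#' Bundles the parameters of the A <-> B exchange model: minor-state
#' population `pb`, total exchange rate `kex = k1 + km1` (with
#' `k1 = pb * kex` the A -> B rate), chemical-shift difference
#' `dw_ppm` between the states, and intrinsic transverse relaxation
#' rates of the two states.  By convention the minor state is B, so
#' `pb <= 0.5`, and the sign of `dw_ppm` is not identifiable from CPMG
#' data, so it is stored non-negative.
#'
#' @param pb minor-state population fraction, in `[0, 0.5]`.
#' @param kex exchange rate `k1 + km1` in s^-1 (> 0).
#' @param dw_ppm chemical-shift difference between states, ppm (>= 0).
#' @param r2a,r2b intrinsic transverse relaxation rates (s^-1) of the
#'   major and minor states; `r2b` defaults to `r2a`.
#' @param nucleus nucleus of the observed coherence.
#' @param field_mhz spectrometer 1H field in MHz.
#' @return an object of class `"two_site_params"`.
#' @export
two_site_params <- function(pb, kex, dw_ppm, r2a, r2b = r2a,
                            nucleus = "13C", field_mhz = 700) {
  stopifnot(is.numeric(pb), length(pb) == 1L, is.finite(pb))
  if (pb < 0 || pb > 0.5)
    stop("'pb' must lie in [0, 0.5] (minor state by convention)")
  if (!is.finite(kex) || kex <= 0) stop("'kex' must be > 0")
  if (!is.finite(dw_ppm) || dw_ppm < 0)
    stop("'dw_ppm' must be >= 0 (sign not identifiable from CPMG)")
  if (r2a < 0 || r2b < 0) stop("intrinsic R2 rates must be >= 0")
  nucleus <- match.arg(nucleus, names(.GAMMA))
  structure(list(pb = pb, kex = kex, dw_ppm = dw_ppm,
                 r2a = r2a, r2b = r2b,
                 nucleus = nucleus, field_mhz = field_mhz),
            class = "two_site_params")
}

#' @export
print.two_site_params <- function(x, ...) {
  cat(sprintf(
    "Two-site exchange: pB = %.3f, kex = %.1f /s, dw = %.3f ppm (%s at %.0f MHz), R2a = %.2f, R2b = %.2f\n",
    x$pb, x$kex, x$dw_ppm, x$nucleus, x$field_mhz, x$r2a, x$r2b))
  invisible(x)
}

# Angular shift difference in rad/s for the stated nucleus and field.
.dw_rad <- function(p) 2 * pi * p$dw_ppm * larmor_mhz(p$nucleus, p$field_mhz)

# Echo count n = t_cp * nu for the constant-time CPMG element; values
# implying a non-integer count are accepted with a warning when the
# mismatch is below `tol`, otherwise rejected.
.echo_count <- function(nu_cpmg, t_cp, tol = 0.01) {
  n <- round(t_cp * nu_cpmg)
  bad <- abs(n - t_cp * nu_cpmg) >= tol
  if (any(bad))
    stop("nu_cpmg values imply a non-integer echo count: ",
         paste(nu_cpmg[bad], collapse = ", "))
  off <- !bad & abs(n - t_cp * nu_cpmg) > 1e-9
  if (any(off))
    warning("nu_cpmg values rounded to an integer echo count: ",
            paste(nu_cpmg[off], collapse = ", "))
  if (any(n < 1)) stop("nu_cpmg too small for the constant-time period")
  n
}

#' Exact two-site CPMG dispersion
#'
#' Computes the effective transverse relaxation rate R2eff observed in a
#' constant-time CPMG experiment for two-site chemical exchange, valid
#' on all exchange timescales and for unequal intrinsic relaxation
#' rates.  The single-cycle propagator of the transverse magnetization,
#' a 2x2 complex Bloch-McConnell matrix conjugated by the refocusing
#' pulses, is diagonalized in closed form and raised to the echo-block
#' count, and
#' \deqn{R_{2,\mathrm{eff}} = -\frac{1}{T_{CP}}
#'       \ln\frac{|M(T_{CP})|}{|M(0)|}.}
#'
#' @param params a [two_site_params()] object.
#' @param nu_cpmg CPMG refocusing frequencies in Hz (vectorized).  The
#'   echo-block count `n = t_cp * nu_cpmg` must be a (near) integer.
#' @param t_cp constant-time relaxation period in seconds (default 20 ms).
#' @return R2eff in s^-1, one value per element of `nu_cpmg`.
#' @seealso [r2eff_numeric()] for the independent stepwise-propagation
#'   oracle.
#' @export
r2eff_exact <- function(params, nu_cpmg, t_cp = 0.020) {
  stopifnot(inherits(params, "two_site_params"))
  if (any(!is.finite(nu_cpmg)) || any(nu_cpmg <= 0))
    stop("'nu_cpmg' must be positive and finite")
  n <- .echo_count(nu_cpmg, t_cp)
  .r2eff_kernel(params$pb, params$kex, .dw_rad(params),
                params$r2a, params$r2b, n, t_cp)
}

# validation-free computational kernel of r2eff_exact; `n` is the
# precomputed echo-block count vector, dw in rad/s
.r2eff_kernel <- function(pb, kex, dw, r2a, r2b, n, t_cp) {
  tau <- t_cp / (4 * n)
  k1 <- pb * kex
  km1 <- (1 - pb) * kex
  # Free-evolution matrix A (column-major scalar entries)
  a11 <- complex(real = -(r2a + k1))
  a21 <- complex(real = k1)
  a12 <- complex(real = km1)
  a22 <- complex(real = -(r2b + km1), imaginary = dw)

  tr <- a11 + a22
  dt <- a11 * a22 - a12 * a21
  disc <- sqrt(tr^2 - 4 * dt)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2

  # closed-form exp(A t) components for a vector of times
  expA <- function(t) {
    if (Mod(l1 - l2) < 1e-10 * (1 + Mod(l1))) {
      f <- exp(l1 * t)
      list(e11 = f * (1 + t * (a11 - l1)), e12 = f * t * a12,
           e21 = f * t * a21, e22 = f * (1 + t * (a22 - l1)))
    } else {
      f1 <- exp(l1 * t); f2 <- exp(l2 * t); den <- l1 - l2
      list(e11 = (f1 * (a11 - l2) - f2 * (a11 - l1)) / den,
           e12 = (f1 - f2) * a12 / den,
           e21 = (f1 - f2) * a21 / den,
           e22 = (f1 * (a22 - l2) - f2 * (a22 - l1)) / den)
    }
  }
  E1 <- expA(tau)        # tau differs per nu_cpmg: vectors
  E2 <- expA(2 * tau)

  # one (tau - 180 - 2 tau - 180 - tau) block: M = E1 Conj(E2) E1
  b11 <- E1$e11 * Conj(E2$e11) + E1$e12 * Conj(E2$e21)
  b12 <- E1$e11 * Conj(E2$e12) + E1$e12 * Conj(E2$e22)
  b21 <- E1$e21 * Conj(E2$e11) + E1$e22 * Conj(E2$e21)
  b22 <- E1$e21 * Conj(E2$e12) + E1$e22 * Conj(E2$e22)
  m11 <- b11 * E1$e11 + b12 * E1$e21
  m12 <- b11 * E1$e12 + b12 * E1$e22
  m21 <- b21 * E1$e11 + b22 * E1$e21
  m22 <- b21 * E1$e12 + b22 * E1$e22

  # matrix power M^n by closed-form eigen-decomposition, elementwise
  trm <- m11 + m22
  dtm <- m11 * m22 - m12 * m21
  dsc <- sqrt(trm^2 - 4 * dtm)
  mu1 <- (trm + dsc) / 2
  mu2 <- (trm - dsc) / 2
  deg <- Mod(mu1 - mu2) < 1e-12 * (1 + Mod(mu1))
  den <- mu1 - mu2
  den[deg] <- 1   # placeholder; degenerate entries handled below
  p1 <- mu1^n; p2 <- mu2^n
  q11 <- (p1 * (m11 - mu2) - p2 * (m11 - mu1)) / den
  q12 <- (p1 - p2) * m12 / den
  q21 <- (p1 - p2) * m21 / den
  q22 <- (p1 * (m22 - mu2) - p2 * (m22 - mu1)) / den
  if (any(deg)) {
    f <- mu1[deg]^(n[deg] - 1)
    q11[deg] <- f * (mu1[deg] + n[deg] * (m11[deg] - mu1[deg]))
    q12[deg] <- f * n[deg] * m12[deg]
    q21[deg] <- f * n[deg] * m21[deg]
    q22[deg] <- f * (mu1[deg] + n[deg] * (m22[deg] - mu1[deg]))
  }

  pa <- 1 - pb
  s <- (q11 + q21) * pa + (q12 + q22) * pb
  -log(Mod(s)) / t_cp
}

# Series (scaling-and-squaring) matrix exponential of a small complex
# matrix; deliberately independent of the closed-form route above.
.expm_series <- function(a) {
  nrm <- max(rowSums(Mod(a)))
  k <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  as <- a / 2^k
  e <- diag(1 + 0i, nrow(a))
  term <- e
  for (i in 1:24) {
    term <- term %*% as / i
    e <- e + term
    if (max(Mod(term)) < 1e-18) break
  }
  if (k > 0) for (i in seq_len(k)) e <- e %*% e
  e
}

#' Numerical Bloch-McConnell CPMG oracle
#'
#' Propagates the 2x2 complex Bloch-McConnell matrix stepwise through
#' `n = t_cp * nu_cpmg` (tau - 180 - tau)^2 echo blocks, applying each
#' refocusing pulse as a complex conjugation of the magnetization
#' vector, and returns
#' `R2eff = -(1/t_cp) * log(|M(t_cp)| / |M(0)|)`.  The matrix
#' exponentials use a scaling-and-squaring series, so this route is
#' computationally independent of the closed-form eigen-decomposition
#' in [r2eff_exact()] and serves as its oracle.
#'
#' @inheritParams r2eff_exact
#' @return R2eff in s^-1, one value per element of `nu_cpmg`.
#' @export
r2eff_numeric <- function(params, nu_cpmg, t_cp = 0.020) {
  stopifnot(inherits(params, "two_site_params"))
  p <- params
  k1 <- p$pb * p$kex
  km1 <- (1 - p$pb) * p$kex
  dw <- .dw_rad(p)
  A <- matrix(c(complex(real = -(p$r2a + k1)), complex(real = k1),
                complex(real = km1),
                complex(real = -(p$r2b + km1), imaginary = dw)), 2, 2)
  n_all <- .echo_count(nu_cpmg, t_cp)
  vapply(seq_along(nu_cpmg), function(i) {
    n <- n_all[i]
    tau <- t_cp / (4 * n)
    E1 <- .expm_series(A * tau)
    E2 <- .expm_series(A * 2 * tau)
    v <- complex(real = c(1 - p$pb, p$pb))
    for (j in seq_len(n)) {
      v <- E1 %*% v
      v <- Conj(v)        # 180 degree refocusing pulse
      v <- E2 %*% v
      v <- Conj(v)
      v <- E1 %*% v
    }
    -log(Mod(sum(v))) / t_cp
  }, numeric(1))
}

#' Convert constant-time CPMG intensities to R2eff
#'
#' For a constant-time relaxation period `t_cp`, the peak intensity `i`
#' relative to the reference intensity `i0` (recorded without the
#' relaxation period) gives `R2eff = -(1/t_cp) * log(i / i0)`.  When an
#' intensity noise estimate `sigma_i` is supplied, the propagated R2eff
#' error `sigma_i / (i * t_cp)` is attached as attribute `"sigma"`.
#'
#' @param i,i0 peak intensity and reference intensity (same units, > 0).
#' @param t_cp constant-time relaxation period in seconds.
#' @param sigma_i optional intensity noise (same units as `i`).
#' @return R2eff in s^-1, with attribute `"sigma"` if `sigma_i` given.
#' @export
intensities_to_r2eff <- function(i, i0, t_cp = 0.020, sigma_i = NULL) {
  if (any(i <= 0) || any(i0 <= 0))
    stop("intensities must be positive")
  r2 <- -log(i / i0) / t_cp
  if (!is.null(sigma_i)) attr(r2, "sigma") <- sigma_i / (i * t_cp)
  r2
}

#' Arrhenius rate law
#'
#' `arrhenius_law()` constructs a rate law `k(T) = A exp(-Ea / (R T))`.
#' For numerical conditioning it may be parameterized by the rate at a
#' reference temperature instead of the prefactor; the prefactor is then
#' derived.  `arrhenius_k()` evaluates the law.
#'
#' @param ea_kj activation energy in kJ/mol.
#' @param prefactor prefactor A in s^-1 (give this or `k_ref`).
#' @param k_ref rate at `t_ref` in s^-1.
#' @param t_ref reference temperature in K (default 298.15).
#' @return `arrhenius_law()`: an object of class `"arrhenius_law"`;
#'   `arrhenius_k()`: rate(s) in s^-1.
#' @export
arrhenius_law <- function(ea_kj, prefactor = NULL, k_ref = NULL,
                          t_ref = 298.15) {
  if (is.null(prefactor) == is.null(k_ref))
    stop("give exactly one of 'prefactor' or 'k_ref'")
  if (is.null(prefactor))
    prefactor <- k_ref * exp(1000 * ea_kj / (.RGAS * t_ref))
  if (prefactor <= 0) stop("prefactor must be > 0")
  structure(list(prefactor = prefactor, ea_kj = ea_kj, t_ref = t_ref),
            class = "arrhenius_law")
}

.RGAS <- 8.314  # J mol^-1 K^-1

#' @rdname arrhenius_law
#' @param law an `"arrhenius_law"` object.
#' @param temperature temperature(s) in K (> 0).
#' @export
arrhenius_k <- function(law, temperature) {
  stopifnot(inherits(law, "arrhenius_law"))
  if (any(temperature <= 0)) stop("temperature must be > 0 K")
  law$prefactor * exp(-1000 * law$ea_kj / (.RGAS * temperature))
}

#' @export
print.arrhenius_law <- function(x, ...) {
  cat(sprintf("Arrhenius law: Ea = %.2f kJ/mol, k(%.2f K) = %.4g /s\n",
              x$ea_kj, x$t_ref, arrhenius_k(x, x$t_ref)))
  invisible(x)
}

#' One-dimensional exchange lineshape
#'
#' Frequency-domain lineshape of n mutually exchanging sites from the
#' McConnell equations:
#' \deqn{I(\omega) = \mathrm{Re}\,[\mathbf{1}^T
#'       (i(\omega I - \Omega) + R_2 - K)^{-1} p],}
#' where `Omega` is the diagonal matrix of site offsets, `R2` the
#' diagonal matrix of site linewidths and `K` the kinetic exchange
#' matrix (columns sum to zero).  The populations must sum to one and
#' the exchange matrix must satisfy detailed balance with them.
#'
#' @param populations site populations (sum to 1).
#' @param offsets site offsets in rad/s.
#' @param r2 site transverse relaxation rates in s^-1.  A small
#'   linewidth floor (`1e-3` s^-1) is applied to keep the resolvent
#'   finite on resonance.
#' @param kex for two sites, the scalar exchange rate `k1 + km1`;
#'   in general an n x n kinetic matrix with columns summing to zero.
#' @param grid frequency axis in rad/s (strictly increasing).
#' @return an object of class `"spectrum_grid"`: list with `omega` and
#'   `intensity`.
#' @export
lineshape_1d <- function(populations, offsets, r2, kex, grid) {
  ns <- length(populations)
  stopifnot(length(offsets) == ns, length(r2) == ns)
  if (abs(sum(populations) - 1) > 1e-8)
    stop("populations must sum to 1")
  if (is.unsorted(grid, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
  if (is.matrix(kex)) {
    K <- kex
    if (any(abs(colSums(K)) > 1e-8 * max(abs(K))))
      stop("columns of the exchange matrix must sum to zero")
    db <- K * rep(populations, each = ns)   # K[i,j] p[j]
    if (max(abs(db - t(db))) > 1e-6 * max(abs(db), 1e-300))
      stop("exchange matrix violates detailed balance")
  } else {
    stopifnot(ns == 2L)
    k1 <- populations[2] * kex
    km1 <- populations[1] * kex
    K <- matrix(c(-k1, k1, km1, -km1), 2, 2)
  }
  r2 <- pmax(r2, 1e-3)
  base <- diag(r2, ns) - K - 1i * diag(offsets, ns)
  one <- rep(1, ns)
  intensity <- vapply(grid, function(w) {
    Re(sum(one * solve(base + 1i * w * diag(ns), populations)))
  }, numeric(1))
  structure(list(omega = grid, intensity = intensity),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, omega in [%.4g, %.4g] rad/s\n",
              length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

#' @export
plot.spectrum_grid <- function(x, ...) {
  graphics::plot(x$omega, x$intensity, type = "l",
                 xlab = expression(omega ~ (rad/s)),
                 ylab = "intensity", ...)
  invisible(x)
}

#' Total integrated intensity of a spectrum (trapezoidal rule)
#'
#' @param spectrum a `"spectrum_grid"` object.
#' @return the integral of intensity over the frequency axis.
#' @export
spectrum_area <- function(spectrum) {
  w <- spectrum$omega; y <- spectrum$intensity
  sum(diff(w) * (y[-1] + y[-length(y)]) / 2)
}

#' Fit a pair of Lorentzians to a two-peak spectrum
#'
#' Least-squares fit of the sum of two Lorentzian lines
#' `a_k * (w_k/pi) / ((omega - x_k)^2 + w_k^2)` to a spectrum, used to
#' quantify peak areas (hence populations) in slow-exchange spectra.
#' Initial positions are the two highest local maxima.
#'
#' @param spectrum a `"spectrum_grid"` object with two resolved peaks.
#' @return a list with matrices of per-peak `position`, `width`, `area`
#'   (major peak first by area) and the fitted curve.
#' @export
fit_lorentzian_pair <- function(spectrum) {
  w <- spectrum$omega; y <- spectrum$intensity
  n <- length(y)
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(loc) < 2L)
    stop("spectrum does not show two resolved peaks")
  loc <- loc[order(y[loc], decreasing = TRUE)][1:2]
  par0 <- unlist(lapply(loc, function(i) {
    half <- y[i] / 2
    width <- tryCatch({
      r <- range(w[y > half & abs(w - w[i]) < diff(range(w)) / 4])
      max(diff(r) / 2, diff(range(w)) / n)
    }, error = function(e) diff(range(w)) / 50)
    c(w[i], log(width), log(pi * width * y[i]))
  }))
  model <- function(p) {
    p1 <- p[1:3]; p2 <- p[4:6]
    lor <- function(q) {
      wd <- exp(q[2]); a <- exp(q[3])
      a * (wd / pi) / ((w - q[1])^2 + wd^2)
    }
    lor(p1) + lor(p2)
  }
  obj <- function(p) sum((y - model(p))^2)
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  pk <- rbind(fit$par[1:3], fit$par[4:6])
  out <- data.frame(position = pk[, 1], width = exp(pk[, 2]),
                    area = exp(pk[, 3]))
  out <- out[order(out$area, decreasing = TRUE), ]
  rownames(out) <- c("major", "minor")
  list(peaks = out, fitted = model(fit$par), sse = fit$value)
}

#' Minor-state population from peak areas
#'
#' @param major,minor integrated areas (or heights for equal-width
#'   lines) of the major and minor peaks; both must be non-negative and
#'   not both zero.
#' @return the minor fraction `minor / (major + minor)`.
#' @export
populations_from_peaks <- function(major, minor) {
  if (major < 0 || minor < 0) stop("areas must be >= 0")
  if (major + minor == 0) stop("both areas are zero")
  minor / (major + minor)
}
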