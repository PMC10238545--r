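# Per-residue and global fitting of CPMG dispersion profiles: a
# single-temperature two-site fit with (kex, pB) shared across
# residues, and the multi-temperature global fit with
# Arrhenius-coupled rates and temperature-independent per-residue
# shift differences.  Both start from an extensive grid search and end
# with bounded quasi-Newton descent; errors come from the spread of
# the best multi-start refits.

# exchange contribution Rex(nu) for equal intrinsic R2: with r2a = r2b
# the cycle propagator factorizes as exp(-r2 T) times an exchange-only
# part, so R2eff = r2 + Rex with Rex computed at r2 = 0
.rex_vec <- function(pb, kex, dw_rad, n, t_cp) {
  .r2eff_kernel(pb, kex, dw_rad, 0, 0, n, t_cp)
}

# organize a dispersion table into per-(residue, temperature) profiles
# with precomputed echo counts
.disp_profiles <- function(data, t_cp) {
  key <- paste(data$residue, data$temperature)
  idx <- split(seq_len(nrow(data)), key)
  lapply(idx, function(ii) {
    d <- data[ii, ]
    list(residue = d$residue[1], temperature = d$temperature[1],
         nu = d$nu_cpmg, r2eff = d$r2eff, sigma = d$sigma,
         n = .echo_count(d$nu_cpmg, t_cp))
  })
}

# chi^2 of one profile given Rex values, with the intrinsic R2 offset
# profiled out in closed form (weighted mean of obs - Rex)
.prof_chi2 <- function(prof, rex) {
  w <- 1 / prof$sigma^2
  r0 <- sum(w * (prof$r2eff - rex)) / sum(w)
  list(chi2 = sum(w * (prof$r2eff - rex - r0)^2), r2_0 = max(r0, 0))
}

#' Detect whether a profile shows measurable dispersion
#'
#' The dispersion amplitude is the mean R2eff at the lowest CPMG
#' frequency minus the mean at the highest.  Exchange is reported only
#' when this amplitude is strictly greater than `threshold` times the
#' median point error.
#'
#' @param profile a `"dispersion_table"` subset for one residue and
#'   temperature.
#' @param threshold multiple of the median sigma (default 2).
#' @return list with logical `detected` and the `amplitude` in 1/s.
#' @export
detect_dispersion <- function(profile, threshold = 2) {
  nu <- profile$nu_cpmg
  amp <- mean(profile$r2eff[nu == min(nu)]) -
    mean(profile$r2eff[nu == max(nu)])
  list(detected = amp > threshold * stats::median(profile$sigma),
       amplitude = amp)
}

#' Fit two-site exchange models to CPMG dispersion profiles
#'
#' `mode = "single"` fits one temperature: a global (kex, pB) shared
#' across residues with per-residue shift difference and intrinsic R2,
#' minimizing the error-weighted chi-square against the exact two-site
#' model.  `mode = "multitemp"` fits all temperatures jointly: the
#' forward and reverse rates each follow an Arrhenius law (fitted as
#' rate at 25 C plus activation energy), populations derive from the
#' rates at each temperature, each residue's shift difference is fixed
#' across temperature, and intrinsic R2 is free per residue and
#' temperature.  Both modes start from an extensive grid search over
#' (kex, pB, per-residue dw) and finish with bounded quasi-Newton
#' (L-BFGS-B) descent; replicate points enter the chi-square
#' individually.
#'
#' @param data a `"dispersion_table"` data frame (columns `residue`,
#'   `temperature`, `nu_cpmg`, `r2eff`, `sigma`).
#' @param mode `"single"` or `"multitemp"`.
#' @param nucleus,field_mhz observed nucleus and 1H field (taken from
#'   the table's `nucleus`/`field` columns when present).
#' @param t_cp constant-time CPMG period in seconds.
#' @param control list of optional tuning values: `kex_grid` (log-
#'   spaced, default 20 points in 100-6000 /s), `pb_grid` (default 10
#'   points in 0.01-0.5), `dw_grid` (default 10 points in 0.1-5 ppm),
#'   `maxit` (default 200), `t_ref` (reference temperature for the
#'   Arrhenius parameterization, default 298.15 K).
#' @param start optional named start values bypassing the grid search.
#' @return an object of class `"cpmg_fit"`.
#' @export
fit_dispersion <- function(data, mode = c("single", "multitemp"),
                           nucleus = NULL, field_mhz = NULL,
                           t_cp = 0.020, control = list(),
                           start = NULL) {
  mode <- match.arg(mode)
  if (is.null(nucleus))
    nucleus <- if ("nucleus" %in% names(data)) data$nucleus[1] else "13C"
  if (is.null(field_mhz))
    field_mhz <- if ("field" %in% names(data)) data$field[1] else 700
  ctl <- utils::modifyList(list(
    kex_grid = exp(seq(log(100), log(6000), length.out = 20)),
    pb_grid = seq(0.01, 0.5, length.out = 10),
    dw_grid = seq(0.1, 5, length.out = 10),
    maxit = 200, t_ref = 298.15), control)
  if (any(data$sigma <= 0)) stop("point errors must be > 0")
  profs <- .disp_profiles(data, t_cp)
  for (p in profs)
    if (length(unique(p$nu)) < 4)
      stop("each profile needs >= 4 distinct nu_cpmg values")
  temps <- sort(unique(data$temperature))
  omega_ppm <- 2 * pi * larmor_mhz(nucleus, field_mhz)  # rad/s per ppm

  fit <- if (mode == "single") {
    if (length(temps) != 1)
      stop("'single' mode expects one temperature; use mode = 'multitemp'")
    .fit_single_t(profs, omega_ppm, t_cp, ctl, start)
  } else {
    if (length(temps) < 2)
      stop("multi-temperature fit needs at least 2 distinct temperatures")
    .fit_multi_t(profs, temps, omega_ppm, t_cp, ctl, start)
  }

  detect <- lapply(split(data, data$residue), function(d) {
    d25 <- d[d$temperature == d$temperature[which.min(
      abs(d$temperature - 298.15))], ]
    detect_dispersion(d25)
  })
  fit$detectable <- vapply(detect, `[[`, TRUE, "detected")
  fit$amplitude <- vapply(detect, `[[`, 1, "amplitude")
  fit$data <- data
  fit$nucleus <- nucleus; fit$field_mhz <- field_mhz; fit$t_cp <- t_cp
  fit$control <- ctl
  class(fit) <- "cpmg_fit"
  fit
}

# ---- single-temperature global fit ---------------------------------

.fit_single_t <- function(profs, omega_ppm, t_cp, ctl, start = NULL) {
  nres <- length(profs)
  resid_ids <- vapply(profs, `[[`, 1, "residue")
  # grid stage: shared (kex, pb), per-residue best dw with closed-form R2,0
  best <- NULL
  if (is.null(start)) {
    for (kex in ctl$kex_grid) for (pb in ctl$pb_grid) {
      tot <- 0; dws <- r2s <- numeric(nres)
      for (i in seq_len(nres)) {
        pr <- profs[[i]]
        cb <- Inf
        for (dw in ctl$dw_grid) {
          rex <- .rex_vec(pb, kex, dw * omega_ppm, pr$n, t_cp)
          cc <- .prof_chi2(pr, rex)
          if (cc$chi2 < cb) { cb <- cc$chi2; dws[i] <- dw; r2s[i] <- cc$r2_0 }
        }
        tot <- tot + cb
      }
      if (is.null(best) || tot < best$chi2)
        best <- list(chi2 = tot, kex = kex, pb = pb, dw = dws, r2 = r2s)
    }
  } else {
    best <- list(kex = start$kex, pb = start$pb,
                 dw = rep_len(start$dw, nres), r2 = rep_len(start$r2, nres))
  }
  # the intrinsic R2 offsets enter linearly and are profiled out in
  # closed form, leaving (log kex, pB, per-residue dw)
  obj <- function(par) {
    kex <- exp(par[1]); pb <- par[2]
    dw <- par[2 + seq_len(nres)]
    tot <- 0
    for (i in seq_len(nres)) {
      pr <- profs[[i]]
      rex <- .rex_vec(pb, kex, dw[i] * omega_ppm, pr$n, t_cp)
      w <- 1 / pr$sigma^2
      r0 <- sum(w * (pr$r2eff - rex)) / sum(w)
      tot <- tot + sum(w * (pr$r2eff - rex - r0)^2)
    }
    tot
  }
  par0 <- c(log(best$kex), best$pb, best$dw)
  lower <- c(log(20), 1e-3, rep(0, nres))
  upper <- c(log(3e4), 0.5, rep(10, nres))
  opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = ctl$maxit, factr = 1e7,
                                     parscale = c(0.5, 0.05,
                                                  rep(0.2, nres))))
  kex <- exp(opt$par[1]); pb <- opt$par[2]
  dw <- opt$par[2 + seq_len(nres)]
  r2 <- vapply(seq_len(nres), function(i) {
    pr <- profs[[i]]
    rex <- .rex_vec(pb, kex, dw[i] * omega_ppm, pr$n, t_cp)
    .prof_chi2(pr, rex)$r2_0
  }, numeric(1))
  names(dw) <- names(r2) <- resid_ids
  fitted <- unlist(lapply(seq_len(nres), function(i) {
    pr <- profs[[i]]
    r2[i] + .rex_vec(pb, kex, dw[i] * omega_ppm, pr$n, t_cp)
  }))
  obs <- unlist(lapply(profs, `[[`, "r2eff"))
  sig <- unlist(lapply(profs, `[[`, "sigma"))
  npar <- length(opt$par) + nres   # profiled R2,0 count as parameters
  list(mode = "single",
       kex = kex, pb = pb, dw = dw, r2_0 = r2,
       chisq = opt$value,
       redchi = opt$value / max(1, length(obs) - npar),
       residuals = (obs - fitted) / sig, fitted = fitted,
       converged = opt$convergence == 0,
       profiles = profs, omega_ppm = omega_ppm,
       optim = opt,
       bounds = list(lower = lower, upper = upper),
       objective = obj)
}

# ---- multi-temperature Arrhenius-coupled global fit -----------------

.fit_multi_t <- function(profs, temps, omega_ppm, t_cp, ctl, start = NULL) {
  resid_ids <- sort(unique(vapply(profs, `[[`, 1, "residue")))
  nres <- length(resid_ids)
  nt <- length(temps)
  tref <- ctl$t_ref
  rate <- function(kref, ea, tt)
    kref * exp(-1000 * ea / .RGAS * (1 / tt - 1 / tref))
  # parameters: ea1, ea2, log k1ref, log km1ref, dw[res]; the per-
  # profile intrinsic R2 offsets are profiled out in closed form
  unpack <- function(par) {
    list(ea1 = par[1], ea2 = par[2], k1r = exp(par[3]),
         km1r = exp(par[4]), dw = par[4 + seq_len(nres)])
  }
  model_chi2 <- function(q) {
    tot <- 0
    for (pr in profs) {
      i <- match(pr$residue, resid_ids)
      k1 <- rate(q$k1r, q$ea1, pr$temperature)
      km1 <- rate(q$km1r, q$ea2, pr$temperature)
      kex <- k1 + km1; pb <- k1 / kex
      rex <- .rex_vec(pb, kex, q$dw[i] * omega_ppm, pr$n, t_cp)
      w <- 1 / pr$sigma^2
      r0 <- sum(w * (pr$r2eff - rex)) / sum(w)
      tot <- tot + sum(w * (pr$r2eff - rex - r0)^2)
    }
    tot
  }
  if (is.null(start)) {
    # grid stage at flat Arrhenius (equal activation energies: constant
    # populations) over (kex, pb) and per-residue dw
    best <- NULL
    for (kex in ctl$kex_grid) for (pb in ctl$pb_grid) {
      tot <- 0
      dws <- numeric(nres); r2s <- matrix(0, nres, nt)
      for (i in seq_len(nres)) {
        cbest <- Inf; dwbest <- ctl$dw_grid[1]
        for (dw in ctl$dw_grid) {
          cc <- 0
          for (pr in profs[vapply(profs, `[[`, 1, "residue") ==
                             resid_ids[i]]) {
            rex <- .rex_vec(pb, kex, dw * omega_ppm, pr$n, t_cp)
            cc <- cc + .prof_chi2(pr, rex)$chi2
          }
          if (cc < cbest) { cbest <- cc; dwbest <- dw }
        }
        dws[i] <- dwbest
        for (pr in profs[vapply(profs, `[[`, 1, "residue") ==
                           resid_ids[i]]) {
          j <- match(pr$temperature, temps)
          rex <- .rex_vec(pb, kex, dwbest * omega_ppm, pr$n, t_cp)
          r2s[i, j] <- .prof_chi2(pr, rex)$r2_0
        }
        tot <- tot + cbest
      }
      if (is.null(best) || tot < best$chi2)
        best <- list(chi2 = tot, kex = kex, pb = pb, dw = dws, r2 = r2s)
    }
    par0 <- c(50, 50, log(best$pb * best$kex),
              log((1 - best$pb) * best$kex), best$dw)
  } else {
    par0 <- c(start$ea1, start$ea2, log(start$k1_ref), log(start$km1_ref),
              rep_len(start$dw, nres))
  }
  obj <- function(par) model_chi2(unpack(par))
  lower <- c(0, 0, log(1), log(1), rep(0, nres))
  upper <- c(250, 250, log(1e5), log(1e5), rep(10, nres))
  opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = ctl$maxit, factr = 1e7,
                                     parscale = c(5, 5, 0.5, 0.5,
                                                  rep(0.2, nres))))
  q <- unpack(opt$par)
  # recover the profiled intrinsic R2 offsets
  q$r2 <- matrix(0, nres, nt)
  for (pr in profs) {
    i <- match(pr$residue, resid_ids)
    j <- match(pr$temperature, temps)
    k1 <- rate(q$k1r, q$ea1, pr$temperature)
    km1 <- rate(q$km1r, q$ea2, pr$temperature)
    rex <- .rex_vec(k1 / (k1 + km1), k1 + km1, q$dw[i] * omega_ppm,
                    pr$n, t_cp)
    q$r2[i, j] <- .prof_chi2(pr, rex)$r2_0
  }
  k1_laws <- arrhenius_law(ea_kj = q$ea1, k_ref = q$k1r, t_ref = tref)
  km1_laws <- arrhenius_law(ea_kj = q$ea2, k_ref = q$km1r, t_ref = tref)
  k1 <- arrhenius_k(k1_laws, temps); km1 <- arrhenius_k(km1_laws, temps)
  pops <- data.frame(temperature = temps, k1 = k1, km1 = km1,
                     kex = k1 + km1, pb = k1 / (k1 + km1))
  fitted <- unlist(lapply(profs, function(pr) {
    i <- match(pr$residue, resid_ids); j <- match(pr$temperature, temps)
    kk1 <- rate(q$k1r, q$ea1, pr$temperature)
    kkm <- rate(q$km1r, q$ea2, pr$temperature)
    q$r2[i, j] + .rex_vec(kk1 / (kk1 + kkm), kk1 + kkm,
                          q$dw[i] * omega_ppm, pr$n, t_cp)
  }))
  obs <- unlist(lapply(profs, `[[`, "r2eff"))
  sig <- unlist(lapply(profs, `[[`, "sigma"))
  dw <- q$dw; names(dw) <- resid_ids
  rownames(q$r2) <- resid_ids; colnames(q$r2) <- temps
  list(mode = "multitemp",
       arrhenius = list(k1 = k1_laws, km1 = km1_laws),
       populations = pops,
       kex = pops$kex[which.min(abs(temps - tref))],
       pb = pops$pb[which.min(abs(temps - tref))],
       dw = dw, r2_0 = q$r2,
       chisq = opt$value,
       redchi = opt$value /
         max(1, length(obs) - length(opt$par) - nres * nt),
       residuals = (obs - fitted) / sig, fitted = fitted,
       converged = opt$convergence == 0,
       profiles = profs, omega_ppm = omega_ppm, temps = temps,
       optim = opt,
       bounds = list(lower = lower, upper = upper),
       objective = obj)
}

# ---- methods --------------------------------------------------------

#' @export
print.cpmg_fit <- function(x, ...) {
  if (x$mode == "single") {
    cat(sprintf(
      "Two-site CPMG fit (single temperature): kex = %.0f /s, pB = %.3f\n",
      x$kex, x$pb))
  } else {
    cat("Two-site CPMG fit (multi-temperature, Arrhenius-coupled)\n")
    cat(sprintf("  Ea(k1) = %.1f kJ/mol, Ea(k-1) = %.1f kJ/mol\n",
                x$arrhenius$k1$ea_kj, x$arrhenius$km1$ea_kj))
    cat(sprintf("  at %.2f K: kex = %.0f /s, pB = %.3f\n",
                x$control$t_ref, x$kex, x$pb))
  }
  cat(sprintf("  chi^2 = %.1f (reduced %.2f), %d residue(s)%s\n",
              x$chisq, x$redchi, length(x$dw),
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
summary.cpmg_fit <- function(object, ...) {
  x <- object
  tab <- data.frame(residue = as.integer(names(x$dw)),
                    dw_ppm = as.numeric(x$dw),
                    detectable = x$detectable[as.character(names(x$dw))])
  out <- list(fit = x, table = tab,
              populations = if (x$mode == "multitemp") x$populations)
  class(out) <- "summary.cpmg_fit"
  out
}

#' @export
print.summary.cpmg_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-residue shift differences:\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$populations)) {
    cat("\nPopulations per temperature:\n")
    print(x$populations, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cpmg_fit <- function(object, ...) {
  if (object$mode == "single")
    c(kex = object$kex, pb = object$pb, object$dw)
  else
    c(kex = object$kex, pb = object$pb,
      ea_k1 = object$arrhenius$k1$ea_kj,
      ea_km1 = object$arrhenius$km1$ea_kj, object$dw)
}

#' @export
fitted.cpmg_fit <- function(object, ...) object$fitted

#' @export
residuals.cpmg_fit <- function(object, ...) object$residuals

#' Predicted R2eff profiles from a fitted model
#'
#' @param object a `"cpmg_fit"`.
#' @param residue residue number (default: first fitted residue).
#' @param nu_cpmg frequencies at which to predict.
#' @param temperature for multi-temperature fits, the temperature in K.
#' @param ... unused.
#' @return predicted R2eff values in 1/s.
#' @export
predict.cpmg_fit <- function(object, residue = NULL,
                             nu_cpmg = c(100, 200, 400, 500, 800, 1000),
                             temperature = NULL, ...) {
  x <- object
  if (is.null(residue)) residue <- as.integer(names(x$dw)[1])
  i <- match(as.character(residue), names(x$dw))
  if (is.na(i)) stop("residue not in the fit")
  n <- .echo_count(nu_cpmg, x$t_cp)
  if (x$mode == "single") {
    x$r2_0[i] + .rex_vec(x$pb, x$kex, x$dw[i] * x$omega_ppm, n, x$t_cp)
  } else {
    if (is.null(temperature)) temperature <- x$control$t_ref
    k1 <- arrhenius_k(x$arrhenius$k1, temperature)
    km1 <- arrhenius_k(x$arrhenius$km1, temperature)
    j <- which.min(abs(x$temps - temperature))
    x$r2_0[i, j] + .rex_vec(k1 / (k1 + km1), k1 + km1,
                            x$dw[i] * x$omega_ppm, n, x$t_cp)
  }
}

#' @export
plot.cpmg_fit <- function(x, residue = NULL, ...) {
  if (is.null(residue)) residue <- as.integer(names(x$dw)[1])
  d <- x$data[x$data$residue == residue, ]
  graphics::plot(d$nu_cpmg, d$r2eff, pch = 16,
                 xlab = expression(nu[CPMG] ~ (Hz)),
                 ylab = expression(R[2][",eff"] ~ (s^-1)),
                 main = paste("residue", residue), ...)
  nus <- seq(50, max(d$nu_cpmg), by = 50)
  for (tt in unique(d$temperature)) {
    pr <- predict(x, residue, nus, temperature = tt)
    graphics::lines(nus, pr)
  }
  invisible(x)
}

#' Multi-start parameter uncertainties for a dispersion fit
#'
#' Re-runs the local optimization from `n_starts` random initial
#' points drawn within the parameter bounds and reports, for every
#' parameter, the standard deviation over the `n_keep` refits with the
#' lowest chi-square (the convention used for dispersion-fit error
#' bars: 10 best of 100).
#'
#' @param fit a `"cpmg_fit"` object.
#' @param n_starts number of random starts (default 100).
#' @param n_keep number of best refits kept (default 10); must not
#'   exceed `n_starts`.
#' @param seed integer seed for the random starts.
#' @return list with `sd` (named per-parameter standard deviations over
#'   the kept refits), `kept` (their parameter table) and `chisq` (all
#'   final chi-squares).
#' @export
estimate_errors <- function(fit, n_starts = 100, n_keep = 10, seed = 1) {
  stopifnot(inherits(fit, "cpmg_fit"))
  if (n_keep > n_starts) stop("n_keep must not exceed n_starts")
  lo <- fit$bounds$lower; up <- fit$bounds$upper
  # random starts within the grid-search ranges rather than the full
  # box, mirroring randomly selected initial points
  lo2 <- lo; up2 <- up
  if (fit$mode == "single") {
    lo2[1:2] <- c(log(100), 0.01); up2[1:2] <- c(log(6000), 0.5)
  } else {
    lo2[1:4] <- c(5, 5, log(10), log(10))
    up2[1:4] <- c(120, 120, log(5000), log(5000))
  }
  ndw <- length(fit$dw)
  dwslot <- (if (fit$mode == "single") 2 else 4) + seq_len(ndw)
  up2[dwslot] <- 5; lo2[dwslot] <- 0.1
  runs <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      p0 <- stats::runif(length(lo), lo2, up2)
      opt <- tryCatch(
        stats::optim(p0, fit$objective, method = "L-BFGS-B",
                     lower = lo, upper = up,
                     control = list(maxit = fit$control$maxit,
                                    factr = 1e7)),
        error = function(e) NULL)
      opt
    })
  })
  ok <- !vapply(runs, is.null, TRUE)
  if (!any(ok)) stop("all starts failed to converge")
  runs <- runs[ok]
  chis <- vapply(runs, `[[`, 1, "value")
  kept <- runs[order(chis)[seq_len(min(n_keep, length(runs)))]]
  P <- do.call(rbind, lapply(kept, `[[`, "par"))
  # report on natural scales
  if (fit$mode == "single") {
    nat <- cbind(exp(P[, 1]), P[, -1, drop = FALSE])
    cn <- c("kex", "pb", paste0("dw_", names(fit$dw)))
  } else {
    nat <- cbind(P[, 1:2], exp(P[, 3:4]), P[, -(1:4), drop = FALSE])
    cn <- c("ea_k1", "ea_km1", "k1_ref", "km1_ref",
            paste0("dw_", names(fit$dw)))
  }
  colnames(nat) <- cn
  list(sd = apply(nat, 2, stats::sd), kept = nat,
       chisq = sort(chis)[seq_len(min(n_keep, length(runs)))],
       all_chisq = chis)
}
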