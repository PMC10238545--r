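# Synthetic-data generator: two-conformer backbone ensembles with
# known localized displacements, multi-medium RDC sets, Arrhenius-
# coupled multi-temperature dispersion profiles, and 1D exchange
# spectra.  Every generator is a pure function of its parameters and
# seed.

# evaluate expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# mixed alpha/beta secondary-structure plan (phi/psi in degrees),
# proportionally rescaled from a 166-residue G-domain-like layout
.ss_plan <- function(n) {
  seg166 <- rbind(
    c(3, 9, 1), c(16, 25, 2), c(38, 44, 1), c(49, 57, 1),
    c(66, 74, 2), c(77, 83, 1), c(87, 104, 2), c(111, 116, 1),
    c(127, 137, 2), c(141, 143, 1), c(152, 165, 2))  # 1 = strand, 2 = helix
  sc <- n / 166
  phi <- rep(-70, n); psi <- rep(145, n)
  coil <- cbind(c(-70, -100, -60, -80), c(145, 120, 150, 130))
  idx <- (seq_len(n) - 1) %% 4 + 1
  phi <- coil[idx, 1]; psi <- coil[idx, 2]
  for (r in seq_len(nrow(seg166))) {
    a <- max(1, round(seg166[r, 1] * sc))
    b <- min(n, round(seg166[r, 2] * sc))
    if (b < a) next
    if (seg166[r, 3] == 1) { phi[a:b] <- -120; psi[a:b] <- 130 }
    else { phi[a:b] <- -57; psi[a:b] <- -47 }
  }
  list(phi = phi, psi = psi)
}

# rotation matrix about unit axis u by angle th (radians)
.rot_axis <- function(u, th) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

#' Generate a two-state backbone ensemble with known displacements
#'
#' Builds an idealized mixed alpha/beta backbone (the ground state)
#' and a minor conformer obtained by smooth, localized, rigid-body-like
#' displacements of the requested segments: each segment is rotated
#' about a random axis through its centroid (so that bond vectors
#' genuinely reorient) and slightly translated, flanking residues are
#' blended, and the result is relaxed under the local-geometry elastic
#' network while tethered to the displaced target, restoring chemical
#' regularity.  All atoms stay within `max_displacement` of the ground
#' state.
#'
#' @param n_residues chain length (default 166).
#' @param segments list of inclusive residue ranges to displace.
#' @param max_displacement target maximum atomic displacement in
#'   Angstrom; must not exceed the 3 Angstrom refinement cap.
#' @param seed integer seed; output is a pure function of arguments.
#' @return list with `ground` and `minor` [structure_model()]s and the
#'   true per-residue backbone `displacement` profile (Angstrom).
#' @export
make_two_state_structures <- function(n_residues = 166,
                                      segments = list(c(105, 118),
                                                      c(125, 140)),
                                      max_displacement = 2.8,
                                      seed = 1) {
  if (max_displacement > 3)
    stop("displacement request exceeds the 3 Angstrom cap")
  for (s in segments)
    if (s[1] < 1 || s[2] > n_residues || s[2] < s[1])
      stop("segment outside the sequence")
  plan <- .ss_plan(n_residues)
  ground <- .build_backbone(plan$phi, plan$psi)
  ground$metadata <- "synthetic ground state"
  if (max_displacement == 0 || length(segments) == 0) {
    minor <- ground
    minor$metadata <- "synthetic minor state"
    prof <- rep(0, n_residues); names(prof) <- seq_len(n_residues)
    return(list(ground = ground, minor = minor, displacement = prof))
  }
  a <- ground$atoms
  X0 <- as.matrix(a[c("x", "y", "z")])
  .with_seed(seed, {
    U <- X0 * 0
    amp <- rep(max_displacement, length(segments))
    for (s in seq_along(segments)) {
      rng <- segments[[s]]
      insel <- a$resno >= rng[1] & a$resno <= rng[2]
      ctr <- colMeans(X0[insel, , drop = FALSE])
      rel <- sweep(X0[insel, , drop = FALSE], 2, ctr)
      rho <- max(sqrt(rowSums(rel^2)))
      # tilt axis perpendicular to the segment's principal axis, so a
      # helix/strand is tipped rather than twisted and its bond
      # vectors genuinely reorient
      pc <- svd(rel, nu = 0, nv = 1)$v[, 1]
      rnd <- stats::rnorm(3)
      axis <- c(pc[2] * rnd[3] - pc[3] * rnd[2],
                pc[3] * rnd[1] - pc[1] * rnd[3],
                pc[1] * rnd[2] - pc[2] * rnd[1])
      th <- 2 * asin(min(1, 0.9 * amp[s] / (2 * rho)))
      R <- .rot_axis(axis, th)
      tvec <- stats::rnorm(3); tvec <- tvec / sqrt(sum(tvec^2))
      # residue weight: 1 inside the segment, tapering over 4 flanking
      # residues, 0 elsewhere
      flank <- 4
      wres <- rep(0, n_residues)
      wres[rng[1]:rng[2]] <- 1
      for (f in seq_len(flank)) {
        b <- 1 - f / (flank + 1)
        if (rng[1] - f >= 1) wres[rng[1] - f] <- max(wres[rng[1] - f], b)
        if (rng[2] + f <= n_residues)
          wres[rng[2] + f] <- max(wres[rng[2] + f], b)
      }
      rigid <- sweep(X0, 2, ctr) %*% (t(R) - diag(3))
      rigid <- sweep(rigid, 2, 0.1 * amp[s] * tvec, "+")
      U <- U + rigid * wres[a$resno]
    }
    target <- X0 + U
    # elastic relaxation toward the displaced target
    pr <- .elastic_pairs(a$resno, a$atom, X0)
    obj <- function(xv) {
      X <- matrix(xv, ncol = 3)
      pe <- .pair_energy(X, pr)
      te <- .tether_energy(X, target, 2)
      pe$E + te$E
    }
    grd <- function(xv) {
      X <- matrix(xv, ncol = 3)
      pe <- .pair_energy(X, pr)
      te <- .tether_energy(X, target, 2)
      as.numeric(pe$G + te$G)
    }
    fit <- stats::optim(as.numeric(target), obj, grd, method = "L-BFGS-B",
                        control = list(maxit = 400, factr = 1e7))
    Xm <- matrix(fit$par, ncol = 3)
  })
  minor <- ground
  minor$atoms[c("x", "y", "z")] <- Xm
  minor$metadata <- "synthetic minor state"
  d2 <- rowSums((Xm - X0)^2)
  prof <- sqrt(tapply(d2, a$resno, mean))
  prof <- prof[order(as.integer(names(prof)))]
  prof <- stats::setNames(as.numeric(prof), names(prof))
  list(ground = ground, minor = minor, displacement = prof)
}

#' Orientationally sparse (anisotropic) RDC subset
#'
#' Restricts an RDC table to couplings whose bond vectors lie away
#' from the alignment-tensor principal axis (|cos theta| below
#' `cone`).  Such subsets sample orientations anisotropically: fitted
#' against an imperfect reference structure, their SVD tensor
#' magnitude is systematically underestimated — the situation the
#' tensor-magnitude grid correction compensates.
#'
#' @param truth a [synthetic_truth()] (supplies the true tensor frame
#'   and ground structure).
#' @param rdc an `"rdc_table"`.
#' @param medium which alignment medium to restrict.
#' @param types coupling types kept (default NH and CA-HA).
#' @param cone |cos theta| threshold to the tensor z axis (default
#'   0.75).
#' @return the restricted `"rdc_table"`.
#' @export
anisotropic_rdc_subset <- function(truth, rdc, medium = "pf1",
                                   types = c("NH", "CAHA"),
                                   cone = 0.75) {
  bv <- build_bond_vectors(truth$ground, types)
  z <- truth$tensors[[medium]]$eigenvectors[, 3]
  ct <- abs(as.matrix(bv[c("vx", "vy", "vz")]) %*% z)[, 1]
  names(ct) <- paste(bv$residue, bv$type)
  sub <- rdc[rdc$medium == medium & rdc$type %in% types, ]
  sel <- ct[paste(sub$residue, sub$type)] < cone
  out <- sub[!is.na(sel) & sel, ]
  rownames(out) <- NULL
  class(out) <- c("rdc_table", "data.frame")
  out
}

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds independent Gaussian noise to every atomic coordinate,
#' emulating an imperfect reference model (coordinate error plus
#' unmodeled internal motion) relative to the true average structure.
#' Used to study how model imperfection attenuates SVD-fitted
#' alignment-tensor magnitudes.
#'
#' @param x a [structure_model()].
#' @param sigma coordinate noise in Angstrom.
#' @param seed integer seed.
#' @return the perturbed [structure_model()].
#' @export
perturb_structure <- function(x, sigma = 0.15, seed = 1) {
  .with_seed(seed, {
    xyz <- as.matrix(x$atoms[c("x", "y", "z")])
    x$atoms[c("x", "y", "z")] <-
      xyz + matrix(stats::rnorm(length(xyz), 0, sigma), ncol = 3)
  })
  x$metadata <- paste(x$metadata, "(perturbed)")
  x
}

#' Assemble the default synthetic ground truth
#'
#' Bundles the study conditions emulated by the generator: a
#' 166-residue two-conformer ensemble with a 30% minor population and
#' localized sub-3-Angstrom displacements; two alignment media with
#' distinct tensors (magnitudes on the N-H scale typical of Pf1 phage
#' and bicelle alignment); per-probe two-site exchange parameters with
#' a 15% CPMG-visible minor population and kex of 1000 /s at 25 C,
#' Arrhenius-coupled so that the minor population grows on cooling
#' (about 26% at 2 C); and measurement noise at the stated precisions
#' (0.5 Hz N-H, 1.0 Hz CA-HA, 0.2 Hz N-C'/HN-C', 0.3 /s R2eff).
#'
#' @param n_residues chain length.
#' @param minor_weight minor-conformer population for RDC averaging.
#' @param seed integer seed.
#' @param max_displacement passed to [make_two_state_structures()].
#' @param segments displaced segments; by default the two
#'   strand/helix analogues, rescaled with the chain length.
#' @return an object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(n_residues = 166, minor_weight = 0.30,
                            seed = 1, max_displacement = 2.8,
                            segments = NULL) {
  if (is.null(segments))   # displaced beta5/beta6 + alpha4 analogues
    segments <- lapply(list(c(105, 118), c(125, 140)),
                       function(s) pmax(2, round(s * n_residues / 166)))
  st <- make_two_state_structures(n_residues = n_residues,
                                  segments = segments,
                                  max_displacement = max_displacement,
                                  seed = seed)
  tensors <- .with_seed(seed + 1000L, {
    repeat {
      r1 <- .random_rotation(); r2 <- .random_rotation()
      # require visibly different principal axes
      if (abs(sum(r1[, 3] * r2[, 3])) < 0.9) break
    }
    list(pf1 = tensor_from_params(-13, 0.30, r1),
         bicelles = tensor_from_params(8.5, 0.55, r2))
  })
  probes <- c(21L, 24L, 36L, 55L, 100L, 139L, 142L)
  probes <- probes[probes <= n_residues]
  exch <- list(
    residues = probes,
    dw_ppm = c(1.6, 0.9, 2.4, 1.3, 0.7, 1.1, 1.9)[seq_along(probes)],
    r2_base = c(11, 9, 10, 12, 8, 9, 10)[seq_along(probes)],
    k1 = arrhenius_law(ea_kj = 40, k_ref = 150),
    km1 = arrhenius_law(ea_kj = 60, k_ref = 850),
    nucleus = "13C", field_mhz = 700, t_cp = 0.020)
  structure(list(
    ground = st$ground, minor = st$minor,
    displacement = st$displacement,
    minor_weight = minor_weight,
    tensors = tensors,
    exchange = exch,
    switch_regions = region_selection(),
    noise = list(rdc = c(NH = 0.5, CAHA = 1.0, NC = 0.2, HNC = 0.2),
                 r2eff = 0.3),
    seed = seed), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d residues, minor weight %.2f, max displacement %.2f A, seed %d\n",
    length(unique(x$ground$atoms$resno)), x$minor_weight,
    max(x$displacement), x$seed))
  invisible(x)
}

#' Simulate multi-medium RDC tables from a synthetic truth
#'
#' Back-calculates population-weighted couplings
#' `D = (1 - w) D(ground) + w D(minor)` for every requested type and
#' medium, adds Gaussian noise at the per-type precision, removes
#' switch-region residues (emulating exchange broadening) and a random
#' fraction of further residues (incomplete assignment), and tags each
#' record with its error.
#'
#' @param truth a [synthetic_truth()].
#' @param types coupling types to simulate.
#' @param media alignment media (names into `truth$tensors`).
#' @param completeness fraction of measurable residues retained.
#' @param noise named per-type Gaussian sigma in Hz; use 0 for
#'   noise-free data.
#' @param weights override the conformer weights
#'   `c(ground, minor)` (default from `truth$minor_weight`).
#' @param seed seed (default derived from the truth's).
#' @return an `"rdc_table"` data frame.
#' @export
simulate_rdc_sets <- function(truth, types = .RDC_TYPES,
                              media = names(truth$tensors),
                              completeness = 0.92,
                              noise = truth$noise$rdc,
                              weights = c(1 - truth$minor_weight,
                                          truth$minor_weight),
                              seed = truth$seed + 2000L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  z3 <- vapply(media, function(m) truth$tensors[[m]]$eigenvectors[, 3],
               numeric(3))
  if (length(media) > 1 && abs(sum(z3[, 1] * z3[, 2])) > 0.98)
    warning("media tensors nearly collinear: degenerate information")
  ens <- ensemble_model(list(truth$ground, truth$minor), weights)
  drop_res <- region_residues(truth$switch_regions)
  out <- list()
  .with_seed(seed, {
    for (m in media) {
      pred <- ensemble_rdc(ens, truth$tensors[[m]], types)
      pred <- pred[!(pred$residue %in% drop_res), ]
      for (tt in unique(pred$type)) {
        sub <- pred[pred$type == tt, ]
        keep <- stats::runif(nrow(sub)) <= completeness
        sub <- sub[keep, ]
        sig <- if (length(noise) > 1) noise[[tt]] else noise
        out[[length(out) + 1]] <- data.frame(
          residue = sub$residue, type = tt, medium = m,
          value = sub$value + stats::rnorm(nrow(sub), 0, sig),
          error = rep(max(sig, 1e-6), nrow(sub)),
          stringsAsFactors = FALSE)
      }
    }
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("rdc_table", "data.frame")
  tab
}

# rates and populations implied by the truth's Arrhenius pair
.truth_rates <- function(truth, temperature) {
  k1 <- arrhenius_k(truth$exchange$k1, temperature)
  km1 <- arrhenius_k(truth$exchange$km1, temperature)
  list(k1 = k1, km1 = km1, kex = k1 + km1, pb = k1 / (k1 + km1))
}

#' Simulate multi-temperature CPMG dispersion tables
#'
#' Generates R2eff profiles for each probe residue at each temperature
#' from the exact two-site model, with rates following the truth's
#' Arrhenius pair, the shift difference fixed across temperature, and
#' intrinsic R2 increasing modestly on cooling.  The 100, 400 and
#' 1000 Hz points are repeated, and Gaussian noise at sigma is added
#' to every point (replicates are independent).
#'
#' @param truth a [synthetic_truth()].
#' @param temperatures in K (default 20, 25, 30 C).
#' @param nu_grid base CPMG frequencies in Hz.
#' @param replicate_nu frequencies measured twice.
#' @param noise Gaussian sigma on R2eff in 1/s.
#' @param seed seed.
#' @return a `"dispersion_table"` data frame with `nucleus` and
#'   `field` columns.
#' @export
simulate_dispersion <- function(truth,
                                temperatures = c(293.15, 298.15, 303.15),
                                nu_grid = c(100, 200, 400, 500, 800, 1000),
                                replicate_nu = c(100, 400, 1000),
                                noise = truth$noise$r2eff,
                                seed = truth$seed + 3000L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ex <- truth$exchange
  nus <- sort(c(nu_grid, replicate_nu))
  out <- list()
  .with_seed(seed, {
    for (ti in seq_along(temperatures)) {
      tt <- temperatures[ti]
      rt <- .truth_rates(truth, tt)
      for (ri in seq_along(ex$residues)) {
        r2_0 <- ex$r2_base[ri] * (1 + 0.02 * (298.15 - tt))
        p <- two_site_params(pb = rt$pb, kex = rt$kex,
                             dw_ppm = ex$dw_ppm[ri],
                             r2a = r2_0, nucleus = ex$nucleus,
                             field_mhz = ex$field_mhz)
        r2 <- r2eff_exact(p, nus, ex$t_cp)
        out[[length(out) + 1]] <- data.frame(
          residue = ex$residues[ri], temperature = tt,
          nu_cpmg = nus,
          r2eff = r2 + stats::rnorm(length(nus), 0, noise),
          sigma = rep(max(noise, 1e-6), length(nus)),
          nucleus = ex$nucleus, field = ex$field_mhz,
          stringsAsFactors = FALSE)
      }
    }
  })
  tab <- do.call(rbind, out)
  key <- paste(tab$residue, tab$temperature, tab$nu_cpmg)
  tab$rep <- stats::ave(seq_len(nrow(tab)), key, FUN = seq_along)
  rownames(tab) <- NULL
  class(tab) <- c("dispersion_table", "data.frame")
  tab
}

#' Simulate a temperature series of 1D exchange spectra
#'
#' Evaluates the two-site McConnell lineshape of one probe at each
#' temperature, with rates and populations from the truth's Arrhenius
#' pair: a single averaged line at high temperature, splitting into
#' resolved major/minor peaks as cooling slows the exchange.
#'
#' @param truth a [synthetic_truth()].
#' @param temperatures in K, low to high.
#' @param residue probe residue (default the first exchange probe).
#' @param r2 intrinsic linewidth parameter in 1/s.
#' @param n_points grid size.
#' @return list of `"spectrum_grid"` objects, one per temperature,
#'   each with attribute `"temperature"`.
#' @export
simulate_spectrum_series <- function(truth,
                                     temperatures = c(275.15, 280.15,
                                                      285.15, 292.15,
                                                      300.15, 308.15),
                                     residue = truth$exchange$residues[1],
                                     r2 = 20, n_points = 4096) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ex <- truth$exchange
  ri <- match(residue, ex$residues)
  if (is.na(ri)) stop("residue is not an exchange probe")
  dw <- 2 * pi * ex$dw_ppm[ri] * larmor_mhz(ex$nucleus, ex$field_mhz)
  grid <- seq(-1.5 * dw, 2.5 * dw, length.out = n_points)
  lapply(temperatures, function(tt) {
    rt <- .truth_rates(truth, tt)
    sp <- lineshape_1d(populations = c(1 - rt$pb, rt$pb),
                       offsets = c(0, dw), r2 = c(r2, r2),
                       kex = rt$kex, grid = grid)
    attr(sp, "temperature") <- tt
    sp
  })
}
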