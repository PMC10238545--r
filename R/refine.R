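# Population-weighted N = 2 ensemble refinement: the ground conformer
# is fixed to the crystal structure, the minor conformer is refined by
# restrained Cartesian minimization against multi-medium RDC sets
# under a local-geometry elastic network, a 3 Angstrom displacement
# cap and optional backbone dihedral restraints.  Leave-one-set-out
# cross-validation yields R-free; a grid over the minor population
# locates the optimal ratio.

#' Refinement configuration
#'
#' @param max_displacement cap on atomic departures from the starting
#'   coordinates, Angstrom (default 3.0).
#' @param k_rdc force weight of every RDC restraint set (multiplies
#'   the error-weighted chi-square term).
#' @param k_geom multiplier on the local-geometry elastic network.
#' @param k_contact force constant of the weak long-range CA-CA
#'   contact springs (sequence separation >= 3, reference distance
#'   < 9 Angstrom) that preserve the tertiary fold; set 0 to disable.
#' @param k_disp force constant of the flat-bottom displacement cap.
#' @param k_dihe force constant of the flat-bottom dihedral restraints
#'   (per rad^2).
#' @param dihedral_restraints optional data frame `residue`, `angle`
#'   (`"phi"`/`"psi"`), `target` and `halfwidth` in degrees.
#' @param n_runs number of random-start minimizations (default 100).
#' @param n_keep number of lowest-energy runs reported (default 10).
#' @param start_sigma Gaussian coordinate noise (Angstrom) applied to
#'   the mobile atoms of each random start.
#' @param maxit minimizer iteration budget per run.
#' @param seed integer seed.
#' @param flat_tol relative spread of the cross-validated score below
#'   which a population grid is declared flat (no identifiable
#'   optimum).
#' @return a list of class `"refinement_config"`.
#' @export
refinement_config <- function(max_displacement = 3.0, k_rdc = 0.3,
                              k_geom = 20, k_contact = 2,
                              k_disp = 50, k_dihe = 30,
                              dihedral_restraints = NULL,
                              n_runs = 100, n_keep = 10,
                              start_sigma = 0.25, maxit = 600, seed = 1,
                              flat_tol = 0.02) {
  if (max_displacement <= 0) stop("max_displacement must be > 0")
  if (n_keep > n_runs) stop("n_keep must not exceed n_runs")
  structure(list(max_displacement = max_displacement, k_rdc = k_rdc,
                 k_geom = k_geom, k_contact = k_contact,
                 k_disp = k_disp, k_dihe = k_dihe,
                 dihedral_restraints = dihedral_restraints,
                 n_runs = n_runs, n_keep = n_keep,
                 start_sigma = start_sigma, maxit = maxit, seed = seed,
                 flat_tol = flat_tol),
            class = "refinement_config")
}

#' Backbone dihedral restraints taken from a structure
#'
#' Extracts phi/psi from a (target) structure and formats them as the
#' generic flat-bottom dihedral restraints consumed by the refinement
#' (the role chemical-shift-derived dihedral predictions play on real
#' data).
#'
#' @param x a [structure_model()].
#' @param residues residues to restrain (default all with defined
#'   angles).
#' @param halfwidth flat-bottom halfwidth in degrees.
#' @return data frame `residue`, `angle`, `target`, `halfwidth`.
#' @export
dihedral_restraints_from <- function(x, residues = NULL, halfwidth = 5) {
  pp <- .phi_psi(x)
  if (!is.null(residues)) pp <- pp[pp$residue %in% residues, ]
  out <- rbind(
    data.frame(residue = pp$residue, angle = "phi", target = pp$phi,
               halfwidth = halfwidth),
    data.frame(residue = pp$residue, angle = "psi", target = pp$psi,
               halfwidth = halfwidth))
  out[!is.na(out$target), ]
}

# assemble the minimization system: heavy-atom coordinates, elastic
# pairs, cap, dihedral quads and per-set RDC restraint blocks.  RDC
# vectors involving protons are rigid analytic functions of the heavy
# atoms (ideal-geometry construction), so fitting an RDC can only
# reorient the local backbone, never an isolated bond vector.
.make_refine_system <- function(ground, rdc, tensors, config) {
  gh <- ground
  a <- gh$atoms
  X0 <- as.matrix(a[c("x", "y", "z")])
  row_of <- function(resno, atom) {
    m <- match(paste(resno, atom), paste(a$resno, a$atom))
    m
  }
  pairs <- .elastic_pairs(a$resno, a$atom, X0,
                          k_bond = 200 * config$k_geom,
                          k_13 = 50 * config$k_geom,
                          k_14 = 20 * config$k_geom)
  if (config$k_contact > 0) {
    cp <- .contact_pairs(a$resno, a$atom, X0, k = config$k_contact)
    if (!is.null(cp)) pairs <- rbind(pairs, cp)
  }
  quads <- NULL
  dr <- config$dihedral_restraints
  if (!is.null(dr) && nrow(dr)) {
    at4 <- function(angle, r) {
      if (angle == "phi") cbind(row_of(r - 1, "C"), row_of(r, "N"),
                                row_of(r, "CA"), row_of(r, "C"))
      else cbind(row_of(r, "N"), row_of(r, "CA"), row_of(r, "C"),
                 row_of(r + 1, "N"))
    }
    qq <- do.call(rbind, lapply(seq_len(nrow(dr)), function(i) {
      m <- at4(dr$angle[i], dr$residue[i])
      data.frame(i1 = m[1], i2 = m[2], i3 = m[3], i4 = m[4],
                 target = dr$target[i] * pi / 180,
                 halfwidth = dr$halfwidth[i] * pi / 180,
                 k = config$k_dihe)
    }))
    quads <- qq[stats::complete.cases(qq), ]
  }
  # RDC restraint blocks, one per (medium, type) set
  sets <- unique(rdc[c("medium", "type")])
  gvec <- build_bond_vectors(gh)   # ground-state vectors (fixed)
  blocks <- list()
  for (si in seq_len(nrow(sets))) {
    med <- sets$medium[si]; typ <- sets$type[si]
    if (!med %in% names(tensors))
      stop("no tensor supplied for medium ", med)
    obs <- rdc[rdc$medium == med & rdc$type == typ, ]
    idx <- switch(typ,
      NH = list(iN = row_of(obs$residue, "N"),
                iCA = row_of(obs$residue, "CA"),
                iCp = row_of(obs$residue - 1L, "C")),
      CAHA = list(iCA = row_of(obs$residue, "CA"),
                  iN = row_of(obs$residue, "N"),
                  iC = row_of(obs$residue, "C"),
                  iCB = row_of(obs$residue, "CB")),
      NC = list(iN = row_of(obs$residue, "N"),
                iCp = row_of(obs$residue - 1L, "C")),
      HNC = list(iN = row_of(obs$residue, "N"),
                 iCA = row_of(obs$residue, "CA"),
                 iCp = row_of(obs$residue - 1L, "C")))
    ok <- Reduce(`&`, lapply(idx, function(v) !is.na(v)))
    obs <- obs[ok, ]
    idx <- lapply(idx, function(v) v[ok])
    gv <- gvec[gvec$type == typ, ]
    m <- match(obs$residue, gv$residue)
    if (anyNA(m))
      stop("restraint/residue mismatch for set ", med, "/", typ)
    dg <- back_calc_rdc(gv[m, ], tensors[[med]])
    blocks[[paste(med, typ)]] <- c(idx, list(
      medium = med, type = typ,
      scale = rdc_type_scale(typ), S = tensors[[med]]$matrix,
      dobs = obs$value, dg = dg, sigma = obs$error,
      residue = obs$residue, k = config$k_rdc))
  }
  list(atoms = a, X0 = X0, pairs = pairs, quads = quads,
       blocks = blocks, ground = gh)
}

# rowwise helpers for the analytic RDC vector constructions
.runit <- function(u) {
  r <- sqrt(rowSums(u^2))
  list(u = u / r, r = r)
}
.rproj <- function(uhat, r, g) (g - uhat * rowSums(uhat * g)) / r

# predicted couplings of one restraint block and, when `coefD` (the
# per-record dE/dD) is given, the gradient contributions as a list of
# (index vector, gradient matrix) pairs
.rdc_block <- function(X, b, coefD = NULL) {
  S <- b$S; cc <- b$scale
  qform <- function(vh) rowSums((vh %*% S) * vh)
  gq <- function(vh, r, q)   # dD/dv for D = cc * vhat' S vhat
    (2 * cc / r) * (vh %*% S - q * vh)
  if (b$type == "NC") {
    v <- X[b$iCp, , drop = FALSE] - X[b$iN, , drop = FALSE]
    vu <- .runit(v); q <- qform(vu$u)
    D <- cc * q
    if (is.null(coefD)) return(list(D = D))
    gv <- gq(vu$u, vu$r, q) * coefD
    return(list(D = D, grads = list(list(b$iCp, gv), list(b$iN, -gv))))
  }
  if (b$type == "NH") {
    u1 <- .runit(X[b$iCA, , drop = FALSE] - X[b$iN, , drop = FALSE])
    u2 <- .runit(X[b$iCp, , drop = FALSE] - X[b$iN, , drop = FALSE])
    s <- u1$u + u2$u
    su <- .runit(s); q <- qform(su$u)
    D <- cc * q                      # sign of the N-H vector cancels
    if (is.null(coefD)) return(list(D = D))
    gs <- gq(su$u, su$r, q) * coefD
    g1 <- .rproj(u1$u, u1$r, gs)
    g2 <- .rproj(u2$u, u2$r, gs)
    return(list(D = D, grads = list(list(b$iCA, g1), list(b$iCp, g2),
                                    list(b$iN, -(g1 + g2)))))
  }
  if (b$type == "CAHA") {
    u1 <- .runit(X[b$iN, , drop = FALSE] - X[b$iCA, , drop = FALSE])
    u2 <- .runit(X[b$iC, , drop = FALSE] - X[b$iCA, , drop = FALSE])
    u3 <- .runit(X[b$iCB, , drop = FALSE] - X[b$iCA, , drop = FALSE])
    s <- u1$u + u2$u + u3$u
    su <- .runit(s); q <- qform(su$u)
    D <- cc * q
    if (is.null(coefD)) return(list(D = D))
    gs <- gq(su$u, su$r, q) * coefD
    g1 <- .rproj(u1$u, u1$r, gs)
    g2 <- .rproj(u2$u, u2$r, gs)
    g3 <- .rproj(u3$u, u3$r, gs)
    return(list(D = D, grads = list(list(b$iN, g1), list(b$iC, g2),
                                    list(b$iCB, g3),
                                    list(b$iCA, -(g1 + g2 + g3)))))
  }
  # HNC: amide proton H = N - l * shat; vector H -> C'(i-1)
  l <- .BOND_NH
  u1 <- .runit(X[b$iCA, , drop = FALSE] - X[b$iN, , drop = FALSE])
  u2c <- X[b$iCp, , drop = FALSE] - X[b$iN, , drop = FALSE]
  u2 <- .runit(u2c)
  s <- u1$u + u2$u
  su <- .runit(s)
  v <- u2c + l * su$u
  vu <- .runit(v); q <- qform(vu$u)
  D <- cc * q
  if (is.null(coefD)) return(list(D = D))
  gv <- gq(vu$u, vu$r, q) * coefD
  pgv <- .rproj(su$u, su$r, gv)
  br1 <- .rproj(u1$u, u1$r, pgv)
  br2 <- .rproj(u2$u, u2$r, pgv)
  list(D = D, grads = list(list(b$iCA, l * br1),
                           list(b$iCp, gv + l * br2),
                           list(b$iN, -gv - l * (br1 + br2))))
}

# total energy and gradient of the minor conformer coordinates
.refine_energy <- function(xv, sys, w, config) {
  X <- matrix(xv, ncol = 3)
  pe <- .pair_energy(X, sys$pairs)
  E <- pe$E; G <- pe$G
  ce <- .cap_energy(X, sys$X0, config$max_displacement, config$k_disp)
  E <- E + ce$E; G <- G + ce$G
  dihe_e <- 0
  if (!is.null(sys$quads) && nrow(sys$quads)) {
    de <- .dihedral_energy(X, sys$quads)
    E <- E + de$E; G <- G + de$G
    dihe_e <- de$E
  }
  rdc_e <- 0
  for (b in sys$blocks) {
    pred0 <- .rdc_block(X, b)
    resid <- (b$dobs - (1 - w) * b$dg - w * pred0$D) / b$sigma
    Eb <- b$k * sum(resid^2)
    E <- E + Eb; rdc_e <- rdc_e + Eb
    coefD <- b$k * 2 * resid * (-w) / b$sigma    # dE/dD per record
    bg <- .rdc_block(X, b, coefD)
    for (g in bg$grads) G <- .acc_grad(G, g[[1]], g[[2]])
  }
  list(E = E, G = G, rdc = rdc_e, dihedral = dihe_e)
}

# per-set fit rmsd (Hz, natural units) of an ensemble prediction
.block_rmsd <- function(sys, Xm, w) {
  vapply(sys$blocks, function(b) {
    dm <- .rdc_block(Xm, b)$D
    sqrt(mean((b$dobs - (1 - w) * b$dg - w * dm)^2))
  }, numeric(1))
}

#' Two-state ensemble refinement of a minor conformer against RDCs
#'
#' Refines the excited-state (minor) conformer of a population-
#' weighted N = 2 ensemble whose major conformer is fixed to the
#' ground-state structure.  The energy is the sum of error-weighted
#' RDC terms over all restraint sets, with each coupling predicted as
#' `(1 - w) D(ground) + w D(minor)`, a local-geometry elastic network,
#' a flat-bottom cap that keeps every atom within
#' `config$max_displacement` of its start, and optional flat-bottom
#' dihedral restraints.  `n_runs` minimizations are started from the
#' ground coordinates perturbed by Gaussian noise; all runs are
#' returned sorted by energy and the `n_keep` lowest-energy minor
#' conformers form the reported ensemble.
#'
#' @param ground the ground-state [structure_model()] (held fixed).
#' @param rdc an `"rdc_table"` with all media and types to use.
#' @param tensors named list of `"alignment_tensor"` objects, one per
#'   medium, pre-fitted (and magnitude-corrected) and held fixed.
#' @param config a [refinement_config()].
#' @param w minor-conformer population in (0, 1).
#' @return an object of class `"ensemble_refit"`: runs sorted by
#'   energy (`energies`, `converged`), the kept minor conformers
#'   (`conformers`, proton-completed), per-set fit rmsd of the best
#'   run, and the [ensemble_model()] of ground plus best minor.
#' @export
refine_two_state <- function(ground, rdc, tensors, config, w) {
  stopifnot(inherits(config, "refinement_config"))
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)")
  sys <- .make_refine_system(ground, rdc, tensors, config)
  nx <- nrow(sys$X0)
  # fn and gr share one evaluation through a last-point cache
  cache <- new.env(parent = emptyenv())
  evalc <- function(xv) {
    if (!is.null(cache$x) && identical(cache$x, xv)) return(cache$v)
    v <- .refine_energy(xv, sys, w, config)
    cache$x <- xv; cache$v <- v
    v
  }
  runs <- .with_seed(config$seed, {
    lapply(seq_len(config$n_runs), function(r) {
      X1 <- sys$X0 + matrix(stats::rnorm(nx * 3, 0, config$start_sigma),
                            nx, 3)
      e0 <- .refine_energy(as.numeric(X1), sys, w, config)$E
      opt <- tryCatch(
        stats::optim(as.numeric(X1),
                     fn = function(xv) evalc(xv)$E,
                     gr = function(xv) as.numeric(evalc(xv)$G),
                     method = "L-BFGS-B",
                     control = list(maxit = config$maxit, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) return(NULL)
      list(X = matrix(opt$par, ncol = 3), energy = opt$value,
           energy0 = e0, converged = opt$convergence == 0)
    })
  })
  ok <- !vapply(runs, is.null, TRUE)
  if (!any(ok)) stop("all refinement runs diverged")
  if (any(!ok))
    warning(sum(!ok), " run(s) diverged and were discarded")
  runs <- runs[ok]
  en <- vapply(runs, `[[`, 1, "energy")
  ord <- order(en)
  runs <- runs[ord]; en <- en[ord]
  keep <- seq_len(min(config$n_keep, length(runs)))
  conformers <- lapply(runs[keep], function(rn) {
    st <- structure_model(
      within(sys$atoms, { x <- rn$X[, 1]; y <- rn$X[, 2]; z <- rn$X[, 3] }),
      metadata = "refined minor conformer")
    st
  })
  terms <- .refine_energy(as.numeric(runs[[1]]$X), sys, w, config)
  structure(list(
    w = w, energies = en,
    energy0 = vapply(runs, `[[`, 1, "energy0"),
    converged = vapply(runs, `[[`, TRUE, "converged"),
    kept = keep, conformers = conformers,
    set_rmsd = .block_rmsd(sys, runs[[1]]$X, w),
    rdc_energy = terms$rdc, dihedral_energy = terms$dihedral,
    ensemble = ensemble_model(list(ground, conformers[[1]]),
                              c(1 - w, w)),
    system = sys, config = config),
    class = "ensemble_refit")
}

#' @export
print.ensemble_refit <- function(x, ...) {
  cat(sprintf(
    "N = 2 ensemble refinement: w(minor) = %.2f, %d runs (%d kept)\n",
    x$w, length(x$energies), length(x$kept)))
  cat(sprintf("  energy best/median: %.2f / %.2f\n",
              x$energies[1], stats::median(x$energies)))
  cat("  per-set fit rmsd (Hz):\n")
  print(round(x$set_rmsd, 3))
  invisible(x)
}

# mean minor-conformer RDC prediction over the kept runs of a refit,
# for one restraint block (indices refer to the shared atom layout)
.kept_prediction <- function(refit, b) {
  preds <- vapply(refit$conformers, function(cf) {
    X <- as.matrix(cf$atoms[c("x", "y", "z")])
    .rdc_block(X, b)$D
  }, numeric(length(b$dobs)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Leave-one-set-out R-free cross-validation
#'
#' For each RDC set (one coupling type in one medium, or the subset
#' named in `sets`), the two-state refinement is repeated with that
#' set entirely excluded from every energy term, and the held-out set
#' is scored against the population-weighted prediction of the
#' resulting ensemble (averaged over the kept runs): the
#' cross-validated R-free.  For comparison the same set is scored
#' against the ground-state (N = 1) prediction alone.
#'
#' @inheritParams refine_two_state
#' @param sets optional data frame `medium`, `type` naming the sets to
#'   hold out (default: every set present in `rdc`).
#' @return data frame of class `"rfree_table"`: per held-out set the
#'   number of couplings, `r_free` (N = 2) and `r_n1` (ground only),
#'   plus the mean dihedral restraint energy of the refits.
#' @export
crossval_rfree <- function(ground, rdc, tensors, config, w,
                           sets = NULL) {
  allsets <- unique(rdc[c("medium", "type")])
  if (nrow(allsets) < 2) stop("need at least two RDC sets")
  if (is.null(sets)) sets <- allsets
  out <- lapply(seq_len(nrow(sets)), function(si) {
    med <- sets$medium[si]; typ <- sets$type[si]
    hold <- rdc$medium == med & rdc$type == typ
    if (!any(hold)) stop("held-out set not present: ", med, "/", typ)
    refit <- refine_two_state(ground, rdc[!hold, ], tensors, config, w)
    # score the held-out set against the refit ensemble
    sysfull <- .make_refine_system(ground, rdc[hold, ], tensors, config)
    b <- sysfull$blocks[[1]]
    dm <- .kept_prediction(refit, b)
    pred <- (1 - w) * b$dg + w * dm
    tn <- tensors[[med]]
    sc <- b$scale
    qf <- quality_factors(b$dobs / sc, pred / sc, tn$da, tn$rhombicity)
    qn1 <- quality_factors(b$dobs / sc, b$dg / sc, tn$da, tn$rhombicity)
    data.frame(medium = med, type = typ, n = length(b$dobs),
               r_free = qf$r, r_n1 = qn1$r,
               rmsd_free = qf$rmsd * abs(sc),
               dihedral_energy = refit$dihedral_energy,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  class(tab) <- c("rfree_table", "data.frame")
  tab
}

#' Population-ratio grid search
#'
#' Repeats the N = 2 refinement and leave-one-set-out cross-validation
#' over a grid of minor-population fractions and selects the fraction
#' minimizing the summed cross-validated R-free.  The dihedral
#' restraint energy per fraction is reported alongside as a secondary
#' diagnostic.  If the score varies by less than `config$flat_tol`
#' (relative) across the grid, the diagnostics are flat within noise
#' and `no_optimum` is set.
#'
#' @inheritParams crossval_rfree
#' @param grid minor fractions to test, all in (0, 0.5].
#' @return an object of class `"population_grid"`: diagnostic `table`
#'   (fraction, summed R-free, summed N = 1 R, dihedral energy),
#'   `optimum`, and logical `no_optimum`.
#' @export
population_grid_search <- function(ground, rdc, tensors, config,
                                   grid = seq(0.1, 0.5, by = 0.1),
                                   sets = NULL) {
  if (length(grid) == 0) stop("empty population grid")
  if (any(grid <= 0 | grid > 0.5))
    stop("population grid must lie in (0, 0.5]")
  rows <- lapply(grid, function(w) {
    cv <- crossval_rfree(ground, rdc, tensors, config, w, sets)
    data.frame(w = w, rfree_sum = sum(cv$r_free),
               r_n1_sum = sum(cv$r_n1),
               improved_sets = sum(cv$r_free < cv$r_n1),
               dihedral_energy = mean(cv$dihedral_energy))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$rfree_sum)
  spread <- diff(range(tab$rfree_sum)) / min(tab$rfree_sum)
  # no identifiable optimum when the diagnostics are flat within noise
  # or when no fraction beats the one-state (ground-only) fit
  no_opt <- spread < config$flat_tol ||
    min(tab$rfree_sum) >= tab$r_n1_sum[1]
  structure(list(table = tab, optimum = grid[best],
                 no_optimum = no_opt, spread = spread),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat("Population-ratio grid search (summed cross-validated R-free):\n")
  print(x$table, row.names = FALSE)
  if (x$no_optimum)
    cat("No identifiable optimum: diagnostics flat within noise\n")
  else
    cat(sprintf("Optimal minor fraction: %.2f\n", x$optimum))
  invisible(x)
}

#' Reporting ensemble from a set of refinement runs
#'
#' Selects the `n_keep` lowest-energy minor conformers of a refit and
#' summarizes their spread: rmsd of each to their mean structure and
#' pairwise rmsd to the ground state.
#'
#' @param refit an `"ensemble_refit"`.
#' @param n_keep number of lowest-energy structures to report
#'   (default: the refit's configured number).
#' @return list with `conformers`, `energies`, `rmsd_to_mean`,
#'   `mean_rmsd` and `rmsd_to_ground` (range).
#' @export
select_reporting_ensemble <- function(refit, n_keep = NULL) {
  stopifnot(inherits(refit, "ensemble_refit"))
  if (is.null(n_keep)) n_keep <- length(refit$kept)
  nconv <- sum(refit$converged)
  if (n_keep > length(refit$energies))
    stop("fewer runs than n_keep")
  conf <- refit$conformers[seq_len(min(n_keep, length(refit$conformers)))]
  if (length(conf) < n_keep) {
    # rebuild from stored runs if more are requested than kept
    stop("refit kept fewer conformers than n_keep; rerun with larger n_keep")
  }
  ground <- refit$system$ground
  st <- ensemble_rmsd_stats(conf, ground)
  list(conformers = conf, energies = refit$energies[seq_len(n_keep)],
       rmsd_to_mean = st$rmsd_to_mean, mean_rmsd = st$mean_rmsd,
       rmsd_to_ground = st$range, n_converged = nconv)
}

#' Calibrate the RDC force weight to fit within experimental error
#'
#' Bisection on the common RDC force weight so that the refined
#' ensemble fits the N-H couplings within, but not tighter than, their
#' experimental precision (target fit rmsd inside `band` times the
#' N-H error), the criterion used to avoid overfitting.
#'
#' @inheritParams refine_two_state
#' @param band target rmsd band as multiples of the N-H error
#'   (default `c(1, 2)`).
#' @param max_iter bisection iterations.
#' @return the calibrated [refinement_config()] with the selected
#'   `k_rdc` and the achieved N-H rmsd as attribute `"nh_rmsd"`.
#' @export
calibrate_rdc_weight <- function(ground, rdc, tensors, config, w,
                                 band = c(1, 2), max_iter = 6) {
  cfg <- config
  cfg$n_runs <- 2; cfg$n_keep <- 1
  sig_nh <- stats::median(rdc$error[rdc$type == "NH"])
  lo <- cfg$k_rdc / 64; hi <- cfg$k_rdc * 64
  k <- cfg$k_rdc
  rms <- NA_real_
  for (i in seq_len(max_iter)) {
    cfg$k_rdc <- k
    rf <- refine_two_state(ground, rdc, tensors, cfg, w)
    nh <- rf$set_rmsd[grep("NH$", names(rf$set_rmsd))]
    rms <- mean(nh)
    if (rms > band[2] * sig_nh) { lo <- k; k <- sqrt(k * hi) }
    else if (rms < band[1] * sig_nh) { hi <- k; k <- sqrt(lo * k) }
    else break
  }
  out <- config
  out$k_rdc <- k
  attr(out, "nh_rmsd") <- rms
  out
}
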