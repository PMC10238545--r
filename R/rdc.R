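# RDC geometry and statistics: bond-vector construction (with
# geometric hydrogen building), Saupe-tensor SVD fitting, quality
# factors, ensemble-weighted back-calculation and the sparsity-aware
# tensor-magnitude grid search.

# effective internuclear distances (Angstrom) defining the type-specific
# dipolar constants; geometric build lengths differ slightly (vibrational
# averaging is folded into the effective lengths, not the geometry)
.RDC_REFF <- c(NH = 1.041, CAHA = 1.117, NC = 1.329, HNC = 2.085)
.RDC_NUC <- list(NH = c("15N", "1H"), CAHA = c("13C", "1H"),
                 NC = c("15N", "13C"), HNC = c("1H", "13C"))
.BOND_NH <- 1.02
.BOND_CAHA <- 1.09

# maximal dipolar coupling (Hz) for two nuclei at distance r (Angstrom);
# only ratios between types matter downstream
.dmax_hz <- function(g1, g2, r_ang) {
  mu0 <- 4e-7 * pi; h <- 6.62607015e-34
  -(mu0 * h * g1 * g2) / (16 * pi^3 * (r_ang * 1e-10)^3)
}

#' Dipolar scale factor of a coupling type relative to N-H
#'
#' Computed from gyromagnetic ratios and effective bond lengths
#' (N-H 1.041, CA-HA 1.117, N-C' 1.329, HN-C' 2.085 Angstrom).  All
#' couplings are expressed on the N-H scale by dividing by this factor.
#'
#' @param type coupling type id(s): `"NH"`, `"CAHA"`, `"NC"`, `"HNC"`.
#' @return numeric scale factor(s) (N-H is 1; CA-HA about -2.01).
#' @export
rdc_type_scale <- function(type) {
  ref <- .dmax_hz(.GAMMA[["15N"]], .GAMMA[["1H"]], .RDC_REFF[["NH"]])
  vapply(type, function(tt) {
    tt <- match.arg(tt, .RDC_TYPES)
    g <- .RDC_NUC[[tt]]
    .dmax_hz(.GAMMA[[g[1]]], .GAMMA[[g[2]]], .RDC_REFF[[tt]]) / ref
  }, numeric(1), USE.NAMES = FALSE)
}

.unit <- function(v) {
  n <- sqrt(rowSums(v^2))
  v / n
}

# ideal-geometry amide and alpha protons for every residue where the
# parent heavy atoms exist; returns a data frame of atom records
.ideal_protons <- function(x) {
  res <- residue_numbers(x)
  resname <- x$atoms$resname[match(res, x$atoms$resno)]
  N <- .atom_xyz(x, res, "N"); CA <- .atom_xyz(x, res, "CA")
  C <- .atom_xyz(x, res, "C"); CB <- .atom_xyz(x, res, "CB")
  prev <- match(res - 1L, res)
  Cprev <- C[prev, , drop = FALSE]
  H <- N + .BOND_NH * .unit(-(.unit(CA - N) + .unit(Cprev - N)))
  HA <- CA + .BOND_CAHA * .unit(-(.unit(N - CA) + .unit(C - CA) +
                                    .unit(CB - CA)))
  okH <- resname != "PRO" & is.finite(H[, 1])
  okHA <- resname != "GLY" & is.finite(HA[, 1])
  ch <- x$atoms$chain[1]
  rbind(
    data.frame(chain = ch, resno = res[okH], resname = resname[okH],
               atom = "H", element = "H", x = H[okH, 1], y = H[okH, 2],
               z = H[okH, 3], stringsAsFactors = FALSE),
    data.frame(chain = ch, resno = res[okHA], resname = resname[okHA],
               atom = "HA", element = "H", x = HA[okHA, 1],
               y = HA[okHA, 2], z = HA[okHA, 3], stringsAsFactors = FALSE))
}

# structure with ideal protons appended (file protons take precedence)
.with_protons <- function(x) {
  pro <- .ideal_protons(x)
  have <- paste(x$atoms$resno, x$atoms$atom)
  pro <- pro[!(paste(pro$resno, pro$atom) %in% have), ]
  x$atoms <- rbind(x$atoms, pro)
  x$atoms <- x$atoms[order(x$atoms$resno), ]
  rownames(x$atoms) <- NULL
  x
}

#' Construct internuclear unit vectors for RDC back-calculation
#'
#' Builds the bond (or internuclear) unit vectors of the requested
#' coupling types from backbone coordinates.  Amide and alpha protons
#' absent from crystal structures are reconstructed by ideal geometry:
#' HN on the external bisector of CA-N-C'(i-1) at 1.02 Angstrom, HA by
#' tetrahedral completion of N/C'/CB around CA at 1.09 Angstrom.  N-C'
#' couples N(i) to the preceding carbonyl C'(i-1); HN-C' couples the
#' amide proton to C'(i-1).  Prolines carry no N-H (or HN-C') vector;
#' glycines carry no CA-HA vector; residues missing a required heavy
#' atom are skipped with a warning.
#'
#' @param x a [structure_model()].
#' @param types coupling types to build (default all four).
#' @return data frame of class `"bond_vectors"`: `residue`, `type`,
#'   unit-vector components `vx`, `vy`, `vz`, and the dipolar `scale`
#'   relative to N-H.
#' @export
build_bond_vectors <- function(x, types = .RDC_TYPES) {
  stopifnot(inherits(x, "structure_model"))
  types <- match.arg(types, .RDC_TYPES, several.ok = TRUE)
  res <- residue_numbers(x)
  resname <- x$atoms$resname[match(res, x$atoms$resno)]
  N <- .atom_xyz(x, res, "N"); CA <- .atom_xyz(x, res, "CA")
  C <- .atom_xyz(x, res, "C"); CB <- .atom_xyz(x, res, "CB")
  Hfile <- .atom_xyz(x, res, "H")
  HAfile <- .atom_xyz(x, res, "HA")
  prev <- match(res - 1L, res)     # index of preceding residue
  Cprev <- C[prev, , drop = FALSE]

  # amide proton: use the file's if present, else external bisector
  Hpos <- Hfile
  missH <- is.na(Hpos[, 1])
  if (any(missH)) {
    u <- -(.unit(CA - N) + .unit(Cprev - N))
    Hbuilt <- N + .BOND_NH * .unit(u)
    Hpos[missH, ] <- Hbuilt[missH, ]
  }
  HApos <- HAfile
  missHA <- is.na(HApos[, 1])
  if (any(missHA)) {
    u <- -(.unit(N - CA) + .unit(C - CA) + .unit(CB - CA))
    HAbuilt <- CA + .BOND_CAHA * .unit(u)
    HApos[missHA, ] <- HAbuilt[missHA, ]
  }

  out <- list()
  add <- function(type, from, to, keep) {
    v <- to - from
    ok <- keep & is.finite(v[, 1]) & is.finite(from[, 1])
    nskip <- sum(keep & !ok)
    if (nskip > 0)
      warning(nskip, " residue(s) missing heavy atoms for ", type,
              " vectors; skipped")
    v <- .unit(v[ok, , drop = FALSE])
    data.frame(residue = res[ok], type = type,
               vx = v[, 1], vy = v[, 2], vz = v[, 3],
               scale = rdc_type_scale(type), stringsAsFactors = FALSE)
  }
  notpro <- resname != "PRO"
  notfirst <- !is.na(prev)
  if ("NH" %in% types)
    out$NH <- add("NH", N, Hpos, notpro & notfirst)
  if ("CAHA" %in% types)
    out$CAHA <- add("CAHA", CA, HApos, resname != "GLY")
  if ("NC" %in% types)
    out$NC <- add("NC", N, Cprev, notfirst)
  if ("HNC" %in% types)
    out$HNC <- add("HNC", Hpos, Cprev, notpro & notfirst)
  bv <- do.call(rbind, out)
  rownames(bv) <- NULL
  class(bv) <- c("bond_vectors", "data.frame")
  bv
}

#' Alignment (Saupe) tensor
#'
#' `alignment_tensor()` constructs the tensor from its five independent
#' traceless-symmetric components on the N-H Hz scale (order
#' `Sxx, Syy, Sxy, Sxz, Syz`); `tensor_from_params()` constructs it
#' from magnitude, rhombicity and orientation.  Derived quantities
#' follow the usual conventions: eigenvalues ordered
#' `|Szz| >= |Syy| >= |Sxx|`, magnitude `Da = Szz / 2` (Hz, N-H scale)
#' and rhombicity `R = (2/3) (Sxx - Syy) / Szz`, which lies in
#' `[0, 2/3]`.
#'
#' @param s5 numeric length-5 Saupe vector `(Sxx, Syy, Sxy, Sxz, Syz)`.
#' @return an object of class `"alignment_tensor"` with elements
#'   `s5`, `matrix` (traceless symmetric 3x3), `da`, `rhombicity`,
#'   `eigenvalues`, `eigenvectors` (columns x, y, z of the tensor
#'   frame) and `euler` (z-y-z angles, radians).
#' @export
alignment_tensor <- function(s5) {
  stopifnot(is.numeric(s5), length(s5) == 5)
  S <- matrix(c(s5[1], s5[3], s5[4],
                s5[3], s5[2], s5[5],
                s5[4], s5[5], -s5[1] - s5[2]), 3, 3)
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))          # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]
  szz <- vals[3]
  da <- szz / 2
  rh <- (2 / 3) * (vals[1] - vals[2]) / szz
  # z-y-z Euler angles of the frame rotation
  beta <- acos(max(-1, min(1, vecs[3, 3])))
  if (abs(sin(beta)) > 1e-8) {
    alpha <- atan2(vecs[2, 3], vecs[1, 3])
    gamma <- atan2(vecs[3, 2], -vecs[3, 1])
  } else {
    alpha <- atan2(vecs[2, 1], vecs[1, 1]); gamma <- 0
  }
  structure(list(s5 = s5, matrix = S, da = da, rhombicity = rh,
                 eigenvalues = vals, eigenvectors = vecs,
                 euler = c(alpha = alpha, beta = beta, gamma = gamma)),
            class = "alignment_tensor")
}

#' @rdname alignment_tensor
#' @param da tensor magnitude in Hz on the N-H scale (`Szz = 2 Da`).
#' @param rhombicity rhombicity in `[0, 2/3]`.
#' @param rotation 3x3 proper rotation whose columns are the tensor
#'   frame axes in the molecular frame (default identity).
#' @export
tensor_from_params <- function(da, rhombicity, rotation = diag(3)) {
  if (rhombicity < 0 || rhombicity > 2 / 3)
    stop("rhombicity must lie in [0, 2/3]")
  szz <- 2 * da
  sxx <- -da + 1.5 * rhombicity * da
  syy <- -da - 1.5 * rhombicity * da
  S <- rotation %*% diag(c(sxx, syy, szz)) %*% t(rotation)
  alignment_tensor(c(S[1, 1], S[2, 2], S[1, 2], S[1, 3], S[2, 3]))
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf(
    "Alignment tensor: Da = %.3f Hz (N-H scale), rhombicity = %.3f\n",
    x$da, x$rhombicity))
  invisible(x)
}

#' Back-calculate RDCs from bond vectors and an alignment tensor
#'
#' Evaluates `D = scale * v' S v` for each vector, the Saupe-matrix
#' form of the dipolar coupling (equivalent to
#' `Da [(3 cos^2 theta - 1) + (3/2) R sin^2 theta cos 2 phi]` in the
#' tensor frame, times the type scale).
#'
#' @param vectors a `"bond_vectors"` data frame.
#' @param tensor an `"alignment_tensor"`.
#' @return predicted couplings in Hz (natural units of each type).
#' @export
back_calc_rdc <- function(vectors, tensor) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  V <- as.matrix(vectors[c("vx", "vy", "vz")])
  vectors$scale * rowSums((V %*% tensor$matrix) * V)
}

#' RDC fit-quality factors
#'
#' Computes, on the N-H-normalized scale, the rmsd of fit
#' `sqrt(mean((obs - calc)^2))`, the quality factor
#' `Q = rmsd / sqrt(mean(obs^2))` and the R factor
#' `R = rmsd / sqrt(2 Da^2 (4 + 3 Rh^2) / 5)`, whose denominator is
#' the rms of couplings from an isotropic (random) distribution of
#' bond orientations for the given tensor.  When computed on RDC sets
#' excluded from a refinement, the R factor is the cross-validated
#' R-free.
#'
#' @param observed,predicted paired couplings (same units).
#' @param da,rhombicity magnitude and rhombicity of the tensor, with
#'   `da` on the same scale as the couplings.
#' @param n_restraints number of restraints used in the fit that is
#'   being evaluated (informational).
#' @return an object of class `"fit_quality"`: list with `rmsd`, `q`,
#'   `r`, `n`.
#' @export
quality_factors <- function(observed, predicted, da, rhombicity,
                            n_restraints = length(observed)) {
  if (length(observed) == 0) stop("empty input")
  stopifnot(length(observed) == length(predicted))
  rmsd <- sqrt(mean((observed - predicted)^2))
  q <- rmsd / sqrt(mean(observed^2))
  r <- rmsd / sqrt(2 * da^2 * (4 + 3 * rhombicity^2) / 5)
  structure(list(rmsd = rmsd, q = q, r = r, n = n_restraints),
            class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("RDC fit: rmsd = %.3f Hz, Q = %.3f, R = %.3f (n = %d)\n",
              x$rmsd, x$q, x$r, x$n))
  invisible(x)
}

# join observations to vectors on (residue, type); returns the merged
# frame with vector components, scale, obs, sigma
.match_rdc <- function(vectors, observed) {
  m <- merge(as.data.frame(vectors),
             as.data.frame(observed)[c("residue", "type", "value", "error")],
             by = c("residue", "type"))
  if (nrow(m) == 0) stop("no observations match the available vectors")
  m
}

#' Fit an alignment tensor to observed RDCs by SVD
#'
#' Least-squares solution for the five Saupe components from the
#' direction-cosine design matrix, rows weighted by `1/error` (with
#' couplings kept in natural units, this weighting puts all types on a
#' common N-H scale relative to their precision).  The solution uses
#' the singular value decomposition of the weighted design matrix and
#' requires rank 5.
#'
#' @param vectors a `"bond_vectors"` data frame (from
#'   [build_bond_vectors()]).
#' @param observed an `"rdc_table"` data frame (one alignment medium).
#' @return an object of class `"tensor_fit"`: the `"alignment_tensor"`
#'   plus `quality` (a `"fit_quality"` on the N-H-normalized scale),
#'   `observed`, `predicted` and the matched data.
#' @export
svd_fit_tensor <- function(vectors, observed) {
  m <- .match_rdc(vectors, observed)
  if (nrow(m) < 5) stop("need at least 5 matched RDCs")
  V <- as.matrix(m[c("vx", "vy", "vz")])
  X <- cbind(V[, 1]^2 - V[, 3]^2,
             V[, 2]^2 - V[, 3]^2,
             2 * V[, 1] * V[, 2],
             2 * V[, 1] * V[, 3],
             2 * V[, 2] * V[, 3]) * m$scale
  w <- 1 / m$error
  sv <- svd(X * w)
  if (sum(sv$d > max(sv$d) * 1e-8) < 5)
    stop("degenerate orientation sampling: design matrix rank < 5")
  s5 <- sv$v %*% ((t(sv$u) %*% (m$value * w)) / sv$d)
  tensor <- alignment_tensor(as.numeric(s5))
  pred <- back_calc_rdc(m, tensor)
  qual <- quality_factors(m$value / m$scale, pred / m$scale,
                          tensor$da, tensor$rhombicity, nrow(m))
  structure(list(tensor = tensor, quality = qual, data = m,
                 predicted = pred),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  print(x$tensor)
  print(x$quality)
  invisible(x)
}

#' @export
coef.tensor_fit <- function(object, ...) {
  c(da = object$tensor$da, rhombicity = object$tensor$rhombicity,
    object$tensor$euler)
}

#' @export
predict.tensor_fit <- function(object, vectors = NULL, ...) {
  if (is.null(vectors)) return(object$predicted)
  back_calc_rdc(vectors, object$tensor)
}

#' Sparsity-corrected alignment-tensor magnitudes
#'
#' An RDC set that samples bond orientations sparsely and
#' anisotropically yields an SVD tensor whose magnitude is biased low
#' (typically by about 10%), while its rhombicity and orientation are
#' essentially unaffected.  This grid search imposes a common scale
#' factor on the SVD-fitted magnitudes of all RDC sets (coupling
#' types) measured in one alignment medium, holding each set's
#' orientation and rhombicity fixed, and selects the scale that
#' minimizes the summed R factor over the sets.
#'
#' @param structure the reference [structure_model()] (ground state).
#' @param observed an `"rdc_table"` restricted to one medium, with at
#'   least two coupling types.
#' @param scale_grid candidate scale factors (default 1.00-1.20 in
#'   steps of 0.01).
#' @return an object of class `"tensor_correction"`: list with the
#'   selected `scale`, per-set corrected tensors (`tensors`), per-set
#'   uncorrected SVD fits (`svd_fits`), and the grid diagnostic table
#'   `r_table` (scale vs summed R factor).  If the summed R factor is
#'   still decreasing at the end of the grid a warning reports that
#'   the grid does not bracket the minimum.
#' @export
correct_tensor_magnitude <- function(structure, observed,
                                     scale_grid = seq(1, 1.2, by = 0.01)) {
  if (length(scale_grid) == 0) stop("empty scale grid")
  if (length(unique(observed$medium)) != 1)
    stop("'observed' must contain a single alignment medium")
  types <- unique(observed$type)
  if (length(types) < 2)
    stop("need at least two RDC types in the medium")
  vectors <- build_bond_vectors(structure, types)
  fits <- lapply(types, function(tt)
    svd_fit_tensor(vectors[vectors$type == tt, ],
                   observed[observed$type == tt, ]))
  names(fits) <- types
  rsum <- vapply(scale_grid, function(s) {
    sum(vapply(fits, function(f) {
      sc <- f$data$scale
      quality_factors(f$data$value / sc, s * f$predicted / sc,
                      s * f$tensor$da, f$tensor$rhombicity)$r
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(rsum)
  if (best == length(scale_grid) && length(scale_grid) > 1)
    warning("scale grid does not bracket a minimum; ",
            "summed R factor still decreasing at ",
            scale_grid[best])
  scale <- scale_grid[best]
  tensors <- lapply(fits, function(f)
    alignment_tensor(scale * f$tensor$s5))
  structure(list(scale = scale, tensors = tensors, svd_fits = fits,
                 r_table = data.frame(scale = scale_grid, r_sum = rsum),
                 medium = observed$medium[1]),
            class = "tensor_correction")
}

#' @export
print.tensor_correction <- function(x, ...) {
  cat(sprintf(
    "Tensor magnitude correction (%s): scale = %.2f over %d set(s)\n",
    x$medium, x$scale, length(x$tensors)))
  for (tt in names(x$tensors))
    cat(sprintf("  %-5s Da(SVD) = %8.3f -> Da(corrected) = %8.3f Hz\n",
                tt, x$svd_fits[[tt]]$tensor$da, x$tensors[[tt]]$da))
  invisible(x)
}

#' Two-or-more-conformer ensemble model
#'
#' A weighted list of conformers sharing residue numbering and atom
#' naming; the weights must sum to one (within 1e-6).
#'
#' @param conformers list of [structure_model()] objects.
#' @param weights numeric weights summing to 1.
#' @return an object of class `"ensemble_model"`.
#' @export
ensemble_model <- function(conformers, weights) {
  stopifnot(length(conformers) == length(weights))
  if (abs(sum(weights) - 1) > 1e-6)
    stop("ensemble weights must sum to 1 (within 1e-6)")
  ref <- residue_numbers(conformers[[1]])
  for (cf in conformers[-1])
    if (!identical(residue_numbers(cf), ref))
      stop("conformers must share residue numbering")
  structure(list(conformers = conformers, weights = weights),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("Ensemble model: %d conformers, weights %s\n",
              length(x$conformers),
              paste(sprintf("%.3f", x$weights), collapse = ":")))
  invisible(x)
}

#' Population-weighted ensemble RDC prediction
#'
#' Predicts each coupling as the weighted sum over conformers,
#' `D = sum_k w_k D_k`, with bond vectors rebuilt per conformer.
#'
#' @param ensemble an [ensemble_model()].
#' @param tensor an `"alignment_tensor"` (one medium).
#' @param types coupling types to predict.
#' @return data frame `residue`, `type`, `value` of predicted couplings
#'   (natural units).
#' @export
ensemble_rdc <- function(ensemble, tensor, types = .RDC_TYPES) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  preds <- lapply(ensemble$conformers, function(cf) {
    bv <- build_bond_vectors(cf, types)
    data.frame(residue = bv$residue, type = bv$type,
               value = back_calc_rdc(bv, tensor))
  })
  out <- preds[[1]]
  key <- paste(out$residue, out$type)
  out$value <- out$value * ensemble$weights[1]
  for (k in seq_along(preds)[-1]) {
    m <- match(key, paste(preds[[k]]$residue, preds[[k]]$type))
    if (anyNA(m)) stop("conformers yield different vector sets")
    out$value <- out$value + ensemble$weights[k] * preds[[k]]$value[m]
  }
  out
}
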