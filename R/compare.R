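# Superposition and RMSD utilities with region exclusion, per-residue
# displacement profiles and ensemble spread statistics.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# paired coordinate matrices for two models over the (residue, atom)
# intersection of the selected atom set, minus excluded regions
.pair_coords <- function(mobile, reference, atoms = "backbone",
                         exclude = NULL) {
  sel <- if (identical(atoms, "backbone")) .BACKBONE_ATOMS
         else if (identical(atoms, "ca")) "CA"
         else atoms
  drop <- region_residues(exclude)
  am <- mobile$atoms[mobile$atoms$atom %in% sel &
                       !(mobile$atoms$resno %in% drop), ]
  ar <- reference$atoms[reference$atoms$atom %in% sel &
                          !(reference$atoms$resno %in% drop), ]
  keym <- paste(am$resno, am$atom)
  keyr <- paste(ar$resno, ar$atom)
  common <- intersect(keym, keyr)
  if (length(common) == 0) stop("no shared residues/atoms to pair")
  im <- match(common, keym); ir <- match(common, keyr)
  list(xm = as.matrix(am[im, c("x", "y", "z")]),
       xr = as.matrix(ar[ir, c("x", "y", "z")]),
       resno = am$resno[im], atom = am$atom[im],
       selection = paste0(paste(sel, collapse = "/"),
                          if (length(drop))
                            paste0(" excluding ",
                                   paste(names(exclude), collapse = ","))
                          else ""))
}

# Kabsch: proper rotation R and centers minimizing rms of
# (xm - cm) R - (xr - cr)
.kabsch <- function(xm, xr) {
  cm <- colMeans(xm); cr <- colMeans(xr)
  P <- sweep(xm, 2, cm); Q <- sweep(xr, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d < 0)
    warning("optimal superposition requires a reflection; ",
            "chirality mismatch between the models")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)                       # so that P %*% R approximates Q
  list(rotation = R, center_mobile = cm, center_reference = cr,
       aligned = sweep(P %*% R, 2, cr, "+"))
}

#' Optimal least-squares superposition of two structures
#'
#' Solves the orthogonal Procrustes problem by SVD (Kabsch) over atoms
#' paired by (residue number, atom name) intersection, optionally
#' excluding named residue regions (e.g. the switch regions) from both
#' the fit and the reported rmsd.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param atoms `"backbone"` (N, CA, C, O), `"ca"`, or a character
#'   vector of atom names.
#' @param exclude optional [region_selection()] excluded from pairing.
#' @return an object of class `"superposition"`: proper `rotation`
#'   (3x3), centers, `rmsd` (Angstrom), `n` atoms used and a selection
#'   description.
#' @export
superpose <- function(mobile, reference, atoms = "backbone",
                      exclude = NULL) {
  pc <- .pair_coords(mobile, reference, atoms, exclude)
  if (nrow(pc$xm) < 3) stop("fewer than 3 paired atoms")
  kb <- .kabsch(pc$xm, pc$xr)
  rmsd <- sqrt(mean(rowSums((kb$aligned - pc$xr)^2)))
  structure(list(rotation = kb$rotation,
                 center_mobile = kb$center_mobile,
                 center_reference = kb$center_reference,
                 rmsd = rmsd, n = nrow(pc$xm),
                 selection = pc$selection),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition (%s): rmsd = %.3f A over %d atoms\n",
              x$selection, x$rmsd, x$n))
  invisible(x)
}

#' Apply a superposition transform to a structure
#'
#' @param x a [structure_model()] (the mobile structure).
#' @param sp a `"superposition"` from [superpose()].
#' @return the transformed [structure_model()].
#' @export
apply_superposition <- function(x, sp) {
  xyz <- as.matrix(x$atoms[c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, sp$center_mobile) %*% sp$rotation,
               2, sp$center_reference, "+")
  x$atoms[c("x", "y", "z")] <- xyz
  if (!is.null(x$het)) {
    h <- as.matrix(x$het[c("x", "y", "z")])
    x$het[c("x", "y", "z")] <-
      sweep(sweep(h, 2, sp$center_mobile) %*% sp$rotation,
            2, sp$center_reference, "+")
  }
  x
}

#' Per-residue backbone displacement profile
#'
#' After a global superposition on the non-excluded residue set, the
#' rms displacement of the backbone atoms of each shared residue is
#' reported.  Excluded residues do not appear in the output (they are
#' absent, not zero).
#'
#' @param mobile,reference [structure_model()] objects sharing
#'   numbering.
#' @param atoms atom selection as in [superpose()].
#' @param exclude optional [region_selection()] excluded from the fit
#'   and the profile.
#' @return named numeric vector: per-residue displacement in Angstrom,
#'   names = residue numbers.
#' @export
per_residue_displacement <- function(mobile, reference,
                                     atoms = "backbone", exclude = NULL) {
  sp <- superpose(mobile, reference, atoms, exclude)
  pc <- .pair_coords(mobile, reference, atoms, exclude)
  al <- sweep(sweep(pc$xm, 2, sp$center_mobile) %*% sp$rotation,
              2, sp$center_reference, "+")
  d2 <- rowSums((al - pc$xr)^2)
  prof <- sqrt(tapply(d2, pc$resno, mean))
  prof <- prof[order(as.integer(names(prof)))]
  stats::setNames(as.numeric(prof), names(prof))
}

#' Ensemble spread statistics
#'
#' Computes the mean structure of a conformer set (coordinate average
#' after mutual superposition onto an iteratively refined mean), the
#' rmsd of each conformer to that mean, and, when a reference is
#' given, the pairwise rmsd of each conformer to the reference.
#'
#' @param conformers list of at least two [structure_model()] objects.
#' @param reference optional reference [structure_model()] (e.g. the
#'   ground-state crystal structure).
#' @param atoms,exclude selection as in [superpose()].
#' @return list with `rmsd_to_mean` (per conformer), `mean_rmsd`,
#'   and, with a reference, `rmsd_to_reference` and its `range`.
#' @export
ensemble_rmsd_stats <- function(conformers, reference = NULL,
                                atoms = "backbone", exclude = NULL) {
  if (length(conformers) < 2) stop("need at least two conformers")
  ref0 <- conformers[[1]]
  coords <- function(a, b) .pair_coords(a, b, atoms, exclude)
  # superpose all onto the first, then twice refine onto the running mean
  mats <- lapply(conformers, function(cf) {
    pc <- coords(cf, ref0)
    .kabsch(pc$xm, pc$xr)$aligned
  })
  for (it in 1:2) {
    mn <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, function(m) .kabsch(m, mn)$aligned)
  }
  mn <- Reduce(`+`, mats) / length(mats)
  r2m <- vapply(mats, function(m) sqrt(mean(rowSums((m - mn)^2))),
                numeric(1))
  out <- list(rmsd_to_mean = r2m, mean_rmsd = mean(r2m))
  if (!is.null(reference)) {
    rtr <- vapply(conformers, function(cf)
      superpose(cf, reference, atoms, exclude)$rmsd, numeric(1))
    out$rmsd_to_reference <- rtr
    out$range <- range(rtr)
  }
  out
}
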