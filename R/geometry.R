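# Internal geometry machinery: ideal-geometry backbone construction
# (NeRF), torsion angles with analytic gradients, and the
# elastic-network energy model shared by the ensemble refinement and
# the synthetic-structure generator.

.IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.5,
  t_omega = 180, t_cb = 122.6)   # t_cb: improper C'-N-CA-CB

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# NeRF: place atom D bonded to c with |cD| = r, angle(b,c,D) = theta
# and torsion(a,b,c,D) = chi (degrees)
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a)
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# torsion angles (radians) for stacked atom quadruples; optionally the
# analytic gradient with respect to each of the four atoms
.torsion <- function(p1, p2, p3, p4, grad = FALSE) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(.cross3(n1, n2) * b2) / nb2
  theta <- atan2(y, x)
  if (!grad) return(theta)
  nn1 <- rowSums(n1^2); nn2 <- rowSums(n2^2)
  g1 <- -n1 * (nb2 / nn1)
  g4 <- n2 * (nb2 / nn2)
  c12 <- rowSums(b1 * b2) / nb2^2
  c32 <- rowSums(b3 * b2) / nb2^2
  g2 <- -g1 * (1 + c12) + g4 * c32
  g3 <- g1 * c12 - g4 * (1 + c32)
  list(theta = theta, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

# Backbone dihedrals of a structure model: data frame residue/phi/psi
# in degrees (NA at chain termini)
.phi_psi <- function(x) {
  res <- residue_numbers(x)
  N <- .atom_xyz(x, res, "N"); CA <- .atom_xyz(x, res, "CA")
  C <- .atom_xyz(x, res, "C")
  n <- length(res)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    ii <- 2:n
    phi[ii] <- .torsion(C[ii - 1, , drop = FALSE], N[ii, , drop = FALSE],
                        CA[ii, , drop = FALSE], C[ii, , drop = FALSE])
    jj <- 1:(n - 1)
    psi[jj] <- .torsion(N[jj, , drop = FALSE], CA[jj, , drop = FALSE],
                        C[jj, , drop = FALSE], N[jj + 1, , drop = FALSE])
  }
  data.frame(residue = res, phi = phi * 180 / pi, psi = psi * 180 / pi)
}

# Build an idealized all-alanine backbone (N, CA, C, O, CB) from phi /
# psi plans in degrees.  Residues numbered 1..n, chain "A".
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- .IDEAL
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 1:n) {
    if (i < n) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                                g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                 g$a_c_n_ca, g$t_omega)
      C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                                g$a_n_ca_c, phi[i + 1])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o,
                          g$a_ca_c_o, psi[i] + 180)
    CB[i, ] <- .place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb,
                           g$a_n_ca_cb, g$t_cb)
  }
  atoms <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(chain = "A", resno = i, resname = "ALA",
               atom = c("N", "CA", "C", "O", "CB"),
               element = c("N", "C", "C", "O", "C"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1], CB[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2], CB[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3], CB[i, 3]),
               stringsAsFactors = FALSE)
  }))
  structure_model(atoms, metadata = "idealized backbone")
}

# ---- elastic-network machinery -------------------------------------

# accumulate per-row 3-vectors V into gradient matrix G at indices idx
.acc_grad <- function(G, idx, V) {
  s <- rowsum(V, idx, reorder = FALSE)
  u <- as.integer(rownames(s))
  G[u, ] <- G[u, ] + s
  G
}

# pair list (i, j, d0, k) describing the local-geometry elastic
# network of a coordinate set laid out as one row per atom.
# `lookup(resno, atom)` maps to row indices (NA when absent).
.elastic_pairs <- function(resno_of, name_of, X0,
                           k_bond = 200, k_13 = 50, k_14 = 20) {
  res <- sort(unique(resno_of))
  lut <- new.env(hash = TRUE)
  for (i in seq_along(resno_of))
    assign(paste0(resno_of[i], ".", name_of[i]), i, envir = lut)
  gi <- function(r, a) {
    v <- mget(paste0(r, ".", a), envir = lut, ifnotfound = NA)
    unlist(v, use.names = FALSE)
  }
  defs <- list(
    bond = list(c("N", "CA", 0), c("CA", "C", 0), c("C", "O", 0),
                c("CA", "CB", 0), c("C", "N", 1),
                c("N", "H", 0), c("CA", "HA", 0)),
    one3 = list(c("N", "C", 0), c("CA", "O", 0), c("N", "CB", 0),
                c("C", "CB", 0), c("CA", "N", 1), c("O", "N", 1),
                c("C", "CA", 1), c("H", "CA", 0), c("H", "C", -1),
                c("HA", "N", 0), c("HA", "C", 0), c("HA", "CB", 0)),
    one4 = list(c("N", "O", 0), c("O", "CA", 1), c("CB", "N", 1),
                c("CB", "O", 0), c("C", "C", 1), c("N", "N", 1)))
  ks <- c(bond = k_bond, one3 = k_13, one4 = k_14)
  out <- list()
  for (cls in names(defs)) {
    for (d in defs[[cls]]) {
      off <- as.integer(d[3])
      i <- gi(res, d[1]); j <- gi(res + off, d[2])
      ok <- !is.na(i) & !is.na(j)
      if (!any(ok)) next
      out[[length(out) + 1]] <-
        data.frame(i = i[ok], j = j[ok], k = ks[[cls]])
    }
  }
  pr <- do.call(rbind, out)
  d0 <- sqrt(rowSums((X0[pr$i, , drop = FALSE] -
                        X0[pr$j, , drop = FALSE])^2))
  pr$d0 <- d0
  pr
}

# weak long-range CA-CA contact springs (sequence separation >= `sep`,
# distance < `cutoff` in the reference) preserving the tertiary fold
# while the local network preserves covalent geometry
.contact_pairs <- function(resno_of, name_of, X0, cutoff = 9,
                           sep = 3, k = 1) {
  ca <- which(name_of == "CA")
  Xc <- X0[ca, , drop = FALSE]
  rn <- resno_of[ca]
  n <- length(ca)
  ii <- jj <- integer(0)
  cut2 <- cutoff^2
  for (a in seq_len(n - 1)) {
    d2 <- rowSums((Xc[(a + 1):n, , drop = FALSE] -
                     matrix(Xc[a, ], n - a, 3, byrow = TRUE))^2)
    b <- which(d2 < cut2 & rn[(a + 1):n] - rn[a] >= sep) + a
    ii <- c(ii, rep.int(a, length(b))); jj <- c(jj, b)
  }
  if (!length(ii)) return(NULL)
  d0 <- sqrt(rowSums((Xc[ii, , drop = FALSE] - Xc[jj, , drop = FALSE])^2))
  data.frame(i = ca[ii], j = ca[jj], k = k, d0 = d0)
}

# energy + gradient of the elastic pair term
.pair_energy <- function(X, pr, Egrad = TRUE) {
  dv <- X[pr$i, , drop = FALSE] - X[pr$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  dd <- d - pr$d0
  E <- sum(pr$k * dd^2)
  if (!Egrad) return(list(E = E))
  coef <- 2 * pr$k * dd / pmax(d, 1e-9)
  gv <- dv * coef
  G <- matrix(0, nrow(X), 3)
  G <- .acc_grad(G, pr$i, gv)
  G <- .acc_grad(G, pr$j, -gv)
  list(E = E, G = G)
}

# flat-bottom positional restraint: penalize |r - r0| beyond `cap`
.cap_energy <- function(X, X0, cap, k) {
  dv <- X - X0
  d <- sqrt(rowSums(dv^2))
  exc <- pmax(0, d - cap)
  E <- k * sum(exc^2)
  coef <- 2 * k * exc / pmax(d, 1e-9)
  list(E = E, G = dv * coef)
}

# harmonic tether to a target coordinate set
.tether_energy <- function(X, Xt, k) {
  dv <- X - Xt
  list(E = k * sum(dv^2), G = 2 * k * dv)
}

# flat-bottom dihedral restraints: quads is a data frame with atom row
# indices i1..i4, target and halfwidth in radians, force constant k
.dihedral_energy <- function(X, quads) {
  tg <- .torsion(X[quads$i1, , drop = FALSE], X[quads$i2, , drop = FALSE],
                 X[quads$i3, , drop = FALSE], X[quads$i4, , drop = FALSE],
                 grad = TRUE)
  dlt <- tg$theta - quads$target
  dlt <- atan2(sin(dlt), cos(dlt))    # wrap to (-pi, pi]
  exc <- pmax(0, abs(dlt) - quads$halfwidth) * sign(dlt)
  E <- sum(quads$k * exc^2)
  coef <- 2 * quads$k * exc
  G <- matrix(0, nrow(X), 3)
  G <- .acc_grad(G, quads$i1, tg$g1 * coef)
  G <- .acc_grad(G, quads$i2, tg$g2 * coef)
  G <- .acc_grad(G, quads$i3, tg$g3 * coef)
  G <- .acc_grad(G, quads$i4, tg$g4 * coef)
  list(E = E, G = G, violation = exc)
}
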