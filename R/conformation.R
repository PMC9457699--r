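# Structural observables: dihedrals, helicity (window and DSSP-style),
# Kabsch RMSD/RMSF, Rg, end-to-end distance, state populations, and the
# sigmoidal helicity-vs-lambda fit.

#' Signed torsion angle of four points
#'
#' IUPAC convention, degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom
#' @return angle in degrees
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("collinear points: torsion undefined")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Backbone phi/psi series for every frame
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Residues missing a flanking atom (chain termini without caps) are masked.
#' Cap residues (e.g. ACE/NME) contribute flanking atoms but no entries of
#' their own when they lack a complete backbone.
#'
#' @param traj \code{ff_trajectory}
#' @param top \code{ff_topology}
#' @return object of class \code{dihedral_series}: list with \code{phi},
#'   \code{psi} (frames x residues matrices, degrees), \code{defined}
#'   (logical residue mask), \code{residues}
#' @export
phi_psi <- function(traj, top) {
  res <- backbone_residues(top)
  nres <- length(res)
  nf <- n_frames(traj)
  # flanking atoms: previous C and next N, possibly from cap residues
  prevC <- nextN <- rep(NA_integer_, nres)
  at <- top$atoms
  for (k in seq_len(nres)) {
    r <- res[k]
    pc <- which(at$res_index == r - 1L & at$atom_name %in% c("C", "CY"))
    nn <- which(at$res_index == r + 1L & at$atom_name %in% c("N", "NT"))
    if (length(pc)) prevC[k] <- pc[1L]
    if (length(nn)) nextN[k] <- nn[1L]
  }
  phi <- psi <- matrix(NA_real_, nf, nres)
  for (f in seq_len(nf)) {
    X <- traj$coords[f, , ]
    for (k in seq_len(nres)) {
      bb <- top$backbone[[k]]
      if (!is.na(prevC[k]))
        phi[f, k] <- dihedral(X[prevC[k], ], X[bb["N"], ], X[bb["CA"], ],
                              X[bb["C"], ])
      if (!is.na(nextN[k]))
        psi[f, k] <- dihedral(X[bb["N"], ], X[bb["CA"], ], X[bb["C"], ],
                              X[nextN[k], ])
    }
  }
  structure(list(phi = phi, psi = psi,
                 defined = !is.na(prevC) & !is.na(nextN), residues = res),
            class = "dihedral_series")
}

#' Window-criterion helix assignment
#'
#' A residue is helical iff it lies in a maximal run of three or more
#' consecutive residues whose backbone dihedrals satisfy, strictly,
#' -100 < phi < -30 and -67 < psi < -7 degrees.  Residues with undefined
#' angles are never helical.
#'
#' @param d \code{dihedral_series}
#' @return object of class \code{helix_assignment}: \code{helical}
#'   (frames x residues logical), \code{method = "window"}
#' @export
assign_helix_window <- function(d) {
  stopifnot(inherits(d, "dihedral_series"))
  inw <- !is.na(d$phi) & !is.na(d$psi) &
    d$phi > -100 & d$phi < -30 & d$psi > -67 & d$psi < -7
  hel <- matrix(FALSE, nrow(inw), ncol(inw))
  for (f in seq_len(nrow(inw))) {
    r <- rle(inw[f, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 3L
    for (j in which(keep)) hel[f, starts[j]:ends[j]] <- TRUE
  }
  structure(list(helical = hel, method = "window", residues = d$residues),
            class = "helix_assignment")
}

#' Helix fraction (global and per residue)
#'
#' Global fraction = mean over frames of (helical residues / total
#' residues); the denominator is every residue of the chain, residues with
#' undefined dihedrals counting as non-helical.
#'
#' @param h \code{helix_assignment}
#' @return list with \code{global} and \code{per_residue}
#' @export
fraction_helix <- function(h) {
  stopifnot(inherits(h, "helix_assignment"))
  list(global = mean(rowMeans(h$helical)),
       per_residue = colMeans(h$helical))
}

# ---- DSSP-style assignment --------------------------------------------------

#' Reconstruct amide hydrogens on backbone nitrogens
#'
#' H is placed 1.0 Angstrom from N, opposite the bisector of the
#' C(i-1)-N-CA angle (the standard planar amide direction).  Used when the
#' input carries no hydrogens.
#'
#' @param X atoms x 3 coordinate matrix for one frame
#' @param top \code{ff_topology}
#' @return residues x 3 matrix of H positions (NA rows where the previous C
#'   is absent)
#' @keywords internal
.reconstruct_amide_h <- function(X, top) {
  res <- backbone_residues(top)
  at <- top$atoms
  H <- matrix(NA_real_, length(res), 3)
  for (k in seq_along(res)) {
    bb <- top$backbone[[k]]
    if (!is.na(bb["H"])) { H[k, ] <- X[bb["H"], ]; next }
    pc <- which(at$res_index == res[k] - 1L & at$atom_name %in% c("C", "CY"))
    if (!length(pc)) next
    N <- X[bb["N"], ]
    u1 <- X[pc[1L], ] - N; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- X[bb["CA"], ] - N; u2 <- u2 / sqrt(sum(u2^2))
    d <- -(u1 + u2); d <- d / sqrt(sum(d^2))
    H[k, ] <- N + d
  }
  H
}

#' DSSP-style alpha-helix assignment from backbone hydrogen bonds
#'
#' Kabsch-Sander electrostatic hydrogen-bond energy
#' E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol between
#' the C=O of residue i and the N-H of residue j; a bond exists when
#' E < -0.5 kcal/mol.  Residue i is assigned alpha-helical when the
#' four-turns (i-1) -> (i+3) and i -> (i+4) are both present.  Amide
#' hydrogens are reconstructed when absent.  Only the alpha subset is
#' assigned; other DSSP states are out of scope.
#'
#' @param traj \code{ff_trajectory}
#' @param top \code{ff_topology}
#' @return \code{helix_assignment} with \code{method = "dssp"}
#' @export
assign_helix_dssp <- function(traj, top) {
  res <- backbone_residues(top)
  nres <- length(res)
  nf <- n_frames(traj)
  hel <- matrix(FALSE, nf, nres)
  for (f in seq_len(nf)) {
    X <- traj$coords[f, , ]
    H <- .reconstruct_amide_h(X, top)
    Opos <- t(vapply(seq_len(nres), function(k) X[top$backbone[[k]]["O"], ],
                     numeric(3)))
    Cpos <- t(vapply(seq_len(nres), function(k) X[top$backbone[[k]]["C"], ],
                     numeric(3)))
    Npos <- t(vapply(seq_len(nres), function(k) X[top$backbone[[k]]["N"], ],
                     numeric(3)))
    # hbond[i, j]: C=O of residue i accepts from N-H of residue j
    hbond <- matrix(FALSE, nres, nres)
    for (i in seq_len(nres)) for (j in seq_len(nres)) {
      if (abs(res[i] - res[j]) < 2L) next       # no bonded/adjacent pairs
      if (anyNA(H[j, ])) next
      rON <- sqrt(sum((Opos[i, ] - Npos[j, ])^2))
      rCH <- sqrt(sum((Cpos[i, ] - H[j, ])^2))
      rOH <- sqrt(sum((Opos[i, ] - H[j, ])^2))
      rCN <- sqrt(sum((Cpos[i, ] - Npos[j, ])^2))
      E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
      hbond[i, j] <- E < -0.5
    }
    turn4 <- rep(FALSE, nres)  # turn4[i]: hbond (i) -> (i+4)
    for (i in seq_len(nres)) {
      j <- which(res == res[i] + 4L)
      if (length(j)) turn4[i] <- hbond[i, j]
    }
    for (i in seq_len(nres)) {
      iprev <- which(res == res[i] - 1L)
      hel[f, i] <- length(iprev) && turn4[iprev] && turn4[i]
    }
  }
  structure(list(helical = hel, method = "dssp", residues = res),
            class = "helix_assignment")
}

# ---- superposition ----------------------------------------------------------

#' Kabsch superposition RMSD
#'
#' Minimal least-squares RMSD of \code{Y} onto \code{X} after optimal
#' proper rotation and translation (SVD solution; reflections rejected by
#' sign correction of the smallest singular vector).
#'
#' @param X,Y n x 3 coordinate matrices (same n >= 3)
#' @param selection optional row indices applied to both
#' @return list with \code{rmsd} (Angstrom), \code{rotation} (3 x 3 proper
#'   rotation), \code{translation}
#' @export
kabsch_rmsd <- function(X, Y, selection = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(selection)) { X <- X[selection, , drop = FALSE]
                             Y <- Y[selection, , drop = FALSE] }
  if (nrow(X) != nrow(Y)) stop("selection size mismatch")
  if (nrow(X) < 3L) stop("need at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  S <- svd(crossprod(Yc, Xc))      # covariance Y^T X
  d <- sign(det(S$u %*% t(S$v)))
  D <- diag(c(1, 1, d))
  R <- S$u %*% D %*% t(S$v)        # rotate X-frame into Y? define: Yc %*% R ~ Xc
  Yr <- Yc %*% R
  rmsd <- sqrt(mean(rowSums((Yr - Xc)^2)))
  list(rmsd = rmsd, rotation = R, translation = cx - cy)
}

#' Iteratively align all frames to their mean structure
#'
#' @param traj \code{ff_trajectory}
#' @param selection atom indices used for the fit (all atoms rotated)
#' @param max_iter,tol iteration controls on the mean-structure drift
#' @return aligned \code{ff_trajectory}
#' @export
align_frames <- function(traj, selection = NULL, max_iter = 10L, tol = 1e-8) {
  nf <- n_frames(traj); nat <- n_atoms(traj)
  if (is.null(selection)) selection <- seq_len(nat)
  co <- traj$coords
  ref <- co[1, selection, ]
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nf)) {
      fit <- kabsch_rmsd(ref, co[f, selection, ])
      cy <- colMeans(co[f, selection, , drop = FALSE][1, , ])
      allc <- sweep(co[f, , ], 2, cy) %*% fit$rotation
      co[f, , ] <- sweep(allc, 2, colMeans(ref), `+`)
    }
    newref <- apply(co[, selection, , drop = FALSE], c(2, 3), mean)
    drift <- sqrt(mean((newref - ref)^2))
    ref <- newref
    if (drift < tol) break
  }
  ff_trajectory(co, box = traj$box, times = traj$times, wrapped = FALSE)
}

#' Root mean square fluctuation per atom
#'
#' Frames are first iteratively superposed onto their mean structure; the
#' RMSF of each selected atom is the square root of the time-mean squared
#' deviation from its time-mean position.
#'
#' @param traj \code{ff_trajectory} with >= 2 frames
#' @param selection atom indices (default all)
#' @param align superpose first (default TRUE; set FALSE if pre-aligned)
#' @return numeric vector of per-atom RMSF, Angstrom
#' @export
rmsf <- function(traj, selection = NULL, align = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (align) traj <- align_frames(traj, selection)
  co <- traj$coords[, selection, , drop = FALSE]
  mu <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mu)^2
  sqrt(apply(dev2, 2, function(m) mean(rowSums(matrix(m, ncol = 3)))))
}

# ---- size / populations -----------------------------------------------------

#' Radius of gyration and end-to-end distance per frame
#'
#' Rg is computed about the geometric center (mass weighting optional);
#' the end-to-end distance d is between the first and last CA when a
#' topology is given, else between the first and last selected atom.
#'
#' @param traj \code{ff_trajectory}
#' @param top optional \code{ff_topology} (for CA terminals)
#' @param selection atom indices (default all)
#' @param masses optional per-atom masses for mass-weighted Rg
#' @return data.frame with columns \code{time}, \code{rg}, \code{d}
#' @export
rg_and_end_to_end <- function(traj, top = NULL, selection = NULL,
                              masses = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty selection")
  ends <- c(selection[1L], selection[length(selection)])
  if (!is.null(top)) {
    ca <- backbone_atom(top, "CA")
    ca <- ca[!is.na(ca)]
    if (length(ca) >= 2L) ends <- c(ca[1L], ca[length(ca)])
  }
  w <- if (is.null(masses)) rep(1, length(selection))
       else masses[selection]
  w <- w / sum(w)
  nf <- n_frames(traj)
  rg <- d <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[f, selection, , drop = FALSE][1, , ]
    if (length(selection) == 1L) X <- matrix(X, 1, 3)
    ctr <- colSums(X * w)
    rg[f] <- sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)))
    d[f] <- sqrt(sum((traj$coords[f, ends[1L], ] -
                        traj$coords[f, ends[2L], ])^2))
  }
  data.frame(time = traj$times, rg = rg, d = d)
}

#' Fraction of frames strictly below a cutoff
#'
#' Used for native-state populations (e.g. RMSD < 2.2 or < 3.0 Angstrom).
#'
#' @param series per-frame scalar values
#' @param cutoff threshold (strict)
#' @return fraction in [0, 1]
#' @export
state_population <- function(series, cutoff) {
  if (!length(series)) stop("empty series")
  mean(series < cutoff)
}

# ---- sigmoid fit ------------------------------------------------------------

#' Evaluate the helicity-vs-lambda sigmoid
#'
#' f(lambda) = A / (1 + exp(-(lambda - B)/C)) + D.  With C < 0 the curve
#' decreases with lambda; B is the midpoint, where f(B) = A/2 + D.
#'
#' @param lam lambda values
#' @param A,B,C,D parameters
#' @return f(lambda)
#' @export
sigmoid_helicity <- function(lam, A, B, C, D)
  A / (1 + exp(-(lam - B) / C)) + D

#' Fit the four-parameter sigmoid to helicity-vs-lambda points
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start over the
#' sign of C and several midpoint/width guesses; the branch with C < 0 is
#' the natural one when helicity decreases with lambda.
#'
#' @param lams lambda values (>= 4 points)
#' @param fractions helix fractions at those lambdas
#' @return object of class \code{sigmoid_fit} with elements A, B, C, D,
#'   \code{residual} (residual norm) and \code{fitted}
#' @export
fit_sigmoid <- function(lams, fractions) {
  stopifnot(length(lams) == length(fractions))
  if (length(lams) < 4L) stop("need at least 4 points")
  if (diff(range(fractions)) < .Machine$double.eps^0.5)
    stop("degenerate fit: fractions are constant")
  df <- data.frame(x = lams, y = fractions)
  amp <- diff(range(fractions))
  base <- min(fractions)
  span <- diff(range(lams))
  starts <- list()
  for (sgn in c(-1, 1)) for (w in c(0.02, 0.1, 0.4) * span)
    starts[[length(starts) + 1L]] <-
      list(A = amp, B = mean(range(lams)), C = sgn * w, D = base)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A / (1 + exp(-(x - B) / C)) + D, data = df,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$residual) {
      cf <- stats::coef(fit)
      best <- list(A = unname(cf["A"]), B = unname(cf["B"]),
                   C = unname(cf["C"]), D = unname(cf["D"]), residual = rn)
    }
  }
  if (is.null(best)) stop("sigmoid fit failed from every start")
  # The parameterization has an exact mirror (A, C, D) -> (-A, -C, D + A).
  # Canonical branch: C < 0 (A > 0) when fractions decrease with lambda,
  # C > 0 (A > 0) when they increase.
  decreasing <- stats::cor(lams, fractions) < 0
  if ((decreasing && best$C > 0) || (!decreasing && best$C < 0)) {
    best <- list(A = -best$A, B = best$B, C = -best$C, D = best$D + best$A,
                 residual = best$residual)
  }
  best$fitted <- sigmoid_helicity(lams, best$A, best$B, best$C, best$D)
  structure(best, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: A = %.4g, B = %.4g, C = %.4g, D = %.4g (residual %.3g)\n",
              x$A, x$B, x$C, x$D, x$residual))
  invisible(x)
}
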