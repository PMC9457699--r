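# Structural observables: torsions, helicity, superposition, size metrics,
# populations, sigmoid fit.

test_that("dihedral follows the IUPAC convention and rejects collinearity", {
  # planar cis: 0 degrees; planar trans: 180
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(2, 1, 0)), 0)
  expect_equal(dihedral(p1, p2, p3, c(2, -1, 0)), 180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("built backbones reproduce requested dihedrals to high precision", {
  for (ang in list(c(-57, -47), c(-120, 130), c(-65, -40))) {
    bb <- build_backbone(ang[1], ang[2], 8)
    d <- phi_psi(bb$traj, bb$top)
    expect_true(all(abs(d$phi - ang[1]) < 1e-6))
    expect_true(all(abs(d$psi - ang[2]) < 1e-6))
  }
})

test_that("window criterion needs runs of three and strict inequalities", {
  bb <- build_backbone(-65, -40, 15)
  d <- phi_psi(bb$traj, bb$top)
  expect_equal(fraction_helix(assign_helix_window(d))$global, 1.0)

  # exactly 2 consecutive in-window residues -> none helical
  d2 <- d
  d2$phi[1, ] <- -150                      # all out of window
  d2$phi[1, 4:5] <- -65                    # two in-window only
  expect_equal(fraction_helix(assign_helix_window(d2))$global, 0)

  # boundary phi = -100 exactly is outside the open interval
  d3 <- d
  d3$phi[1, 7] <- -100
  h3 <- assign_helix_window(d3)
  expect_false(h3$helical[1, 7])
  expect_true(h3$helical[1, 8])            # neighbours keep their >= 3 run
})

test_that("helix fractions average frames and residues as stated", {
  hel <- matrix(FALSE, 2, 15)
  hel[1, 1:6] <- TRUE                      # frame fractions 0.4 and 0.4
  hel[2, 10:15] <- TRUE
  h <- structure(list(helical = hel, method = "window", residues = 1:15),
                 class = "helix_assignment")
  fr <- fraction_helix(h)
  expect_equal(fr$global, 0.4)
  expect_equal(fr$per_residue[1], 0.5)
  hel2 <- matrix(FALSE, 2, 10); hel2[1, 1:2] <- TRUE; hel2[2, 1:6] <- TRUE
  h2 <- structure(list(helical = hel2, method = "window", residues = 1:10),
                  class = "helix_assignment")
  expect_equal(fraction_helix(h2)$global, 0.4)   # mean of 0.2 and 0.6
})

test_that("DSSP-style assignment marks ideal helix interior, not extended", {
  hel <- build_backbone(-57, -47, 15)
  a <- assign_helix_dssp(hel$traj, hel$top)
  interior <- 2:11                         # residues with both 4-turns
  expect_true(all(a$helical[1, interior]))
  ext <- build_backbone(-179, 179, 15)
  ae <- assign_helix_dssp(ext$traj, ext$top)
  expect_false(any(ae$helical))
})

test_that("Kabsch RMSD is zero under rigid motion and symmetric", {
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(X, X)$rmsd, 0, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- X %*% R + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(X, Y)$rmsd, 0, tolerance = 1e-9)
  Z <- X + matrix(rnorm(30, 0, 0.3), 10, 3)
  expect_equal(kabsch_rmsd(X, Z)$rmsd, kabsch_rmsd(Z, X)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_rmsd(X, X[1:5, ]), "mismatch")
})

test_that("Kabsch matches bio3d superposition on a peptide pair", {
  a <- build_backbone(-57, -47, 10)
  b <- build_backbone(-70, -35, 10)
  ca <- backbone_atom(a$top, "CA")
  X <- a$traj$coords[1, ca, ]; Y <- b$traj$coords[1, ca, ]
  ours <- kabsch_rmsd(X, Y)$rmsd
  ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_lt(abs(ours - ref), 1e-3)         # bio3d reports 3 decimals
})

test_that("Kabsch equals brute-force rotational search on 4-point toys", {
  set.seed(33)
  for (i in 1:3) {
    X <- matrix(rnorm(12), 4, 3)
    Y <- matrix(rnorm(12), 4, 3)
    expect_equal(kabsch_rmsd(X, Y)$rmsd, brute_force_rmsd(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("RMSF reproduces closed forms and the Gaussian-jitter limit", {
  co <- array(0, c(4, 3, 3))
  co[, 1, 1] <- c(1, -1, 1, -1)            # atom 1 oscillates +-1 on x
  co[, 2, ] <- 5; co[, 3, ] <- -2
  tr <- ff_trajectory(co)
  v <- rmsf(tr, align = FALSE)
  expect_equal(v, c(1, 0, 0))
  expect_error(rmsf(ff_trajectory(co[1, , , drop = FALSE])), "two frames")

  set.seed(8)
  sig <- 0.2
  nf <- 4000
  co2 <- array(rnorm(nf * 3 * 3, 0, sig), c(nf, 3, 3))
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, 3, byrow = TRUE)
  for (f in seq_len(nf)) co2[f, , ] <- co2[f, , ] + base
  v2 <- rmsf(ff_trajectory(co2), align = FALSE)
  expect_equal(v2, rep(sig * sqrt(3), 3), tolerance = 0.05)
})

test_that("Rg and end-to-end match closed forms and the helix geometry", {
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 10
  tr <- ff_trajectory(co)
  out <- rg_and_end_to_end(tr)
  expect_equal(out$rg, 5)
  expect_equal(out$d, 10)

  hel <- build_backbone(-57, -47, 15)
  dh <- rg_and_end_to_end(hel$traj, hel$top)$d
  expect_gt(dh, 20); expect_lt(dh, 26)     # ~1.5 A rise per residue
  ext <- build_backbone(-179, 179, 15)
  expect_gt(rg_and_end_to_end(ext$traj, ext$top)$d, 45)
})

test_that("state populations count strictly-below frames, monotone in cutoff", {
  s <- c(1.0, 2.0, 3.0, 4.0)
  expect_equal(state_population(s, 2.2), 0.5)
  expect_equal(state_population(s, 0.5), 0)
  expect_gte(state_population(s, 3.0), state_population(s, 2.2))
})

test_that("sigmoid fit recovers known parameters and the midpoint identity", {
  truth <- c(A = 0.11, B = 1.04, C = -0.0049, D = 0.0055)
  lams <- c(1.00, 1.02, 1.03, 1.04, 1.05, 1.06, 1.09)
  fr <- sigmoid_helicity(lams, truth["A"], truth["B"], truth["C"], truth["D"])
  fit <- fit_sigmoid(lams, fr)
  expect_equal(c(fit$A, fit$B, fit$C, fit$D), unname(truth),
               tolerance = 1e-4)
  expect_lt(fit$residual, 1e-8)
  expect_equal(sigmoid_helicity(fit$B, fit$A, fit$B, fit$C, fit$D),
               fit$A / 2 + fit$D)
  expect_error(fit_sigmoid(lams, rep(0.2, 7)), "constant")
})
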