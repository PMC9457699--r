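# Shared oracle helpers for the suite.  Oracles are deliberately written
# independently of the implementation paths they check.

kT300 <- 0.0019872041 * 300

# Bin-averaged Boltzmann free energy of an analytic 1D potential:
# F_bin = -kT log mean_bin exp(-U/kT), evaluated by dense quadrature.
quadrature_pmf <- function(Ufun, edges, kT = kT300, n_quad = 201) {
  nb <- length(edges) - 1L
  vapply(seq_len(nb), function(b) {
    xx <- seq(edges[b], edges[b + 1L], length.out = n_quad)
    -kT * log(mean(exp(-Ufun(xx) / kT)))
  }, 0)
}

# Align two shift-arbitrary free-energy curves on a common bin selection
# (both re-anchored at their minimum over the selection).
align_min <- function(F1, F2, sel) {
  list(a = F1 - min(F1[sel]), b = F2 - min(F2[sel]))
}

# Brute-force minimal RMSD over rotation space: random-quaternion grid plus
# Nelder-Mead refinement on the axis-angle parameters.  Independent of the
# SVD path.
brute_force_rmsd <- function(X, Y, n_grid = 20000, seed = 99) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj_q <- function(q) sqrt(mean(rowSums((Yc %*% rot_of(q) - Xc)^2)))
  set.seed(seed)
  Q <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(Q, 1, obj_q)
  best <- Q[which.min(vals), ]
  opt <- optim(best, obj_q, control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- optim(opt$par, obj_q, control = list(reltol = 1e-14, maxit = 5000))
  min(opt$value, opt2$value)
}

# Deterministic small parameter text used by several files
fixture_prm <- function() mini_prm(3, 2)
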