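# Histogram PMFs, GaMD cumulant reweighting, MBAR, and the two-step chain.

test_that("histogram PMF is flat for uniform samples and masks empty bins", {
  set.seed(2)
  x <- runif(20000, 0, 1)
  g <- histogram_pmf(x, seq(0, 1, by = 0.1), 300)
  expect_true(all(g$mask))
  expect_lt(max(g$F), 0.05)                # flat within sampling noise
  expect_equal(min(g$F[g$mask]), 0)

  x2 <- c(runif(500, 0, 0.3), runif(500, 0.7, 1))
  g2 <- histogram_pmf(x2, seq(0, 1, by = 0.1), 300)
  expect_false(all(g2$mask))
  expect_true(all(is.na(g2$F[!g2$mask])))  # masked, not -Inf
  expect_error(histogram_pmf(c(5, 6), seq(0, 1, by = 0.5), 300), "outside")
})

test_that("histogram PMF recovers a harmonic potential from Boltzmann samples", {
  s <- langevin_1d(11, 100000, "harmonic", pot_args = list(k = 2),
                   dt = 0.05, thin = 5)
  edges <- seq(-1.2, 1.2, by = 0.2)
  g <- histogram_pmf(s$x, edges, 300, n_min = 100)
  ref <- quadrature_pmf(function(x) harmonic(x, k = 2), edges)
  al <- align_min(g$F, ref, g$mask)
  expect_lt(max(abs(al$a[g$mask] - al$b[g$mask])), 0.1)
})

test_that("GaMD reweighting is exact for zero or constant boost", {
  set.seed(4)
  x <- rnorm(5000)
  edges <- seq(-2.5, 2.5, by = 0.5)
  base <- histogram_pmf(x, edges, 300)
  z <- gamd_reweight(x, rep(0, 5000), edges, 300)
  expect_equal(z$F, base$F)
  cst <- gamd_reweight(x, rep(3.7, 5000), edges, 300)
  expect_equal(cst$F, base$F, tolerance = 1e-10)
  expect_error(gamd_reweight(x, rep(0, 5000), edges, 300, order = 3), "order")
  expect_error(gamd_reweight(x, rep(-1, 5000), edges, 300), "non-negative")
})

test_that("GaMD cumulant reweighting recovers the harmonic PMF", {
  eq <- langevin_1d(11, 20000, "harmonic", pot_args = list(k = 2),
                    dt = 0.05, thin = 5)
  bs <- boost_spec(eq$U, sigma0 = 6)
  s <- langevin_1d(12, 100000, "harmonic", pot_args = list(k = 2),
                   dt = 0.05, thin = 5, boost = bs)
  expect_true(all(s$boost >= 0))
  edges <- seq(-1.6, 1.6, by = 0.16)
  g <- gamd_reweight(s$x, s$boost, edges, 300, n_min = 100)
  ref <- quadrature_pmf(function(x) harmonic(x, k = 2), edges)
  sel <- g$mask & g$counts >= 100
  al <- align_min(g$F, ref, sel)
  expect_lt(max(abs(al$a[sel] - al$b[sel])), 0.2)
})

test_that("MBAR solves degenerate window sets exactly", {
  # two identical windows
  u <- matrix(0, 2, 400)
  sol <- mbar_solve(u, c(200, 200))
  expect_equal(sol$f, c(0, 0), tolerance = 1e-10)

  # equal-force-constant biases on a flat landscape: f_k all equal
  set.seed(9)
  x <- runif(3000, -4, 4)
  win <- lapply(c(-1, 0, 1), function(c) list(center = c, k = 0))
  u2 <- umbrella_u_matrix(x, win, 300)
  sol2 <- mbar_solve(u2, c(1000, 1000, 1000))
  expect_equal(sol2$f, rep(0, 3), tolerance = 1e-10)
})

test_that("MBAR umbrella PMF matches quadrature on the double-well", {
  win <- double_well_umbrella_set()
  sam <- sample_umbrella_set(300, win, n_steps = 80000L, thin = 10L)
  edges <- seq(-2, 2, by = 0.2)
  g <- mbar_pmf(sam$x, sam$N_k, win, edges, 300, n_min = 50)
  ref <- quadrature_pmf(double_well, edges)
  al <- align_min(g$F, ref, g$mask)
  expect_lt(max(abs(al$a[g$mask] - al$b[g$mask])), 0.15)
  expect_gte(sum(g$mask), 18)              # both wells and barrier reported
})

test_that("PMF accuracy improves monotonically with sample size", {
  edges <- seq(-1.2, 1.2, by = 0.2)
  ref <- quadrature_pmf(function(x) harmonic(x, k = 2), edges)
  rmsd_at <- function(n, seed) {
    s <- langevin_1d(seed, 5L * n, "harmonic", pot_args = list(k = 2),
                     dt = 0.05, thin = 5)
    g <- histogram_pmf(s$x, edges, 300, n_min = 10)
    al <- align_min(g$F, ref, g$mask)
    sqrt(mean((al$a[g$mask] - al$b[g$mask])^2))
  }
  errs <- c(rmsd_at(1e3, 1), rmsd_at(1e4, 2), rmsd_at(1e5, 3))
  expect_true(all(diff(errs) < 0))
})

test_that("PMFs are invariant under constant shifts of the boost", {
  s <- langevin_1d(15, 20000, "harmonic", pot_args = list(k = 1),
                   dt = 0.05, thin = 5)
  edges <- seq(-2, 2, by = 0.25)
  dv <- abs(sin(seq_along(s$x)))           # arbitrary non-negative boosts
  g1 <- gamd_reweight(s$x, dv, edges, 300)
  g2 <- gamd_reweight(s$x, dv + 5, edges, 300)
  expect_equal(g1$F, g2$F, tolerance = 1e-9)
})

test_that("two-step reweighting degenerates correctly and recovers the well", {
  # zero boost + single zero-k window == histogram PMF
  s <- langevin_1d(21, 30000, "double_well", dt = 0.02, thin = 5, x0 = 1.5)
  edges <- seq(0.4, 2.4, by = 0.2)
  flat <- list(list(center = 0, k = 0))
  g1 <- gareus_reweight(s$x, rep(0, length(s$x)), length(s$x), flat, edges, 300)
  g0 <- histogram_pmf(s$x, edges, 300)
  expect_equal(g1$F, g0$F, tolerance = 1e-9)

  # zero boost, multi-window == plain MBAR PMF
  win <- double_well_umbrella_set()
  sam <- sample_umbrella_set(400, win, n_steps = 30000L, thin = 10L)
  edges2 <- seq(-2, 2, by = 0.2)
  gz <- gareus_reweight(sam$x, rep(0, length(sam$x)), sam$N_k, win,
                        edges2, 300, n_min = 30)
  gm <- mbar_pmf(sam$x, sam$N_k, win, edges2, 300, n_min = 30)
  expect_equal(gz$F, gm$F, tolerance = 1e-6)
})

test_that("boosted multi-window double-well matches the quadrature oracle", {
  eqw <- langevin_1d(31, 20000, "double_well", dt = 0.02, thin = 5, x0 = 1.5)
  bs <- boost_spec(eqw$U, sigma0 = 6)
  win <- double_well_umbrella_set()
  sam <- sample_umbrella_set(500, win, n_steps = 80000L, thin = 10L,
                             boost = bs)
  expect_true(all(sam$boost >= 0))
  edges <- seq(-2, 2, by = 0.2)
  g <- gareus_reweight(sam$x, sam$boost, sam$N_k, win, edges, 300,
                       n_min = 50)
  ref <- quadrature_pmf(double_well, edges)
  al <- align_min(g$F, ref, g$mask)
  expect_lt(max(abs(al$a[g$mask] - al$b[g$mask])), 0.2)
})

test_that("MBAR with two states agrees with BAR on shared work data", {
  w <- crooks_work_samples(77, 3000, 1.3, 0.8)
  beta <- beta_kcal(300)
  nF <- length(w$forward); nR <- length(w$reverse)
  u <- rbind(c(rep(0, nF), beta * w$reverse),
             c(beta * w$forward, rep(0, nR)))
  sol <- mbar_solve(u, c(nF, nR))
  dF_mbar <- sol$f[2] / beta
  expect_equal(dF_mbar, bar(w)$dF, tolerance = 1e-6)
})
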