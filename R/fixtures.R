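# Seeded synthetic generators: peptide backbones at prescribed dihedrals,
# Brownian particles with known D, 1D Langevin samples under GaMD-form or
# umbrella biases, Crooks-consistent work distributions, and miniature
# CHARMM parameter texts.  Every generator is a pure function of its
# arguments (bit-reproducible given the seed).

# ---- internal-coordinate backbone construction ------------------------------

# Standard backbone geometry (lengths A, angles degrees)
.bb_geom <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.229,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.5)

#' Place a point from three predecessors by internal coordinates
#'
#' NeRF construction: distance r from C, angle theta at C (B-C-D), torsion
#' chi about B-C measured as A-B-C-D.
#'
#' @param A,B,C anchor points (numeric 3-vectors)
#' @param r bond length
#' @param theta bond angle, degrees
#' @param chi torsion, degrees
#' @return numeric 3-vector
#' @export
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a capped peptide backbone at prescribed dihedrals
#'
#' Sequential internal-coordinate construction of an N-CA-C(=O) backbone
#' with standard geometry and omega = 180.  Acetyl- and amide-like cap
#' heavy atoms are added so that phi and psi are defined for every one of
#' the \code{n_res} residues.  Measured dihedrals reproduce the request to
#' numerical precision.
#'
#' @param phi per-residue phi, degrees (scalar recycled)
#' @param psi per-residue psi, degrees (scalar recycled)
#' @param n_res number of residues (>= 2)
#' @param res_name residue name used for all residues (default "ALA")
#' @return list with \code{top} (\code{ff_topology}) and \code{traj}
#'   (single-frame \code{ff_trajectory}); cap residues are named ACE/NME
#'   and have incomplete backbones, so they are excluded from the backbone
#'   map automatically
#' @export
build_backbone <- function(phi = -57, psi = -47, n_res = 15,
                           res_name = "ALA") {
  stopifnot(n_res >= 2L)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  g <- .bb_geom
  # seed: cap CH3 - cap C, then N1; torsions for the seed atoms are
  # arbitrary (they only set the global orientation)
  CH3 <- c(0, 0, 0)
  C0 <- CH3 + c(1.52, 0, 0)
  N1 <- place_atom(c(0, 1, 0), CH3, C0, g$b_C_N, g$a_CA_C_N, 180)

  coords <- list(CH3, C0)
  name <- c("CH3", "C"); resi <- c(0L, 0L); resn <- c("ACE", "ACE")
  prevC <- C0; prevCA <- CH3   # for the first C-N-CA angle/torsion chain
  N <- N1
  omega <- 180
  for (i in seq_len(n_res)) {
    CA <- place_atom(prevCA, prevC, N, g$b_N_CA, g$a_C_N_CA, omega)
    C  <- place_atom(prevC, N, CA, g$b_CA_C, g$a_N_CA_C, phi[i])
    Nn <- place_atom(N, CA, C, g$b_C_N, g$a_CA_C_N, psi[i])
    O  <- place_atom(N, CA, C, g$b_C_O, g$a_CA_C_O, psi[i] + 180)
    coords <- c(coords, list(N, CA, C, O))
    name <- c(name, "N", "CA", "C", "O")
    resi <- c(resi, rep(i, 4L)); resn <- c(resn, rep(res_name, 4L))
    prevCA <- CA; prevC <- C; N <- Nn
  }
  # amide cap: the final N plus its methyl carbon
  CT <- place_atom(prevCA, prevC, N, g$b_N_CA, g$a_C_N_CA, omega)
  coords <- c(coords, list(N, CT))
  name <- c(name, "N", "CH3")
  resi <- c(resi, rep(n_res + 1L, 2L)); resn <- c(resn, rep("NME", 2L))

  X <- do.call(rbind, coords)
  arr <- array(NA_real_, c(1L, nrow(X), 3L)); arr[1, , ] <- X
  top <- ff_topology(name, substr(name, 1, 1), resi, resn)
  list(top = top, traj = ff_trajectory(arr, wrapped = FALSE))
}

# ---- stochastic generators --------------------------------------------------

#' Brownian particle trajectory with known diffusion coefficient
#'
#' Independent Gaussian displacements per axis with variance 2 D dt,
#' wrapped into [0, L).  Times in ps, coordinates in Angstrom.
#'
#' @param seed RNG seed
#' @param n_particles number of particles
#' @param n_frames number of frames
#' @param D_true diffusion coefficient, nm^2/ns
#' @param L cubic box edge, Angstrom
#' @param dt frame spacing, ps
#' @return wrapped \code{ff_trajectory}
#' @export
brownian_traj <- function(seed, n_particles, n_frames, D_true, L, dt = 1) {
  stopifnot(n_particles >= 1L, n_frames >= 2L, D_true >= 0, L > 0, dt > 0)
  D_Aps <- D_true / ff_constants$A2ps_to_nm2ns     # nm^2/ns -> A^2/ps
  stepsd <- sqrt(2 * D_Aps * dt)
  if (stepsd >= L / 4)
    stop("step size too large relative to the box: unwrap would be unsafe")
  set.seed(seed)
  co <- array(NA_real_, c(n_frames, n_particles, 3))
  co[1, , ] <- matrix(runif(n_particles * 3, 0, L), n_particles, 3)
  for (f in 2:n_frames)
    co[f, , ] <- co[f - 1, , ] +
      matrix(rnorm(n_particles * 3, 0, stepsd), n_particles, 3)
  co <- co - L * floor(co / L)
  ff_trajectory(co, box = c(L, L, L), times = (seq_len(n_frames) - 1) * dt,
                wrapped = TRUE)
}

#' Double-well test potential
#'
#' U(x) = a (x^2 - b^2)^2 with defaults (a, b) = (1, 1.5) in kcal/mol and
#' Angstrom: two basins at +-1.5 A separated by a ~5 kcal/mol barrier
#' (about 8.5 kB T at 300 K), resolvable by 8 umbrella windows.
#'
#' @param x positions, Angstrom
#' @param a,b parameters
#' @return energies (kcal/mol); \code{double_well_grad} returns dU/dx
#' @export
double_well <- function(x, a = 1, b = 1.5) a * (x^2 - b^2)^2

#' @rdname double_well
#' @export
double_well_grad <- function(x, a = 1, b = 1.5) 4 * a * x * (x^2 - b^2)

#' Harmonic test potential
#' @param x positions, Angstrom
#' @param k force constant, kcal/(mol A^2)
#' @param x0 center, Angstrom
#' @return energies; \code{harmonic_grad} the gradient
#' @export
harmonic <- function(x, k = 1, x0 = 0) 0.5 * k * (x - x0)^2

#' @rdname harmonic
#' @export
harmonic_grad <- function(x, k = 1, x0 = 0) k * (x - x0)

#' GaMD-form boost specification from an equilibration segment
#'
#' Lower-bound threshold mode: the threshold E is the maximum potential
#' seen; the dimensionless force constant k0 in (0, 1] is chosen by the
#' sigma0 rule, k0 = min(1, (sigma0/sigma_U) (E - Umin)/(E - Uavg)), and the
#' boost is DeltaV(x) = 0.5 k (E - U(x))^2 for U < E with
#' k = k0 / (E - Umin).  Guarantees DeltaV >= 0 and keeps the boost
#' standard deviation at or below sigma0 on the sampled ensemble.
#'
#' @param U_equil potential energies of an unbiased equilibration segment
#' @param sigma0 target upper bound on sd(DeltaV), kcal/mol (default 6)
#' @return object of class \code{boost_spec}: E, k0, k, sigma0
#' @export
boost_spec <- function(U_equil, sigma0 = 6) {
  stopifnot(length(U_equil) >= 2L, sigma0 > 0)
  E <- max(U_equil); Umin <- min(U_equil); Uavg <- mean(U_equil)
  sdU <- sd(U_equil)
  if (E - Umin < .Machine$double.eps)
    stop("flat potential segment: boost undefined")
  k0 <- min(1, (sigma0 / sdU) * (E - Umin) / (E - Uavg))
  structure(list(E = E, k0 = k0, k = k0 / (E - Umin), sigma0 = sigma0),
            class = "boost_spec")
}

#' Evaluate a GaMD boost
#' @param spec \code{boost_spec}
#' @param U potential energies
#' @return DeltaV >= 0, kcal/mol
#' @export
boost_energy <- function(spec, U) {
  dv <- 0.5 * spec$k * pmax(spec$E - U, 0)^2
  dv
}

#' Overdamped 1D Langevin sampler with optional bias
#'
#' Euler-Maruyama on U(x) (+ boost and/or umbrella):
#' x <- x - beta D grad(U_total) dt + sqrt(2 D dt) xi, with a Metropolis
#' acceptance step (MALA) so that the sampled distribution is exactly
#' proportional to exp(-beta U_total) at any stable time step.  Emits
#' positions and the per-sample boost and umbrella energies needed by the
#' reweighting estimators.
#'
#' @param seed RNG seed
#' @param n_steps steps after burn-in
#' @param potential "harmonic" or "double_well"
#' @param pot_args list of parameters passed to the potential
#' @param temperature K
#' @param dt time step (reduced units; stability requires dt small against
#'   the curvature)
#' @param D mobility coefficient of the overdamped dynamics (A^2 per step
#'   unit; affects kinetics only, not the sampled distribution)
#' @param x0 initial position
#' @param burn_in discarded steps
#' @param boost optional \code{boost_spec}
#' @param umbrella optional \code{list(center=, k=)} harmonic bias
#' @param thin keep every thin-th sample
#' @param bound divergence guard on |x|
#' @return list with \code{x}, \code{U} (unbiased potential),
#'   \code{boost} (DeltaV per sample), \code{umbrella_energy}
#' @export
langevin_1d <- function(seed, n_steps, potential = c("harmonic", "double_well"),
                        pot_args = list(), temperature = 300, dt = 0.02,
                        D = 1, x0 = 0, burn_in = 1000L, boost = NULL,
                        umbrella = NULL, thin = 1L, bound = 50) {
  potential <- match.arg(potential)
  Ufun <- switch(potential, harmonic = harmonic, double_well = double_well)
  Gfun <- switch(potential, harmonic = harmonic_grad,
                 double_well = double_well_grad)
  beta <- beta_kcal(temperature)
  utot <- function(x) {
    U <- do.call(Ufun, c(list(x), pot_args))
    v <- U
    if (!is.null(boost) && U < boost$E)
      v <- v + 0.5 * boost$k * (boost$E - U)^2
    if (!is.null(umbrella))
      v <- v + 0.5 * umbrella$k * (x - umbrella$center)^2
    v
  }
  gtot <- function(x) {
    g <- do.call(Gfun, c(list(x), pot_args))
    if (!is.null(boost)) {
      U <- do.call(Ufun, c(list(x), pot_args))
      if (U < boost$E) g <- g * (1 - boost$k * (boost$E - U))
    }
    if (!is.null(umbrella)) g <- g + umbrella$k * (x - umbrella$center)
    g
  }
  set.seed(seed)
  ntot <- burn_in + n_steps
  x <- x0
  ux <- utot(x); gx <- gtot(x)
  keep <- seq(burn_in + thin, ntot, by = thin)
  out <- numeric(length(keep))
  ki <- 1L
  noise <- rnorm(ntot, 0, sqrt(2 * D * dt))
  lu <- log(runif(ntot))
  s4 <- 4 * D * dt
  for (s in seq_len(ntot)) {
    xp <- x - beta * D * gx * dt + noise[s]
    up <- utot(xp); gp <- gtot(xp)
    # MALA acceptance: target change plus proposal asymmetry
    la <- -beta * (up - ux) -
      (x - xp + beta * D * gp * dt)^2 / s4 +
      (xp - x + beta * D * gx * dt)^2 / s4
    if (la >= 0 || lu[s] < la) { x <- xp; ux <- up; gx <- gp }
    if (abs(x) > bound)
      stop("Langevin sampler diverged (|x| > ", bound,
           "); reduce dt or check the potential")
    if (ki <= length(keep) && s == keep[ki]) { out[ki] <- x; ki <- ki + 1L }
  }
  U <- do.call(Ufun, c(list(out), pot_args))
  dv <- if (!is.null(boost)) boost_energy(boost, U) else numeric(length(out))
  ue <- if (!is.null(umbrella))
    0.5 * umbrella$k * (out - umbrella$center)^2 else numeric(length(out))
  list(x = out, U = U, boost = dv, umbrella_energy = ue)
}

#' Crooks-consistent Gaussian work samples with known free energy
#'
#' Forward work ~ N(dF + beta sigma^2 / 2, sigma^2) and reverse work
#' ~ N(-dF + beta sigma^2 / 2, sigma^2); this Gaussian pair satisfies the
#' Crooks fluctuation relation exactly, so every consistent estimator must
#' recover dF.
#'
#' @param seed RNG seed
#' @param n samples per direction
#' @param dF_true target free-energy difference, kcal/mol
#' @param sigma work standard deviation, kcal/mol
#' @param temperature K
#' @return \code{work_samples}
#' @export
crooks_work_samples <- function(seed, n, dF_true, sigma, temperature = 300) {
  stopifnot(sigma > 0, n >= 2L)
  beta <- beta_kcal(temperature)
  set.seed(seed)
  wf <- rnorm(n, dF_true + beta * sigma^2 / 2, sigma)
  wr <- rnorm(n, -dF_true + beta * sigma^2 / 2, sigma)
  work_samples(wf, wr, temperature)
}

#' Miniature CHARMM nonbonded parameter text
#'
#' Syntactically valid NONBONDED section with distinct tokens and round
#' numbers, including a comment line and the ignored first numeric column,
#' suitable for exercising the parser and the NBFIX generator.
#'
#' @param n_protein_types,n_water_types counts (>= 1); water tokens are
#'   OT, HT, OT2, HT2, ...
#' @return character vector of lines
#' @export
mini_prm <- function(n_protein_types = 3L, n_water_types = 2L) {
  stopifnot(n_protein_types >= 1L, n_water_types >= 1L)
  ptok <- paste0("CP", seq_len(n_protein_types))
  wbase <- c("OT", "HT")
  wtok <- vapply(seq_len(n_water_types), function(i) {
    b <- wbase[(i - 1L) %% 2L + 1L]; s <- (i - 1L) %/% 2L
    if (s == 0L) b else paste0(b, s + 1L)
  }, "")
  eps <- -round(0.04 * seq_len(n_protein_types), 4)
  rmh <- round(1.8 + 0.1 * seq_len(n_protein_types), 4)
  weps <- -round(c(0.1521, 0.046, 0.16, 0.05)[seq_len(n_water_types)], 4)
  wrmh <- round(c(1.7682, 0.2245, 1.76, 0.23)[seq_len(n_water_types)], 4)
  c("* miniature nonbonded parameter fixture",
    "*",
    "",
    "NONBONDED nbxmod  5 atom cdiel fshift vatom vdistance vfswitch -",
    "cutnb 14.0 ctofnb 12.0 ctonnb 10.0 eps 1.0 e14fac 1.0 wmin 1.5",
    "! token   ignored  epsilon  Rmin/2",
    sprintf("%-6s 0.0 %9.4f %8.4f ! protein-like type", ptok, eps, rmh),
    sprintf("%-6s 0.0 %9.4f %8.4f ! water type", wtok, weps, wrmh),
    "",
    "END")
}

#' Water tokens emitted by \code{mini_prm}
#' @param n_water_types count
#' @return character vector
#' @export
mini_prm_water_types <- function(n_water_types = 2L) {
  wbase <- c("OT", "HT")
  vapply(seq_len(n_water_types), function(i) {
    b <- wbase[(i - 1L) %% 2L + 1L]; s <- (i - 1L) %/% 2L
    if (s == 0L) b else paste0(b, s + 1L)
  }, "")
}

#' Reference umbrella-window schedule for the double-well fixture
#'
#' Eight harmonic windows spanning the default double-well landscape:
#' soft windows in the basins, stiff windows holding the chain at the
#' barrier top and at the outer walls (mixed force constants, as in
#' practical REUS schedules).  Centers in Angstrom, force constants in
#' kcal/(mol A^2).
#'
#' @return list of \code{list(center=, k=)} windows
#' @export
double_well_umbrella_set <- function() {
  centers <- c(-2.1, -1.4, -0.6, -0.15, 0.15, 0.6, 1.4, 2.1)
  ks <- c(20, 6, 15, 25, 25, 15, 6, 20)
  Map(function(c, k) list(center = c, k = k), centers, ks)
}

#' Sample every umbrella window of a schedule
#'
#' Runs the Langevin sampler once per window (seeded seed + window index)
#' and concatenates the blocks in window order.
#'
#' @param seed base RNG seed
#' @param windows list of \code{list(center=, k=)}
#' @param n_steps,thin,dt sampler controls per window
#' @param potential,pot_args passed to \code{langevin_1d}
#' @param boost optional \code{boost_spec} applied in every window
#' @param temperature K
#' @return list with \code{x}, \code{boost}, \code{N_k}
#' @export
sample_umbrella_set <- function(seed, windows, n_steps = 160000L,
                                thin = 10L, dt = 0.02,
                                potential = "double_well",
                                pot_args = list(), boost = NULL,
                                temperature = 300) {
  xs <- numeric(0); dv <- numeric(0); Nk <- integer(0)
  for (i in seq_along(windows)) {
    s <- langevin_1d(seed + i, n_steps, potential, pot_args = pot_args,
                     temperature = temperature, dt = dt,
                     x0 = windows[[i]]$center, boost = boost,
                     umbrella = windows[[i]], thin = thin)
    xs <- c(xs, s$x); dv <- c(dv, s$boost); Nk <- c(Nk, length(s$x))
  }
  list(x = xs, boost = dv, N_k = Nk)
}
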