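# Translational diffusion with finite-size and viscosity corrections.
#
# The full chain: D = D_MSD + D_PBC(Rh, eta, L)  with the Yeh-Hummer
# periodic-boundary correction; for crowded systems the solvent viscosity
# is replaced by the Einstein suspension viscosity eta_c = eta (1 + 2.5 phi);
# D' = D * eta_sim / eta_expt rescales to the experimental water viscosity.
# Inputs in K / cP / Angstrom, diffusion outputs in nm^2/ns.

#' Mean square displacement curve
#'
#' MSD(tau) = <|r(t0 + tau) - r(t0)|^2> averaged over all time origins t0
#' and selected particles (or per-molecule centers of geometry when a
#' molecule map is given).  Requires an unwrapped trajectory.
#'
#' @param traj unwrapped \code{ff_trajectory}
#' @param selection atom indices (default all)
#' @param molecules optional list of atom-index vectors; each molecule
#'   contributes its center of geometry
#' @param max_lag maximum lag in frames (default nf - 1)
#' @return object of class \code{msd_curve}: data.frame-like list with
#'   \code{lag} (ps), \code{msd} (nm^2), \code{n_pairs}
#' @export
msd <- function(traj, selection = NULL, molecules = NULL, max_lag = NULL) {
  stopifnot(inherits(traj, "ff_trajectory"))
  if (traj$wrapped)
    stop("trajectory is wrapped: call unwrap_pbc() before msd()")
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(max_lag)) max_lag <- nf - 1L
  max_lag <- min(max_lag, nf - 1L)

  if (!is.null(molecules)) {
    P <- array(NA_real_, c(nf, length(molecules), 3))
    for (m in seq_along(molecules))
      P[, m, ] <- apply(traj$coords[, molecules[[m]], , drop = FALSE],
                        c(1, 3), mean)
  } else {
    if (is.null(selection)) selection <- seq_len(n_atoms(traj))
    P <- traj$coords[, selection, , drop = FALSE]
  }
  np <- dim(P)[2]
  lags <- seq_len(max_lag)
  ms <- numeric(max_lag)
  npair <- integer(max_lag)
  for (tau in lags) {
    d <- P[(1L + tau):nf, , , drop = FALSE] - P[1L:(nf - tau), , , drop = FALSE]
    ms[tau] <- mean(apply(d^2, c(1, 2), sum))
    npair[tau] <- (nf - tau) * np
  }
  dt <- traj$times[2L] - traj$times[1L]
  structure(list(lag = c(0, lags * dt), msd = c(0, ms) * 1e-2,  # A^2 -> nm^2
                 n_pairs = c(np * nf, npair)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags, 0 .. %.1f ps, max %.4f nm^2\n",
              length(x$lag), max(x$lag), max(x$msd)))
  invisible(x)
}

#' Diffusion coefficient from the linear MSD regime
#'
#' Least-squares slope of MSD vs lag over the fit window, divided by 6
#' (three dimensions), converted to nm^2/ns.
#'
#' @param m \code{msd_curve}
#' @param window c(t_lo, t_hi) in ps; points with t_lo <= lag <= t_hi enter
#'   the fit
#' @return D_MSD in nm^2/ns
#' @export
fit_diffusion <- function(m, window) {
  stopifnot(inherits(m, "msd_curve"), length(window) == 2L)
  sel <- m$lag >= window[1L] & m$lag <= window[2L]
  if (sum(sel) < 2L) stop("fewer than 2 MSD points inside the fit window")
  sl <- unname(coef(lm(m$msd[sel] ~ m$lag[sel]))[2L])  # nm^2 / ps
  sl * 1e3 / 6                                          # nm^2 / ns
}

#' Yeh-Hummer finite-size correction for periodic boundaries
#'
#' D_PBC = kB T xi / (6 pi eta L) - 2 kB T Rh^2 / (9 eta L^3), with
#' xi = 2.837297 the cubic-lattice Ewald constant and the second term the
#' finite-solute-size extension.  Converted to nm^2/ns.
#'
#' @param temperature K
#' @param eta solvent viscosity, cP
#' @param L cubic box edge, Angstrom
#' @param Rh hydrodynamic radius, Angstrom
#' @return D_PBC in nm^2/ns
#' @export
yeh_hummer_correction <- function(temperature, eta, L, Rh) {
  stopifnot(temperature > 0, eta > 0, L > 0, Rh >= 0)
  kT <- ff_constants$kB_SI * temperature
  eta_si <- eta * ff_constants$cP_to_Pas
  L_si <- L * ff_constants$A_to_m
  Rh_si <- Rh * ff_constants$A_to_m
  d <- kT * ff_constants$xi_EW / (6 * pi * eta_si * L_si) -
    2 * kT * Rh_si^2 / (9 * eta_si * L_si^3)
  d * ff_constants$m2s_to_nm2ns
}

#' Einstein suspension viscosity
#'
#' eta_c = eta0 (1 + 2.5 phi); the dilute-suspension form, reliable for
#' phi below ~0.1 and used here up to phi < 0.5 with a warning.
#'
#' @param eta0 solvent viscosity, cP
#' @param phi crowder volume fraction
#' @return eta_c in cP
#' @export
einstein_viscosity <- function(eta0, phi) {
  if (phi < 0 || phi >= 1) stop("volume fraction must be in [0, 1)")
  if (phi >= 0.5) stop("Einstein relation not meaningful for phi >= 0.5")
  if (phi > 0.1)
    warning(sprintf("phi = %.3f above the strict Einstein validity (~0.1)",
                    phi))
  eta0 * (1 + 2.5 * phi)
}

#' Volume fraction of N crowder spheres in a cubic box
#'
#' phi = N (4/3) pi Rh^3 / L^3.
#'
#' @param N number of crowders
#' @param Rh sphere (hydrodynamic) radius, Angstrom
#' @param L cubic box edge, Angstrom
#' @return dimensionless volume fraction
#' @export
volume_fraction <- function(N, Rh, L) {
  stopifnot(N >= 0, Rh > 0, L > 0)
  N * (4 / 3) * pi * Rh^3 / L^3
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kB T / (6 pi eta Rh), in nm^2/ns.
#'
#' @param temperature K
#' @param eta viscosity, cP
#' @param Rh hydrodynamic radius, Angstrom
#' @return D in nm^2/ns
#' @export
stokes_einstein <- function(temperature, eta, Rh) {
  stopifnot(temperature > 0, eta > 0, Rh > 0)
  kT <- ff_constants$kB_SI * temperature
  d <- kT / (6 * pi * eta * ff_constants$cP_to_Pas *
               Rh * ff_constants$A_to_m)
  d * ff_constants$m2s_to_nm2ns
}

#' Full diffusion correction chain
#'
#' Applies the Einstein suspension viscosity (if phi > 0), the Yeh-Hummer
#' finite-size correction, and the experimental-viscosity rescaling:
#' D = D_MSD + D_PBC(T, eta_c, L, Rh); D' = D * eta_sim / eta_expt.
#'
#' @param D_MSD diffusion coefficient from the MSD slope, nm^2/ns
#' @param temperature K (default 300)
#' @param eta_sim simulation water viscosity, cP (default TIP3P, 0.35)
#' @param eta_expt experimental water viscosity, cP (default 0.89)
#' @param L cubic box edge, Angstrom
#' @param Rh hydrodynamic radius, Angstrom (default 13.86)
#' @param phi crowder volume fraction (default 0, dilute)
#' @return object of class \code{diffusion_result} with D_MSD, D_PBC, D,
#'   D_prime and all inputs
#' @export
correct_diffusion <- function(D_MSD, temperature = 300, eta_sim = 0.35,
                              eta_expt = 0.89, L, Rh = 13.86, phi = 0) {
  stopifnot(D_MSD >= 0)
  eta_used <- if (phi > 0) suppressWarnings(einstein_viscosity(eta_sim, phi))
              else eta_sim
  D_PBC <- yeh_hummer_correction(temperature, eta_used, L, Rh)
  D <- D_MSD + D_PBC
  structure(list(D_MSD = D_MSD, D_PBC = D_PBC, D = D,
                 D_prime = D * eta_sim / eta_expt,
                 temperature = temperature, eta = eta_used,
                 eta_sim = eta_sim, eta_expt = eta_expt,
                 L = L, Rh = Rh, phi = phi),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf(
    paste0("diffusion: D_MSD = %.3f, D_PBC = %.3f, D = %.3f, D' = %.3f nm^2/ns\n",
           "  (T = %g K, eta = %.3f cP, eta_expt = %.2f cP, L = %g A, ",
           "Rh = %g A, phi = %.3f)\n"),
    x$D_MSD, x$D_PBC, x$D, x$D_prime, x$temperature, x$eta, x$eta_expt,
    x$L, x$Rh, x$phi))
  invisible(x)
}
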