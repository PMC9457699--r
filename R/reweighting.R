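# Free-energy surfaces from biased sampling.
#
# PMFs are reported on half-open bins [lo, hi) (the upper edge of the last
# bin is included), masked below a minimum occupancy, and shift-normalized
# so the minimum over reported bins is zero.

#' Construct a PMF grid object
#' @keywords internal
.pmf_grid <- function(edges, F, mask, counts) {
  F[!mask] <- NA_real_
  if (any(mask)) F <- F - min(F[mask])
  structure(list(edges = edges, F = F, mask = mask, counts = counts),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  nd <- if (is.list(x$edges)) length(x$edges) else 1L
  cat(sprintf("PMF grid: %dD, %d bins reported (of %d), range 0 .. %.3f kcal/mol\n",
              nd, sum(x$mask), length(x$F),
              if (any(x$mask)) max(x$F[x$mask]) else NA_real_))
  invisible(x)
}

#' Bin index on half-open edges (upper edge of last bin included)
#' @keywords internal
.bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

#' Histogram potential of mean force
#'
#' F_bin = -kB T log(count / total / binwidth), empty or under-occupied
#' bins masked, minimum shifted to zero.
#'
#' @param samples collective-variable values (1D vector, or 2-column matrix
#'   for a 2D surface)
#' @param edges numeric vector of bin edges (1D), or list of two edge
#'   vectors (2D)
#' @param temperature K
#' @param weights optional per-sample weights
#' @param n_min minimum samples (or effective weight-equivalents) per
#'   reported bin; default 20
#' @return \code{pmf_grid}
#' @export
histogram_pmf <- function(samples, edges, temperature = 300,
                          weights = NULL, n_min = 20) {
  kT <- ff_constants$kB * temperature
  two_d <- is.list(edges)
  if (two_d) {
    samples <- as.matrix(samples)
    stopifnot(ncol(samples) == 2L)
    i1 <- .bin_index(samples[, 1], edges[[1L]])
    i2 <- .bin_index(samples[, 2], edges[[2L]])
    ok <- !is.na(i1) & !is.na(i2)
    if (!any(ok)) stop("all samples fall outside the grid")
    n1 <- length(edges[[1L]]) - 1L; n2 <- length(edges[[2L]]) - 1L
    w <- if (is.null(weights)) rep(1, length(i1)) else weights
    counts <- matrix(0, n1, n2)
    raw <- matrix(0, n1, n2)
    for (k in which(ok)) {
      counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
      raw[i1[k], i2[k]] <- raw[i1[k], i2[k]] + w[k]
    }
    area <- outer(diff(edges[[1L]]), diff(edges[[2L]]))
    p <- raw / sum(raw) / area
    mask <- counts >= n_min & p > 0
    F <- -kT * log(p)
    return(.pmf_grid(edges, F, mask, counts))
  }
  samples <- as.numeric(samples)
  idx <- .bin_index(samples, edges)
  ok <- !is.na(idx)
  if (!any(ok)) stop("all samples fall outside the grid")
  nb <- length(edges) - 1L
  w <- if (is.null(weights)) rep(1, length(idx)) else weights
  counts <- tabulate(idx[ok], nb)
  raw <- vapply(seq_len(nb), function(b) sum(w[ok][idx[ok] == b]), 0)
  width <- diff(edges)
  p <- raw / sum(raw) / width
  mask <- counts >= n_min & p > 0
  F <- -kT * log(p)
  .pmf_grid(edges, F, mask, counts)
}

#' Cumulant-expansion reweighting of GaMD-boosted samples
#'
#' Removes a non-negative boost potential DeltaV from a biased histogram by
#' the per-bin cumulant expansion of log <exp(beta DeltaV)>: to second
#' order, C1 + C2/2 with C1 the mean and C2 the variance of beta DeltaV
#' among the samples of that bin.  F_bin = -kB T [log p_biased(bin) + C1 +
#' C2/2], minimum shifted.
#'
#' @param samples CV values (1D vector or 2-column matrix)
#' @param boost per-sample boost energies DeltaV, kcal/mol (>= 0)
#' @param edges bin edges as in \code{histogram_pmf}
#' @param temperature K
#' @param order cumulant order, 1 or 2 (default 2)
#' @param n_min minimum bin occupancy
#' @return \code{pmf_grid}
#' @export
gamd_reweight <- function(samples, boost, edges, temperature = 300,
                          order = 2L, n_min = 20) {
  if (!order %in% c(1L, 2L)) stop("cumulant order must be 1 or 2")
  if (any(boost < -1e-9)) stop("boost potential must be non-negative")
  kT <- ff_constants$kB * temperature
  b <- boost / kT                       # beta DeltaV
  two_d <- is.list(edges)
  if (two_d) {
    samples <- as.matrix(samples)
    i1 <- .bin_index(samples[, 1], edges[[1L]])
    i2 <- .bin_index(samples[, 2], edges[[2L]])
    ok <- !is.na(i1) & !is.na(i2)
    n1 <- length(edges[[1L]]) - 1L; n2 <- length(edges[[2L]]) - 1L
    key <- i1 + (i2 - 1L) * n1          # column-major, matches matrix F
  } else {
    idx <- .bin_index(as.numeric(samples), edges)
    ok <- !is.na(idx)
    key <- idx
    n1 <- length(edges) - 1L; n2 <- 1L
  }
  if (length(b) != length(ok)) stop("one boost value per sample required")
  if (!any(ok)) stop("all samples fall outside the grid")

  base <- histogram_pmf(samples, edges, temperature, n_min = n_min)
  corr <- rep(0, length(base$F))
  dim(corr) <- dim(base$F)                # matrix for 2D, vector for 1D
  for (bin in which(base$mask)) {
    sel <- ok & key == bin
    bb <- b[sel]
    c1 <- mean(bb)
    c2 <- if (order == 2L) var(bb) else 0
    if (is.na(c2)) c2 <- 0
    corr[bin] <- c1 + c2 / 2
  }
  F <- base$F - kT * corr               # adds log-weight to probability
  .pmf_grid(base$edges, F, base$mask, base$counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- MBAR -------------------------------------------------------------------

#' Solve the MBAR self-consistent equations
#'
#' Given the reduced (beta-scaled, dimensionless) bias energies
#' \code{u[k, n]} of every sample n evaluated in every window k and the
#' sample counts per window \code{N_k}, iterates
#' f_k = -log sum_n exp(-u_k(n)) / sum_l N_l exp(f_l - u_l(n))
#' with log-sum-exp stabilization until max |delta f| < tol, damping the
#' update when the residual grows.  f_1 is anchored at 0.
#'
#' @param u K x N matrix of reduced energies
#' @param N_k integer vector of per-window sample counts (sum = N)
#' @param tol convergence tolerance on max |delta f| (default 1e-8)
#' @param max_iter maximum iterations
#' @return list with \code{f} (dimensionless window free energies, f[1] = 0),
#'   \code{weights} (per-sample unbiased weights, normalized), \code{iter}
#' @export
mbar_solve <- function(u, N_k, tol = 1e-8, max_iter = 10000L) {
  u <- as.matrix(u)
  K <- nrow(u); N <- ncol(u)
  stopifnot(length(N_k) == K, sum(N_k) == N, all(is.finite(u)))
  .overlap_warn(u, N_k)
  logN <- log(N_k)
  # log denominator per sample: log sum_l N_l exp(f_l - u_l(n)),
  # column-wise log-sum-exp over the K x N matrix
  logden_of <- function(f) {
    M <- (logN + f) - u
    m <- M[1L, ]
    if (K > 1L) for (k in 2:K) m <- pmax(m, M[k, ])
    m + log(colSums(exp(M - rep(m, each = K))))
  }
  lse_row <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  sc_update <- function(f) {
    A <- -u - rep(logden_of(f), each = K)
    fnew <- -apply(A, 1, lse_row)
    fnew - fnew[1L]
  }
  # Newton iteration on the gauge-fixed (f1 = 0) stationarity conditions of
  # the convex MBAR objective; quadratic convergence near the solution.
  # Falls back to damped self-consistent steps when a Newton step misfires.
  grad_hess <- function(f) {
    P <- exp((logN + f) - u - rep(logden_of(f), each = K))  # softmax cols
    g <- (rowSums(P) - N_k) / N
    H <- (diag(rowSums(P), K) - tcrossprod(P)) / N
    list(g = g, H = H)
  }
  kappa <- function(f) mean(logden_of(f)) - sum(N_k * f) / N
  f <- numeric(K)
  it_used <- 0L
  if (K > 1L) {
    k0 <- kappa(f)
    for (it in seq_len(200L)) {
      gh <- grad_hess(f)
      dir <- tryCatch(
        -solve(gh$H[-1L, -1L, drop = FALSE] + diag(1e-10, K - 1L),
               gh$g[-1L]),
        error = function(e) -gh$g[-1L])
      slope <- sum(gh$g[-1L] * dir)
      if (slope > 0) { dir <- -gh$g[-1L]; slope <- -sum(gh$g[-1L]^2) }
      # backtracking line search on the convex objective
      step_t <- 1
      repeat {
        ftry <- f; ftry[-1L] <- f[-1L] + step_t * dir
        ktry <- kappa(ftry)
        if (is.finite(ktry) && ktry <= k0 + 1e-4 * step_t * slope) break
        step_t <- step_t / 2
        if (step_t < 1e-12) break
      }
      f <- f; f[-1L] <- f[-1L] + step_t * dir
      k0 <- kappa(f)
      it_used <- it
      if (step_t * max(abs(dir)) < tol / 10) break
    }
  }
  # verify / polish with the self-consistent map to the stated tolerance
  resid_prev <- Inf
  damp <- 1
  for (it in seq_len(max_iter)) {
    fnew <- sc_update(f)
    resid <- max(abs(fnew - f))
    if (resid < tol) {
      w <- exp(-logden_of(fnew))
      return(list(f = fnew, weights = w / sum(w), iter = it_used + it))
    }
    if (resid > resid_prev) damp <- max(damp * 0.5, 0.05) else
      damp <- min(1, damp * 1.2)
    f <- f + damp * (fnew - f)
    resid_prev <- resid
  }
  stop(sprintf("MBAR did not converge in %d iterations (residual %.3g)",
               max_iter, resid_prev))
}

.overlap_warn <- function(u, N_k) {
  K <- nrow(u)
  if (K < 2L) return(invisible())
  # crude pairwise overlap: fraction of window-k samples within the central
  # 99% reduced-energy range of window k+1
  starts <- cumsum(c(0L, N_k))
  worst <- 1
  for (k in seq_len(K - 1L)) {
    sk <- (starts[k] + 1L):(starts[k + 1L])
    du <- u[k + 1L, sk] - u[k, sk]
    ov <- mean(du < 4.6)                # within ~e^4.6 ~ 1% weight
    worst <- min(worst, ov)
  }
  if (worst < 0.01)
    warning("adjacent-window overlap below 1%; MBAR may be unreliable")
  invisible()
}

#' Reduced bias-energy matrix for harmonic umbrella windows
#'
#' u[k, n] = beta * 0.5 * k_k * (x_n - c_k)^2.
#'
#' @param x all CV samples (concatenated window blocks)
#' @param windows list of bias windows, each \code{list(center=, k=)}
#'   (kcal/(mol A^2) force constant, sum-form 0.5*k*(x-c)^2)
#' @param temperature K
#' @return K x N matrix
#' @export
umbrella_u_matrix <- function(x, windows, temperature = 300) {
  beta <- beta_kcal(temperature)
  t(vapply(windows, function(w)
    beta * 0.5 * w$k * (x - w$center)^2, numeric(length(x))))
}

#' Unbiased PMF from umbrella windows via MBAR
#'
#' @param x concatenated CV samples, window blocks in order
#' @param N_k samples per window
#' @param windows list of \code{list(center=, k=)} harmonic biases
#' @param edges bin edges
#' @param temperature K
#' @param n_min minimum bin occupancy
#' @return \code{pmf_grid}
#' @export
mbar_pmf <- function(x, N_k, windows, edges, temperature = 300, n_min = 20) {
  u <- umbrella_u_matrix(x, windows, temperature)
  sol <- mbar_solve(u, N_k)
  histogram_pmf(x, edges, temperature, weights = sol$weights, n_min = n_min)
}

#' Two-step reweighting: GaMD cumulants within windows, then MBAR
#'
#' Step 1 removes the boost within each umbrella window by the second-order
#' per-bin cumulant correction; step 2 combines the windows with MBAR
#' weights from the harmonic biases.  With zero boost this reduces to the
#' plain MBAR PMF; with a single zero-force-constant window and zero boost
#' it reduces to the histogram PMF.
#'
#' @param x concatenated CV samples, window blocks in order
#' @param boost per-sample boost energies DeltaV (kcal/mol, >= 0)
#' @param N_k samples per window
#' @param windows list of \code{list(center=, k=)}
#' @param edges bin edges
#' @param temperature K
#' @param n_min minimum occupancy for a reported bin
#' @return \code{pmf_grid}
#' @export
gareus_reweight <- function(x, boost, N_k, windows, edges,
                            temperature = 300, n_min = 20) {
  stopifnot(length(x) == length(boost), sum(N_k) == length(x))
  kT <- ff_constants$kB * temperature
  u <- umbrella_u_matrix(x, windows, temperature)
  sol <- mbar_solve(u, N_k)
  idx <- .bin_index(x, edges)
  nb <- length(edges) - 1L
  win_of <- rep(seq_along(N_k), N_k)
  b <- boost / kT
  # per-window per-bin cumulant factor applied to that window's MBAR mass
  mass <- numeric(nb)
  counts <- tabulate(idx[!is.na(idx)], nb)
  for (bin in seq_len(nb)) {
    sel <- which(!is.na(idx) & idx == bin)
    if (!length(sel)) next
    for (k in unique(win_of[sel])) {
      sk <- sel[win_of[sel] == k]
      c1 <- mean(b[sk])
      c2 <- if (length(sk) > 1L) var(b[sk]) else 0
      mass[bin] <- mass[bin] + sum(sol$weights[sk]) * exp(c1 + c2 / 2)
    }
  }
  width <- diff(edges)
  p <- mass / sum(mass) / width
  maskbin <- counts >= n_min & p > 0
  F <- -kT * log(p)
  .pmf_grid(edges, F, maskbin, counts)
}
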