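# Bennett acceptance ratio, FEP window schedules, solvation free-energy
# assembly, and block-average errors.

#' Work samples for a two-state free-energy estimate
#'
#' @param forward forward energy differences (U_B - U_A evaluated on
#'   state-A samples), kcal/mol
#' @param reverse reverse energy differences (U_A - U_B on state-B
#'   samples), kcal/mol
#' @param temperature K
#' @return object of class \code{work_samples}
#' @export
work_samples <- function(forward, reverse, temperature = 300) {
  if (!length(forward) || !length(reverse))
    stop("both forward and reverse samples are required for BAR")
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse),
                 temperature = temperature),
            class = "work_samples")
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Solves the Bennett self-consistency
#' sum_F fermi(beta (W_F - dF) + M) = sum_R fermi(beta (W_R + dF) - M),
#' with M = log(nF/nR), by a bracketed root solve (the bracket spans the
#' observed work range plus 50 kB T, which always contains the root).
#' The standard error is the asymptotic (maximum-likelihood) variance.
#'
#' @param w \code{work_samples}
#' @param tol absolute tolerance on dF, kcal/mol (default 1e-10)
#' @return object of class \code{bar_result}: \code{dF}, \code{se} in
#'   kcal/mol, plus sample counts
#' @export
bar <- function(w, tol = 1e-10) {
  stopifnot(inherits(w, "work_samples"))
  beta <- beta_kcal(w$temperature)
  WF <- w$forward; WR <- w$reverse
  nF <- length(WF); nR <- length(WR)
  M <- log(nF / nR)
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(dF)
    sum(fermi(beta * (WF - dF) + M)) - sum(fermi(beta * (WR + dF) - M))
  lo <- min(c(WF, -WR)) - 50 / beta
  hi <- max(c(WF, -WR)) + 50 / beta
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0)
    stop("no forward/reverse overlap: BAR has no solution in bracket; ",
         "add intermediate windows")
  dF <- uniroot(g, c(lo, hi), tol = tol)$root

  # asymptotic variance at the solution (Bennett 1976 / MLE form)
  xF <- beta * (WF - dF) + M
  xR <- beta * (WR + dF) - M
  fF <- fermi(xF); fR <- fermi(xR)
  denom <- sum(fF * (1 - fF)) + sum(fR * (1 - fR))
  if (denom <= 0) stop("vanishing overlap: BAR variance undefined")
  var_bdf <- 1 / denom - 1 / nF - 1 / nR
  se <- sqrt(max(var_bdf, 0)) / beta
  structure(list(dF = dF, se = se, n_forward = nF, n_reverse = nR,
                 temperature = w$temperature),
            class = "bar_result")
}

#' @export
print.bar_result <- function(x, ...) {
  cat(sprintf("BAR: dF = %.4f +/- %.4f kcal/mol (nF = %d, nR = %d, T = %g K)\n",
              x$dF, x$se, x$n_forward, x$n_reverse, x$temperature))
  invisible(x)
}

#' Exponential-averaging (Zwanzig) estimates, forward and reverse
#'
#' Diagnostic companions to BAR; the BAR estimate always lies between them.
#'
#' @param w \code{work_samples}
#' @return named vector c(forward=, reverse=) in kcal/mol
#' @export
exp_averaging <- function(w) {
  beta <- beta_kcal(w$temperature)
  lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  # forward: dF = -kT log <exp(-beta W_F)>_A
  # reverse: dF = +kT log <exp(-beta W_R)>_B  (sign flip of the B->A leg)
  c(forward = -lse(-beta * w$forward) / beta,
    reverse = lse(-beta * w$reverse) / beta)
}

#' Assemble a solvation free energy from annihilation legs
#'
#' dG_solv = dG_vacuum - dG_water, standard errors combined in quadrature.
#'
#' @param dG_vacuum,dG_water values in kcal/mol
#' @param se_vacuum,se_water standard errors
#' @return object of class \code{solvation_result}
#' @export
assemble_solvation <- function(dG_vacuum, dG_water,
                               se_vacuum = 0, se_water = 0) {
  structure(list(dG_vacuum = dG_vacuum, dG_water = dG_water,
                 dG_solv = dG_vacuum - dG_water,
                 se_vacuum = se_vacuum, se_water = se_water,
                 se_solv = sqrt(se_vacuum^2 + se_water^2)),
            class = "solvation_result")
}

#' @export
print.solvation_result <- function(x, ...) {
  cat(sprintf(
    "dG_solv = %.3f +/- %.3f kcal/mol (vacuum %.3f +/- %.3f, water %.3f +/- %.3f)\n",
    x$dG_solv, x$se_solv, x$dG_vacuum, x$se_vacuum, x$dG_water, x$se_water))
  invisible(x)
}

#' Block-average mean and standard error
#'
#' The series is cut into \code{n_blocks} contiguous equal blocks (any
#' remainder joins the last block); SE = sd(block means) / sqrt(n_blocks).
#'
#' @param series numeric vector, length >= n_blocks
#' @param n_blocks number of blocks (default 3)
#' @return list with \code{mean}, \code{se}, \code{block_means}
#' @export
block_error <- function(series, n_blocks = 3L) {
  if (n_blocks < 2L) stop("need at least 2 blocks")
  n <- length(series)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  size <- n %/% n_blocks
  bm <- vapply(seq_len(n_blocks), function(b) {
    from <- (b - 1L) * size + 1L
    to <- if (b == n_blocks) n else b * size
    mean(series[from:to])
  }, 0)
  list(mean = mean(series), se = sd(bm) / sqrt(n_blocks), block_means = bm)
}

#' The 24-window FEP coupling schedule for solute annihilation
#'
#' Electrostatics are switched off first (lambda_elec 1 -> 0 over the first
#' 11 windows) and only then the Lennard-Jones coupling is removed
#' (lambda_LJ 1 -> 0, with refinement near zero).
#'
#' @return data.frame with columns \code{lambda_elec}, \code{lambda_lj}
#'   (24 rows)
#' @export
fep_schedule_annihilation <- function() {
  data.frame(
    lambda_elec = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1,
                    rep(0, 14)),
    lambda_lj = c(rep(1, 11), 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2,
                  0.15, 0.1, 0.05, 0.025, 0))
}

#' Validate an FEP coupling schedule
#'
#' Checks: paired equal-length columns in [0, 1]; fully-coupled (1, 1) and
#' fully-decoupled (0, 0) endpoints present; both columns monotone
#' non-increasing; and electrostatics fully off before any LJ decoupling
#' begins.
#'
#' @param schedule data.frame with \code{lambda_elec} and \code{lambda_lj}
#' @return list with \code{valid} (logical), \code{n_windows}, and
#'   \code{problems} (character vector, itemized)
#' @export
validate_schedule <- function(schedule) {
  e <- schedule$lambda_elec; l <- schedule$lambda_lj
  problems <- character(0)
  if (is.null(e) || is.null(l) || length(e) != length(l))
    return(list(valid = FALSE, n_windows = NA_integer_,
                problems = "schedule must pair lambda_elec and lambda_lj"))
  if (any(e < 0 | e > 1 | l < 0 | l > 1))
    problems <- c(problems, "coupling parameters outside [0, 1]")
  if (!(e[1] == 1 && l[1] == 1))
    problems <- c(problems, "missing fully-coupled endpoint (1, 1)")
  if (!(e[length(e)] == 0 && l[length(l)] == 0))
    problems <- c(problems, "missing fully-decoupled endpoint (0, 0)")
  if (any(diff(e) > 0))
    problems <- c(problems, "lambda_elec not monotone non-increasing")
  if (any(diff(l) > 0))
    problems <- c(problems, "lambda_lj not monotone non-increasing")
  if (any(l < 1 & e > 0))
    problems <- c(problems,
                  "LJ decoupling begins while electrostatics still on")
  list(valid = length(problems) == 0L, n_windows = length(e),
       problems = problems)
}
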