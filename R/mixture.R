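#' von Mises log-density (mean zero)
#'
#' Density `exp(kappa * cos(x)) / (2 * pi * I0(kappa))`, evaluated stably
#' for large `kappa` via the exponentially scaled Bessel function.
#'
#' @param error_rad angular error(s) in radians.
#' @param kappa concentration, `>= 0`; `kappa = 0` is the circular uniform.
#' @return log-density values.
#' @examples
#' vm_logpdf(0, 0)  # log(1 / (2 * pi))
#' @export
vm_logpdf <- function(error_rad, kappa) {
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  # log I0(k) = log(besselI(k, 0, scaled)) + k, finite for k up to ~1e8
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  kappa * cos(error_rad) - log(2 * pi) - log_i0
}

#' Uniform + von Mises mixture log-density
#'
#' The two-component encoding model for colour-report error: a
#' target-centred von Mises with weight `rho` (probability of encoding) and
#' a circular-uniform guessing component with weight `1 - rho`.
#'
#' @inheritParams vm_logpdf
#' @param rho encoding probability in \[0, 1\].
#' @return log-density values, computed without underflow.
#' @export
mixture_logpdf <- function(error_rad, rho, kappa) {
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]", call. = FALSE)
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (rho == 0) return(rep(-log(2 * pi), length(error_rad)))
  if (rho == 1) return(vm_logpdf(error_rad, kappa))
  logaddexp(log(rho) + vm_logpdf(error_rad, kappa),
            log1p(-rho) - log(2 * pi))
}

# Mean resultant length of a von Mises: A1(k) = I1(k)/I0(k); inverted by
# root-finding on log(kappa).
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

vm_a1_inv <- function(r, upper = 1e4) {
  if (r <= 0) return(0)
  if (r >= vm_a1(upper)) return(upper)
  stats::uniroot(function(lk) vm_a1(exp(lk)) - r,
                 lower = log(1e-8), upper = log(upper), tol = 1e-12)$root |> exp()
}

#' Maximum-likelihood mixture fit for one cell (EM)
#'
#' Fits `rho` and `kappa` of the uniform + von Mises mixture to a vector of
#' angular errors by expectation-maximisation: responsibilities of the von
#' Mises component in the E-step; in the M-step `rho` is the mean
#' responsibility and `kappa` solves the mean-resultant-length equation
#' `I1(k)/I0(k) = R` for the responsibility-weighted resultant `R`.
#'
#' @param errors_rad angular errors in radians (at least 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param starts matrix-like list of `c(rho, kappa)` starting points; the
#'   run with the best final log-likelihood wins.  Multiple starts guard
#'   against the ridge at small kappa, where the mixture weight is poorly
#'   identified.
#' @return list with `rho`, `kappa`, `loglik`, `n_iter`, `converged`.
#' @examples
#' set.seed(2)
#' e <- ifelse(runif(500) < 0.8, rvonmises(500, 8), runif(500, -pi, pi))
#' fit_mle_cell(e)
#' @export
fit_mle_cell <- function(errors_rad, max_iter = 5000L, tol = 1e-10,
                         starts = list(c(0.9, 5), c(0.5, 1), c(0.1, 8))) {
  fits <- lapply(starts, function(s) {
    em_mixture(errors_rad, rho = s[1], kappa = s[2], max_iter = max_iter,
               tol = tol)
  })
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

em_mixture <- function(errors_rad, rho, kappa, max_iter, tol) {
  n <- length(errors_rad)
  if (n < 10) stop("need at least 10 errors to fit a cell", call. = FALSE)
  ce <- cos(errors_rad)
  lu <- -log(2 * pi)                      # uniform log-density
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lvm <- vm_logpdf(errors_rad, kappa)
    l1 <- log(rho) + lvm
    l0 <- log1p(-rho) + lu
    lmix <- logaddexp(l1, l0)
    ll <- sum(lmix)
    resp <- exp(l1 - lmix)
    # M-step
    rho <- mean(resp)
    rho <- min(max(rho, 1e-12), 1 - 1e-12)
    r_bar <- sum(resp * ce) / sum(resp)
    kappa <- vm_a1_inv(min(max(r_bar, 0), 1 - 1e-12))
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  loglik <- sum(mixture_logpdf(errors_rad, rho, kappa))
  list(rho = rho, kappa = kappa, loglik = loglik, n_iter = iter,
       converged = converged)
}

#' Mixture fit by dense grid search with local refinement
#'
#' Independent check on [fit_mle_cell()]: evaluates the mixture
#' log-likelihood on a dense (logit rho) x (log kappa) grid, then polishes
#' the best grid point with Nelder-Mead.
#'
#' @inheritParams fit_mle_cell
#' @param n_grid grid points per axis.
#' @return list with `rho`, `kappa`, `loglik`.
#' @export
fit_mle_grid <- function(errors_rad, n_grid = 41L) {
  n <- length(errors_rad)
  if (n < 10) stop("need at least 10 errors to fit a cell", call. = FALSE)
  lrho <- seq(stats::qlogis(0.01), stats::qlogis(0.999), length.out = n_grid)
  lkap <- seq(log(0.1), log(100), length.out = n_grid)
  ll <- function(par) {
    sum(mixture_logpdf(errors_rad, stats::plogis(par[1]), exp(par[2])))
  }
  grid <- as.matrix(expand.grid(lrho = lrho, lkap = lkap))
  vals <- apply(grid, 1L, ll)
  best <- grid[which.max(vals), ]
  opt <- stats::optim(best, ll, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12))
  list(rho = stats::plogis(opt$par[[1]]), kappa = exp(opt$par[[2]]),
       loglik = opt$value)
}
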