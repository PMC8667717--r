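#' Parameters of the fossilized birth-death model
#'
#' Bundles the four parameters of the FBD process: speciation rate
#' \code{lambda}, extinction rate \code{mu} and fossil recovery rate
#' \code{psi}, all in events per lineage per million years (My), and the
#' probability \code{rho} that a lineage alive at the present is sampled.
#'
#' @param lambda speciation rate (> 0 for probability computations; 0 is
#'   tolerated for pure-death simulation).
#' @param mu extinction rate (>= 0).
#' @param psi fossil recovery rate (>= 0).
#' @param rho extant-sampling probability in [0, 1].
#' @return An object of class \code{"fbd_rates"}.
#' @examples
#' fbd_rates(lambda = 0.2, mu = 0.19, psi = 0.1)
#' @export
fbd_rates <- function(lambda, mu, psi = 0, rho = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(psi), length(psi) == 1L, is.finite(psi))
  if (lambda < 0) stop("speciation rate 'lambda' must be non-negative")
  if (mu < 0) stop("extinction rate 'mu' must be non-negative")
  if (psi < 0) stop("fossil recovery rate 'psi' must be non-negative")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("extant-sampling probability 'rho' must be in [0, 1]")
  structure(list(lambda = lambda, mu = mu, psi = psi, rho = rho),
            class = "fbd_rates")
}

#' @export
print.fbd_rates <- function(x, ...) {
  cat("FBD rates: lambda =", x$lambda, ", mu =", x$mu,
      ", psi =", x$psi, ", rho =", x$rho, "\n")
  invisible(x)
}

as_fbd_rates <- function(x) {
  if (inherits(x, "fbd_rates")) return(x)
  if (is.numeric(x) && length(x) %in% c(3L, 4L)) {
    if (is.null(names(x))) names(x) <- c("lambda", "mu", "psi", "rho")[seq_along(x)]
    return(fbd_rates(x[["lambda"]], x[["mu"]], x[["psi"]],
                     if ("rho" %in% names(x)) x[["rho"]] else 1))
  }
  stop("cannot interpret 'rates' as FBD rates")
}

#' Roots of the FBD characteristic polynomial
#'
#' The single-lineage FBD probabilities are driven by the two real roots
#' \code{alpha < beta} of \eqn{-\lambda x^2 + (\lambda+\mu+\psi) x - \mu = 0}
#' and the decay constant \eqn{\omega = -\lambda(\beta - \alpha)} (per My).
#'
#' @param rates an \code{\link{fbd_rates}} object (requires \code{lambda > 0}).
#' @return A list with components \code{alpha}, \code{beta}, \code{omega},
#'   of class \code{"fbd_roots"}.
#' @examples
#' fbd_roots(fbd_rates(0.2, 0.19, 0))  # alpha = mu/lambda, beta = 1
#' @export
fbd_roots <- function(rates) {
  rates <- as_fbd_rates(rates)
  if (rates$lambda <= 0)
    stop("FBD roots require a positive speciation rate 'lambda'")
  s <- rates$lambda + rates$mu + rates$psi
  disc <- s^2 - 4 * rates$lambda * rates$mu
  # discriminant = (lambda - mu)^2 + psi^2 + 2 psi (lambda + mu) >= 0 always
  sq <- sqrt(max(disc, 0))
  beta <- (s + sq) / (2 * rates$lambda)
  # smaller root via the product alpha*beta = mu/lambda (avoids cancellation)
  alpha <- if (beta > 0) rates$mu / (rates$lambda * beta) else (s - sq) / (2 * rates$lambda)
  structure(list(alpha = alpha, beta = beta,
                 omega = -rates$lambda * (beta - alpha)),
            class = "fbd_roots")
}

# Precomputed quantities shared by all single-lineage FBD evaluations.
#
# Writes Phi(t) = b - a e^{omega t} with a = alpha - (1-rho),
# b = beta - (1-rho).  When beta - alpha underflows (lambda = mu, psi = 0)
# all formulas are 0/0; we then switch to the analytic omega -> 0 limit in
# which every factor (beta - alpha) is dropped and Phi(t) is replaced by its
# scaled limit 1 + a*lambda*t (the epsilon powers cancel exactly in every
# assembled quantity).
fbd_env <- function(rates) {
  rates <- as_fbd_rates(rates)
  r <- fbd_roots(rates)
  eps <- r$beta - r$alpha
  degen <- eps < 1e-9
  a <- r$alpha - (1 - rates$rho)
  b <- r$beta - (1 - rates$rho)
  list(rates = rates, alpha = r$alpha, beta = r$beta, omega = r$omega,
       a = a, b = b, eps = eps, degen = degen,
       logbma = if (degen) 0 else log(eps))
}

# log Phi(t); in the degenerate branch, log of the scaled limit 1 + a*lambda*t.
fbd_logphi <- function(t, env) {
  if (env$degen) return(log1p(env$a * env$rates$lambda * t))
  E <- expm1(env$omega * t)                     # in (-1, 0]
  if (env$a >= 0) {
    log(env$eps - env$a * E)                    # sum of non-negatives
  } else {
    log(env$b + (-env$a) * exp(env$omega * t))  # sum of non-negatives
  }
}

# log of the single-observable-line propagator U(u, v), u <= v, relative to
# present time tpres: probability density factor for a lineage at forward
# time u to reach v as one observable line (no fossil, no extinction, every
# side branch unobservable through tpres).
fbd_logU <- function(u, v, tpres, env) {
  env$omega * (v - u) + 2 * (fbd_logphi(tpres - v, env) - fbd_logphi(tpres - u, env))
}
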