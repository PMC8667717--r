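#' Single-lineage FBD probabilities P(n, t)
#'
#' Probability that a single lineage alive at time 0 has exactly \code{n}
#' descendants sampled (each with probability \code{rho}) at time \code{t},
#' without leaving any fossil dated in (0, t).  With \code{rho = 1},
#' \code{fbd_p(0, t, rates)} is the probability that the lineage and all its
#' descendants are extinct before \code{t} with no fossil record.
#'
#' Writing \code{alpha < beta} for the roots of the FBD characteristic
#' polynomial and \code{omega = -lambda (beta - alpha)}:
#' \deqn{P(0,t) = \frac{\alpha(\beta-(1-\rho)) - \beta(\alpha-(1-\rho))e^{\omega t}}
#'                    {\beta-(1-\rho) - (\alpha-(1-\rho))e^{\omega t}}}
#' \deqn{P(n,t) = \frac{\rho^n (\beta-\alpha)^2 e^{\omega t}(1-e^{\omega t})^{n-1}}
#'                    {(\beta-(1-\rho) - (\alpha-(1-\rho))e^{\omega t})^{n+1}}, n > 0.}
#' Both are evaluated in a numerically stable form (via \code{expm1} and
#' log-space products) that remains valid for \code{omega * t} of order
#' -2000 and at the degenerate boundary \code{lambda = mu, psi = 0}, where
#' the analytic \code{omega -> 0} limit is used.
#'
#' @param n non-negative integer count of sampled descendants (scalar).
#' @param t elapsed duration in My (vectorized, >= 0).
#' @param rates an \code{\link{fbd_rates}} object.
#' @param log if \code{TRUE}, return log-probabilities.
#' @return Numeric vector of (log-)probabilities, same length as \code{t}.
#' @examples
#' r <- fbd_rates(0.2, 0.19, 0.1)
#' fbd_p(0, c(1, 10, 100), r)
#' @export
fbd_p <- function(n, t, rates, log = FALSE) {
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  if (any(t < 0)) stop("durations 't' must be non-negative")
  env <- fbd_env(rates)
  lp <- if (n == 0) fbd_logp0(t, env) else fbd_logpn(n, t, env)
  if (log) lp else exp(lp)
}

fbd_logp0 <- function(t, env) {
  rho <- env$rates$rho
  if (env$degen) {
    # limit: ((1-rho) + a*beta*lambda*t) / (1 + a*lambda*t), alpha = beta
    lam <- env$rates$lambda
    return(log((1 - rho) + env$a * env$beta * lam * t) -
             log1p(env$a * lam * t))
  }
  E <- expm1(env$omega * t)
  # numerator (1-rho)(beta-alpha) - beta*a*E: both terms non-negative
  # whatever the sign of a (E <= 0)
  num <- (1 - rho) * env$eps - env$beta * env$a * E
  log(num) - fbd_logphi_raw(E, t, env)
}

fbd_logpn <- function(n, t, env) {
  rho <- env$rates$rho
  if (rho == 0) return(rep(-Inf, length(t)))
  lam <- env$rates$lambda
  if (env$degen) {
    # limit: rho^n (lambda t)^{n-1} / (1 + a lambda t)^{n+1}
    pow <- if (n == 1) 0 else (n - 1) * log(lam * t)
    return(n * log(rho) + pow - (n + 1) * log1p(env$a * lam * t))
  }
  E <- expm1(env$omega * t)
  pow <- if (n == 1) 0 else (n - 1) * log(-E)
  n * log(rho) + 2 * env$logbma + env$omega * t +
    pow - (n + 1) * fbd_logphi_raw(E, t, env)
}

# log Phi given the already-computed E = expm1(omega t) (non-degenerate case)
fbd_logphi_raw <- function(E, t, env) {
  if (env$a >= 0) log(env$eps - env$a * E)
  else log(env$b + (-env$a) * exp(env$omega * t))
}

#' Density of the extinction time of an unobserved lineage
#'
#' The probability density D(t) for a lineage alive at time 0 to go extinct
#' (with all its descendants) exactly at time \code{t} without leaving any
#' fossil; the derivative of \code{fbd_p(0, t, rates)} with respect to t:
#' \deqn{D(t) = \frac{\lambda(\alpha-(1-\rho))(\beta-(1-\rho))
#'   (\beta-\alpha)^2 e^{\omega t}}
#'   {(\beta-(1-\rho)-(\alpha-(1-\rho))e^{\omega t})^2}.}
#'
#' Note that with \code{rho < 1}, \code{fbd_p(0, t, .)} mixes extinction
#' with survival-without-sampling and need not increase with \code{t}; the
#' displayed derivative is then negative, and the extinction reading of
#' these quantities is exact at \code{rho = 1} (the regime used by the
#' extinction-time machinery).
#'
#' @inheritParams fbd_p
#' @return Numeric vector of (log-)densities per My.
#' @export
fbd_extinction_density <- function(t, rates, log = FALSE) {
  if (any(t < 0)) stop("durations 't' must be non-negative")
  env <- fbd_env(rates)
  ab <- env$a * env$b
  if (ab >= 0) {
    ld <- fbd_logD(t, env)
    return(if (log) ld else exp(ld))
  }
  # rho < 1 can make the derivative of P(0, .) negative
  env2 <- env; env2$a <- abs(env$a)
  v <- -exp(fbd_logD(t, env2) + 2 * (fbd_logphi(t, env2) - fbd_logphi(t, env)))
  if (log) rep(NaN, length(t)) else v
}

fbd_logD <- function(t, env) {
  lam <- env$rates$lambda
  ab <- env$a * env$b
  if (ab == 0) return(rep(-Inf, length(t)))
  if (env$degen) return(log(lam * ab) - 2 * log1p(env$a * lam * t))
  log(lam * ab) + 2 * env$logbma + env$omega * t - 2 * fbd_logphi(t, env)
}
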