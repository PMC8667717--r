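# Tree probability density under the FBD model, via the basic-tree
# factorization.  Each piece contributes:
#   - pendant (hidden) piece from the last fossil l of an extinct tip:
#       P(0, T - l)            [or P(0, t - l) under an extinction-by-t
#                               constraint on that tip]
#   - chain from start u to a fossil at g:  U(u, g) * psi
#   - chain from start u to a sampled extant tip:  P(1, T - u)
#   - branching piece: recursive integration over the unknown split times,
#     with a factor 2*lambda per observable node and the single-line
#     propagator U between events; hidden side branches are integrated
#     analytically inside U.
#
# The branching integrals are computed on a per-piece grid, in log space
# (cumulative trapezoid of exponentials with running-maximum scaling), so
# that log-densities remain finite for |omega * t| of order 2000.

logaddexp2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(pmin(x, y) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log of the suffix sums of exp(li), vectorized and stable: suffix sums
# are computed under the global maximum; any suffix that underflows
# entirely (possible when li spans thousands of log units) is a contiguous
# tail and is rescaled recursively.
log_rev_cumsum_exp <- function(li) {
  m <- max(li)
  if (!is.finite(m)) return(rep(-Inf, length(li)))
  v <- rev(cumsum(rev(exp(li - m))))
  out <- m + log(v)
  bad <- which(v == 0)           # zeros form a suffix (v is nonincreasing)
  if (length(bad)) out[bad[1L]:length(li)] <- Recall(li[bad[1L]:length(li)])
  out
}

# log of the reverse cumulative trapezoid integral of exp(lf) on grid x:
# out[i] = log( integral_{x[i]}^{x[n]} exp(lf) )
log_cum_trapz_rev <- function(lf, x) {
  n <- length(x)
  li <- logaddexp2(lf[-n], lf[-1L]) + log(diff(x) / 2)
  # support boundaries (s <= fossil age) coincide with grid points; a cell
  # with a -Inf endpoint lies outside the support and contributes nothing
  li[!is.finite(lf[-n]) | !is.finite(lf[-1L])] <- -Inf
  c(log_rev_cumsum_exp(li), -Inf)
}

# scaled subtree factor G on a grid of candidate times s:
# g(subtree, s) = exp(omega (T - s)) / Phi(T - s)^2 * G(s)
piece_logG <- function(struct, s, env, tpres, lphi_s, lome_s) {
  if (struct$kind == "fossil") {
    out <- rep(-Inf, length(s))
    ok <- s <= struct$time
    out[ok] <- log(env$rates$psi) + 2 * fbd_logphi(tpres - struct$time, env) -
      env$omega * (tpres - struct$time)
    return(out)
  }
  if (struct$kind == "extant") {
    if (env$rates$rho == 0) return(rep(-Inf, length(s)))
    return(rep(log(env$rates$rho) + 2 * env$logbma, length(s)))
  }
  if (struct$kind != "node") stop("unexpected leaf inside a branching piece")
  la <- piece_logG(struct$children[[1L]], s, env, tpres, lphi_s, lome_s)
  lb <- piece_logG(struct$children[[2L]], s, env, tpres, lphi_s, lome_s)
  integrand <- log(2 * env$rates$lambda) + lome_s - 2 * lphi_s + la + lb
  log_cum_trapz_rev(integrand, s)
}

# log-density of one branching piece, by grid integration
piece_logdensity_tree <- function(piece, env, tpres, n_grid) {
  leaf_times <- function(st) {
    if (st$kind == "fossil") return(st$time)
    if (st$kind == "extant") return(tpres)
    c(leaf_times(st$children[[1L]]), leaf_times(st$children[[2L]]))
  }
  M <- max(leaf_times(piece$struct))
  s <- sort(unique(c(seq(piece$start, M, length.out = n_grid),
                     leaf_times(piece$struct))))
  s <- s[s <= M]
  lphi_s <- fbd_logphi(tpres - s, env)
  lome_s <- env$omega * (tpres - s)
  lg <- piece_logG(piece$struct, s, env, tpres, lphi_s, lome_s)
  env$omega * (tpres - piece$start) - 2 * fbd_logphi(tpres - piece$start, env) +
    lg[1L]
}

#' Log probability density of an observable tree with dated fossils
#'
#' Computes the joint log-density of the tree topology and the realized
#' fossil ages under the FBD model, as the product of the densities of the
#' basic trees obtained by cutting at every fossil find.  With \code{S} and
#' \code{t} supplied, computes instead the joint log-density of the data
#' and of the event that every taxon in \code{S} is extinct before forward
#' time \code{t}: the pendant factor of each tip in \code{S} becomes
#' \code{P(0, t - l_n)} in place of \code{P(0, T - l_n)} (and the density
#' is \code{-Inf} when \code{t} precedes some last fossil of \code{S}).
#' At \code{t = T} the two computations coincide exactly and share the same
#' code path, hence the same cost.
#'
#' Densities are reported up to the constant labelling factor common to all
#' trees on the same taxon set, which cancels in every ratio the package
#' uses.
#'
#' @param tree an \code{"fbd_tree"}.
#' @param f named vector of realized forward fossil ages.
#' @param rates an \code{\link{fbd_rates}} object; \code{rho} must be 1
#'   when the tree has extant tips that are unsampled (not applicable here).
#' @param S optional character vector of extinct tip labels constrained to
#'   be extinct before \code{t}.
#' @param t forward time bound used with \code{S}.
#' @param n_grid grid size per branching piece for the split-time
#'   integrals (default 1001).
#' @param decomposition optionally, a precomputed
#'   \code{\link{fbd_decompose}} object for \code{(tree, f)}.
#' @return Log-density (scalar).  \code{-Inf} for zero-density
#'   configurations (e.g. \code{psi = 0} with fossils present), with the
#'   reason in attribute \code{"why"}.
#' @export
fbd_tree_logdensity <- function(tree, f, rates, S = NULL, t = NULL,
                                n_grid = 1001L, decomposition = NULL) {
  rates <- as_fbd_rates(rates)
  if (!is.null(S)) {
    if (is.null(t)) stop("'t' must be supplied with 'S'")
    bad <- S[tree$tip_fate[S] != "extinct"]
    if (length(bad) || anyNA(tree$tip_fate[S]))
      stop("subset 'S' must contain only extinct tips of the tree; offending: ",
           paste(S[is.na(tree$tip_fate[S]) | tree$tip_fate[S] != "extinct"],
                 collapse = ", "))
    if (t > tree$T) stop("'t' must not exceed the present time T")
  }
  if (rates$psi == 0 && nrow(tree$fossils) > 0)
    return(structure(-Inf, why = "fossils present but psi = 0"))
  if (rates$lambda <= 0)
    stop("tree density requires a positive speciation rate")
  dec <- if (is.null(decomposition)) fbd_decompose(tree, f) else decomposition
  env <- fbd_env(rates)
  tpres <- tree$T

  kinds <- vapply(dec, function(p) p$struct$kind, character(1))
  starts <- vapply(dec, function(p) p$start, numeric(1))
  ld <- 0

  # pendant pieces: P(0, T - l) or the constrained P(0, t - l)
  hid <- which(kinds == "hidden")
  if (length(hid)) {
    tips <- vapply(dec[hid], function(p) p$struct$tip, character(1))
    hor <- rep(tpres, length(hid))
    if (!is.null(S)) {
      inS <- tips %in% S
      hor[inS] <- t
      if (any(hor < starts[hid]))
        return(structure(-Inf,
                         why = "t precedes the most recent fossil of a taxon in S"))
    }
    ld <- ld + sum(fbd_logp0(hor - starts[hid], env))
  }

  # chain pieces to a fossil: U(start, g) * psi
  ch <- which(kinds == "fossil")
  if (length(ch)) {
    ends <- vapply(dec[ch], function(p) p$struct$time, numeric(1))
    ld <- ld + sum(fbd_logU(starts[ch], ends, tpres, env) +
                     log(rates$psi))
  }

  # chain pieces to a sampled extant tip: P(1, T - start)
  ex <- which(kinds == "extant")
  if (length(ex)) {
    if (rates$rho == 0)
      return(structure(-Inf, why = "extant tips present but rho = 0"))
    ld <- ld + sum(fbd_logpn(1L, tpres - starts[ex], env))
  }

  # branching pieces: grid integration
  for (i in which(kinds == "node"))
    ld <- ld + piece_logdensity_tree(dec[[i]], env, tpres, n_grid)

  ld
}
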