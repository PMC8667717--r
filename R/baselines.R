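#' Fossil record of one terminal branch
#'
#' The "branch by branch" estimators use only the fossils of the taxon
#' under study: the ordered realized ages on its terminal branch.
#'
#' @param tree an \code{"fbd_tree"}.
#' @param f named vector of realized forward fossil ages.
#' @param tip an extinct tip label.
#' @return A list of class \code{"fbd_branch_record"}: \code{$times}
#'   (sorted forward ages), \code{$n}, \code{$range} (oldest-to-youngest
#'   span, My), \code{$youngest} (most recent, forward time), \code{$T}.
#' @export
fbd_branch_record <- function(tree, f, tip) {
  tipnum <- match(tip, if (is.null(tree$tree)) names(tree$tip_fate)
                  else tree$tree$tip.label)
  if (is.na(tipnum)) stop("unknown tip '", tip, "'")
  idx <- tree$fossils$edge_node == tipnum
  times <- sort(unname(f[tree$fossils$occ[idx]]))
  structure(list(times = times, n = length(times),
                 range = if (length(times)) max(times) - min(times) else 0,
                 youngest = if (length(times)) max(times) else NA_real_,
                 T = tree$T),
            class = "fbd_branch_record")
}

#' Classical range-extension confidence upper bound
#'
#' Assuming fossil ages uniformly distributed over the taxon lifetime, the
#' upper bound of the stratigraphic range at confidence \code{order} is
#' \deqn{youngest + R\,[(1-q)^{-1/(n-1)} - 1],}
#' with \eqn{R} the observed range and \eqn{n \ge 2} the number of fossils.
#'
#' @param rec an \code{\link{fbd_branch_record}}.
#' @param order confidence order in (0, 1).
#' @return Forward time of the bound; \code{NA} when fewer than two
#'   fossils make the method inapplicable.
#' @export
fbd_ss_bound <- function(rec, order = 0.95) {
  if (rec$n < 2) return(NA_real_)
  rec$youngest + rec$range * ((1 - order)^(-1 / (rec$n - 1)) - 1)
}

#' Continuous sighting-rate confidence upper bound (branch-local)
#'
#' Continuous analogue of discrete sighting-record methods: the local
#' fossil recovery rate is estimated from the \eqn{n - 1} gaps of the
#' branch record, \eqn{\hat\psi = (n-1)/R}, and the extension beyond the
#' youngest fossil is the \code{order}-quantile of an exponential waiting
#' time, \eqn{-\ln(1-q)/\hat\psi}.
#'
#' @inheritParams fbd_ss_bound
#' @return Forward time of the bound; \code{NA} when \code{n < 2} or all
#'   fossils share one age (rate not estimable).
#' @export
fbd_mci_bound <- function(rec, order = 0.95) {
  if (rec$n < 2 || rec$range <= 0) return(NA_real_)
  rec$youngest + (-log(1 - order)) * rec$range / (rec$n - 1)
}

#' Global sighting-rate confidence upper bounds
#'
#' Global version of \code{\link{fbd_mci_bound}}: one fossil recovery rate
#' is pooled over all branches of the tree carrying at least two fossils,
#' \eqn{\hat\psi = \sum_b (n_b - 1) / \sum_b R_b}, and applied to every
#' extinct taxon -- including taxa with a single fossil, for which the
#' branch-local methods are undefined.  The method requires at least one
#' branch (terminal or internal) bearing two or more fossils, so it
#' applies whenever any branch-local method does.
#'
#' @param tree an \code{"fbd_tree"}.
#' @param f named vector of realized forward fossil ages.
#' @param order confidence order in (0, 1).
#' @return Named vector of bounds (forward time), one per extinct tip, all
#'   \code{NA} when no branch bears more than two fossils.
#' @export
fbd_glo_bound <- function(tree, f, order = 0.95) {
  ext <- names(tree$tip_fate)[tree$tip_fate == "extinct"]
  out <- rep(NA_real_, length(ext)); names(out) <- ext
  # pool the recovery rate over every branch of the tree (internal
  # branches and the stem included), not only the terminal ones
  ages <- split(unname(f[tree$fossils$occ]), tree$fossils$edge_node)
  ns <- lengths(ages)
  if (!any(ns >= 2)) return(out)  # no branch with two or more fossils
  use <- ns >= 2
  Rs <- vapply(ages[use], function(x) max(x) - min(x), numeric(1))
  psihat <- sum(ns[use] - 1) / sum(Rs)
  ext_mult <- -log(1 - order) / psihat
  for (tp in ext)
    out[tp] <- fbd_branch_record(tree, f, tp)$youngest + ext_mult
  out
}

#' Discrete-time Bayesian confidence upper bound
#'
#' Bayesian iterative estimate over discretized extinction ages: time is
#' cut into bins of width \code{bin_width} My anchored at the oldest
#' fossil; within the observed range, \code{n_p} bins contain a find and
#' \code{n_a} do not, giving a per-bin sighting probability
#' \eqn{p_s = (n_p - 1) / (n_p - 1 + n_a)} -- a choice that makes the
#' method applicable to any branch with at least two fossiliferous
#' horizons.  The posterior over the extinction bin \eqn{e} at or after
#' the last-occurrence bin \eqn{j} is geometric,
#' \eqn{\Pr(e) \propto (1 - p_s)^{e - j}}, truncated at the present and
#' normalized; the bound is the \code{order}-quantile of this posterior
#' (upper edge of the quantile bin, capped at the present).
#'
#' @inheritParams fbd_ss_bound
#' @param bin_width width of the discretization bins in My (default 1).
#' @return Forward time of the bound; \code{NA} with fewer than two
#'   distinct fossiliferous horizons.
#' @export
fbd_alroy_bound <- function(rec, order = 0.95, bin_width = 1) {
  if (rec$n < 2) return(NA_real_)
  w <- bin_width
  bins <- floor((rec$times - rec$times[1]) / w)
  np <- length(unique(bins))
  if (np < 2) return(NA_real_)
  j <- bins[length(bins)]                 # bin of the last occurrence
  na <- (j - bins[1] + 1) - np            # empty bins inside the range
  ps <- (np - 1) / (np - 1 + na)
  M <- floor((rec$T - rec$times[1]) / w)  # bin containing the present
  e <- j:M
  post <- (1 - ps)^(e - j)
  post <- post / sum(post)
  k <- e[which(cumsum(post) >= order)[1]]
  min(rec$times[1] + (k + 1) * w, rec$T)
}
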