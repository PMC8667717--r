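#' Forward simulation of the fossilized birth-death process
#'
#' Simulates a complete diversification history from a single founder
#' lineage at time 0 until \code{horizon} My, with exponential waiting times
#' for speciation (\code{lambda}), extinction (\code{mu}) and fossilization
#' (\code{psi}).  Speciation replaces a lineage by two daughters; a lineage
#' that reaches the horizon is recorded as surviving to the present.
#'
#' @param rates an \code{\link{fbd_rates}} object.
#' @param horizon process duration in My (default 200).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class \code{"fbd_history"}: a list with
#'   \code{$lineages} (data frame: \code{id}, \code{parent} (0 = founder),
#'   \code{birth}, \code{death}, \code{fate} one of \code{"extinct"},
#'   \code{"speciation"}, \code{"present"}) and \code{$fossils} (data frame:
#'   \code{lineage}, \code{time}), plus \code{$horizon}.
#' @examples
#' h <- fbd_simulate(fbd_rates(0.2, 0.19, 0.1), horizon = 50, seed = 1)
#' nrow(h$lineages)
#' @export
fbd_simulate <- function(rates, horizon = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- fbd_simulate_batch(1L, rates, horizon)
  fbd_history_from_batch(b, 1L)
}

#' Batch forward FBD simulation
#'
#' Vectorized simulation of many independent FBD histories at once; the
#' workhorse behind \code{\link{fbd_simulate}} and the benchmark harness.
#' Fossil counts are always drawn; fossil times are drawn only if
#' \code{fossil_times = TRUE} (for accepted simulations they can be filled
#' in later, uniformly within each lineage lifespan, which is the exact
#' conditional law of a Poisson process given its count).
#'
#' @param n_sim number of independent histories.
#' @param rates an \code{\link{fbd_rates}} object.
#' @param horizon process duration in My.
#' @param fossil_times draw individual fossil times (default TRUE).
#' @return A list of parallel vectors describing all lineages of all
#'   histories: \code{sim}, \code{id} (row index, parents precede children),
#'   \code{parent} (0 for founders), \code{birth}, \code{death},
#'   \code{fate} (0 extinct, 1 speciation, 2 present), \code{nfos}
#'   (fossil count), and if requested \code{fossil_lineage},
#'   \code{fossil_time}.
#' @export
fbd_simulate_batch <- function(n_sim, rates, horizon = 200,
                               fossil_times = TRUE) {
  rates <- as_fbd_rates(rates)
  lam <- rates$lambda; mu <- rates$mu; tot <- lam + mu
  sim <- list(); par <- list(); bir <- list(); dea <- list(); fat <- list()
  cur_sim <- seq_len(n_sim)
  cur_par <- rep(0L, n_sim)
  cur_bir <- rep(0, n_sim)
  n_done <- 0L
  repeat {
    k <- length(cur_sim)
    if (k == 0L) break
    life <- if (tot > 0) stats::rexp(k, tot) else rep(Inf, k)
    death <- cur_bir + life
    reach <- death >= horizon
    death[reach] <- horizon
    spec <- !reach & (stats::runif(k) < lam / max(tot, .Machine$double.xmin))
    fate <- integer(k); fate[spec] <- 1L; fate[reach] <- 2L
    id <- n_done + seq_len(k)
    sim[[length(sim) + 1L]] <- cur_sim
    par[[length(par) + 1L]] <- cur_par
    bir[[length(bir) + 1L]] <- cur_bir
    dea[[length(dea) + 1L]] <- death
    fat[[length(fat) + 1L]] <- fate
    n_done <- n_done + k
    w <- which(spec)
    cur_sim <- rep(cur_sim[w], each = 2L)
    cur_par <- rep(id[w], each = 2L)
    cur_bir <- rep(death[w], each = 2L)
  }
  out <- list(sim = unlist(sim), parent = unlist(par), birth = unlist(bir),
              death = unlist(dea), fate = unlist(fat))
  out$id <- seq_along(out$sim)
  out$nfos <- stats::rpois(n_done, rates$psi * (out$death - out$birth))
  if (fossil_times && sum(out$nfos) > 0) {
    lin <- rep.int(out$id, out$nfos)
    out$fossil_lineage <- lin
    out$fossil_time <- out$birth[lin] +
      stats::runif(length(lin)) * (out$death[lin] - out$birth[lin])
  } else {
    out$fossil_lineage <- integer(0)
    out$fossil_time <- numeric(0)
  }
  out$horizon <- horizon
  out$n_sim <- n_sim
  out
}

fbd_history_from_batch <- function(b, s) {
  keep <- which(b$sim == s)
  ids <- b$id[keep]
  par <- match(b$parent[keep], ids)
  par[is.na(par)] <- 0L
  fk <- which(!is.na(match(b$fossil_lineage, ids)))
  structure(list(
    lineages = data.frame(
      id = seq_along(ids),
      parent = par,
      birth = b$birth[keep], death = b$death[keep],
      fate = c("extinct", "speciation", "present")[b$fate[keep] + 1L]),
    fossils = data.frame(lineage = match(b$fossil_lineage[fk], ids),
                         time = b$fossil_time[fk]),
    horizon = b$horizon), class = "fbd_history")
}

#' @export
print.fbd_history <- function(x, ...) {
  cat("FBD history:", nrow(x$lineages), "lineages,",
      nrow(x$fossils), "fossils,",
      sum(x$lineages$fate == "present"), "alive at the present (horizon",
      x$horizon, "My)\n")
  invisible(x)
}

# Observability flags for a batch: a lineage is observable iff its subtree
# contains a fossil or a sampled extant lineage.  Vectorized bottom-up
# propagation (children always have larger row index than parents).
batch_observable_flags <- function(b, rho = 1) {
  n <- length(b$sim)
  obs <- b$nfos > 0
  sampled <- b$fate == 2L
  if (rho < 1) sampled <- sampled & (stats::runif(n) < rho)
  obs <- obs | sampled
  # propagate upward in blocks: repeatedly mark parents of observable rows
  active <- which(obs & b$parent > 0L)
  while (length(active)) {
    p <- unique(b$parent[active])
    newly <- p[!obs[p]]
    if (!length(newly)) break
    obs[newly] <- TRUE
    active <- newly[b$parent[newly] > 0L]
  }
  list(obs = obs, sampled = sampled)
}

# Per-simulation observable-tree summary for a batch:
# number of observable-tree nodes (internal + tips), total fossils,
# number of extinct observable tips.
batch_observable_stats <- function(b, rho = 1) {
  fl <- batch_observable_flags(b, rho)
  obs <- fl$obs
  n <- length(b$sim)
  nobschild <- tabulate(b$parent[obs & b$parent > 0L], nbins = n)
  is_int <- obs & b$fate == 1L & nobschild == 2L
  is_tip <- obs & nobschild == 0L
  tip_extinct <- is_tip & !fl$sampled
  nodes <- tabulate(b$sim[is_int | is_tip], nbins = b$n_sim)
  fossils <- integer(b$n_sim)
  fs <- rowsum(b$nfos, b$sim)
  fossils[as.integer(rownames(fs))] <- fs[, 1L]
  ntip_ext <- tabulate(b$sim[tip_extinct], nbins = b$n_sim)
  data.frame(sim = seq_len(b$n_sim), nodes = nodes, fossils = fossils,
             extinct_tips = ntip_ext)
}

#' Acceptance filter of the simulation protocol
#'
#' A simulated history is retained for the benchmark when its observable
#' tree has between 50 and 100 nodes (internal nodes plus tips) and carries
#' more than 20 fossils.
#'
#' @param obs an \code{"fbd_tree"} from \code{\link{fbd_observable}}, or a
#'   list/data frame with \code{nodes} and \code{fossils} counts.
#' @param min_nodes,max_nodes,min_fossils filter bounds; defaults 50, 100
#'   and more than 20 fossils.
#' @return Logical.
#' @export
fbd_accept <- function(obs, min_nodes = 50, max_nodes = 100,
                       min_fossils = 21) {
  if (inherits(obs, "fbd_tree")) {
    nodes <- obs$n_nodes
    fossils <- nrow(obs$fossils)
  } else {
    nodes <- obs$nodes
    fossils <- obs$fossils
  }
  nodes >= min_nodes & nodes <= max_nodes & fossils >= min_fossils
}
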