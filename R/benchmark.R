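# Simulation benchmark: coverage and width of the 95% (or other order)
# confidence upper bounds on extinction times, per method and
# fossilization rate, over accepted simulated trees.

# Restrict a simulation batch to a subset of simulation indices
batch_subset <- function(b, sims) {
  keep <- b$sim %in% sims
  ids <- b$id[keep]
  fk <- b$fossil_lineage %in% ids
  list(sim = b$sim[keep], id = ids, parent = b$parent[keep],
       birth = b$birth[keep], death = b$death[keep], fate = b$fate[keep],
       nfos = b$nfos[keep],
       fossil_lineage = b$fossil_lineage[fk],
       fossil_time = b$fossil_time[fk],
       horizon = b$horizon, n_sim = b$n_sim)
}

# Draw fossil times for a batch simulated with fossil_times = FALSE:
# given the Poisson count of a lineage, times are iid uniform on its span.
batch_fill_fossil_times <- function(b) {
  lin <- rep.int(b$id, b$nfos)
  pos <- match(lin, b$id)
  b$fossil_lineage <- lin
  b$fossil_time <- b$birth[pos] +
    stats::runif(length(lin)) * (b$death[pos] - b$birth[pos])
  b
}

#' Simulate accepted observable trees
#'
#' Runs the FBD simulator until \code{n_trees} histories pass the
#' acceptance filter (50-100 observable nodes, more than 20 fossils), and
#' returns their observable trees with stored true extinction times.
#'
#' @param rates an \code{\link{fbd_rates}} object.
#' @param n_trees number of accepted trees required.
#' @param horizon process duration in My.
#' @param chunk simulations per vectorized batch.
#' @param max_attempts simulation budget; exceeding it is an error (the
#'   acceptance probability can be as low as a few per thousand).
#' @return List with \code{$trees} (list of \code{"fbd_tree"}),
#'   \code{$attempts}, \code{$accepted}.
#' @export
fbd_simulate_accepted <- function(rates, n_trees = 100, horizon = 200,
                                  chunk = 5000L, max_attempts = 1e7) {
  trees <- vector("list", n_trees)
  got <- 0L
  attempts <- 0L
  while (got < n_trees) {
    if (attempts >= max_attempts)
      stop("simulation budget exhausted: ", attempts, " attempts for ",
           got, " accepted trees")
    b <- fbd_simulate_batch(chunk, rates, horizon, fossil_times = FALSE)
    attempts <- attempts + chunk
    st <- batch_observable_stats(b)
    ok <- st$sim[fbd_accept(st)]
    if (!length(ok)) next
    bs <- batch_fill_fossil_times(batch_subset(b, ok))
    for (s in ok) {
      tr <- fbd_observable(fbd_history_from_batch(bs, s))
      got <- got + 1L
      trees[[got]] <- tr
      if (got >= n_trees) break
    }
  }
  list(trees = trees, attempts = attempts, accepted = got)
}

# closed-form Ref quantile for one taxon: solves
# P(0, t - l) / P(0, T - l) = order by bisection on the exact CDF
ref_bound <- function(l, Tp, env, order) {
  ldenom <- fbd_logp0(Tp - l, env)
  lo <- l; hi <- Tp
  repeat {
    mid <- (lo + hi) / 2
    fm <- exp(fbd_logp0(mid - l, env) - ldenom)
    if (abs(fm - order) < 1e-10 || (hi - lo) < 1e-8) return(mid)
    if (fm < order) lo <- mid else hi <- mid
  }
}

#' Benchmark of extinction-time confidence upper bounds
#'
#' For each fossilization rate, simulates accepted observable trees and
#' computes, for every extinct observable taxon, the confidence upper
#' bound of its extinction time at each requested order with each method:
#' \describe{
#'   \item{SS}{classical range extension, \code{\link{fbd_ss_bound}};}
#'   \item{McI}{branch-local sighting rate, \code{\link{fbd_mci_bound}};}
#'   \item{Alr}{discretized Bayesian posterior, \code{\link{fbd_alroy_bound}};}
#'   \item{Glo}{tree-pooled sighting rate, \code{\link{fbd_glo_bound}};}
#'   \item{Ref}{quantile of the FBD extinction-time distribution at the
#'     true generating rates (the reference: exact nominal coverage);}
#'   \item{Int}{quantile of the distribution integrated over rates by
#'     MCMC (expensive; enable explicitly);}
#'   \item{Present}{degenerate bound at the present time (always covers).}
#' }
#' Two accuracy summaries are reported per method, order, rate and taxon
#' stratum: the error percentage (true extinction later than the bound)
#' and the mean width (bound minus most recent fossil, My).  Strata:
#' \code{branch} (taxa with >= 2 pendant fossils), \code{glo} (taxa of
#' trees where the pooled rate is estimable) and \code{all}.
#'
#' @param psi fossilization rates to benchmark.
#' @param n_trees accepted trees per rate.
#' @param orders confidence orders.
#' @param methods subset of the methods above.
#' @param lambda,mu generating speciation and extinction rates.
#' @param horizon simulated duration, My.
#' @param seed integer seed (the whole benchmark is reproducible).
#' @param mcmc_settings settings for method Int.
#' @param max_attempts per-rate simulation budget.
#' @return An object of class \code{"fbd_benchmark"}: \code{$table}
#'   (summary data frame), \code{$taxa} (per-taxon detail), \code{$stats}
#'   (per-rate acceptance and feasibility percentages).
#' @export
fbd_run_benchmark <- function(psi = c(0.1, 1), n_trees = 100,
                              orders = 0.95,
                              methods = c("SS", "McI", "Alr", "Glo", "Ref"),
                              lambda = 0.2, mu = 0.19, horizon = 200,
                              seed = NULL,
                              mcmc_settings = fbd_mcmc_settings(
                                burn_in = 200L, thinning = 2L,
                                n_samples = 250L),
                              max_attempts = 1e7) {
  if (!is.null(seed)) set.seed(seed)
  methods <- match.arg(methods,
                       c("SS", "McI", "Alr", "Glo", "Ref", "Int", "Present"),
                       several.ok = TRUE)
  taxa <- list()
  stats_rows <- list()
  for (p in psi) {
    rates <- fbd_rates(lambda, mu, p)
    env <- fbd_env(rates)
    sim <- fbd_simulate_accepted(rates, n_trees, horizon,
                                 max_attempts = max_attempts)
    for (ti in seq_along(sim$trees)) {
      tr <- sim$trees[[ti]]
      f <- fbd_sample_fossil_ages(tr$fossils)   # point ages: identity
      ext <- names(tr$tip_fate)[tr$tip_fate == "extinct"]
      if (!length(ext)) next
      recs <- lapply(ext, function(tp) fbd_branch_record(tr, f, tp))
      names(recs) <- ext
      # pooled-rate feasibility: some branch (any edge) with >= 2 fossils
      glo_ok <- any(table(tr$fossils$edge_node) >= 2)
      glo <- if ("Glo" %in% methods) {
        out <- lapply(orders, function(q) fbd_glo_bound(tr, f, q))
        names(out) <- as.character(orders)
        out
      }
      post <- if ("Int" %in% methods)
        fbd_sample_posterior(tr, mcmc_settings, init = c(
          lambda = lambda, mu = mu, psi = p))
      for (tp in ext) {
        l <- recs[[tp]]$youngest
        for (q in orders) {
          row <- data.frame(psi = p, tree = ti, taxon = tp, order = q,
                            youngest = l, truth = tr$truth[[tp]],
                            n_pendant = recs[[tp]]$n,
                            branch_feasible = recs[[tp]]$n >= 2,
                            glo_feasible = glo_ok)
          for (m in methods) {
            bd <- switch(m,
              SS = fbd_ss_bound(recs[[tp]], q),
              McI = fbd_mci_bound(recs[[tp]], q),
              Alr = fbd_alroy_bound(recs[[tp]], q),
              Glo = glo[[as.character(q)]][[tp]],
              Ref = ref_bound(l, tr$T, env, q),
              Int = fbd_integrated_bound(post, tp, q),
              Present = tr$T)
            row[[paste0("bound_", m)]] <- bd
          }
          taxa[[length(taxa) + 1L]] <- row
        }
      }
    }
    ntaxa <- sum(vapply(sim$trees, function(tr)
      sum(tr$tip_fate == "extinct"), numeric(1)))
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      psi = p,
      accept_pct = 100 * sim$accepted / sim$attempts,
      n_extinct = ntaxa)
  }
  taxa <- do.call(rbind, taxa)

  summarize <- function(df, m) {
    bd <- df[[paste0("bound_", m)]]
    ok <- !is.na(bd)
    if (!any(ok)) return(NULL)
    data.frame(method = m, n_taxa = sum(ok),
               error_pct = 100 * mean(df$truth[ok] > bd[ok]),
               mean_width = mean(bd[ok] - df$youngest[ok]))
  }
  rows <- list()
  for (p in unique(taxa$psi)) for (q in orders) {
    sub <- taxa[taxa$psi == p & taxa$order == q, ]
    strata <- list(branch = sub[sub$branch_feasible, ],
                   glo = sub[sub$glo_feasible, ],
                   all = sub)
    for (sname in names(strata)) for (m in methods) {
      s <- summarize(strata[[sname]], m)
      if (!is.null(s))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(psi = p, order = q, stratum = sname), s)
    }
  }
  stats <- do.call(rbind, stats_rows)
  bstat <- stats::aggregate(cbind(branch_feasible, glo_feasible) ~ psi,
                            taxa[taxa$order == orders[1], ],
                            function(x) 100 * mean(x))
  stats <- merge(stats, bstat, by = "psi")
  names(stats)[names(stats) == "branch_feasible"] <- "branch_feasible_pct"
  names(stats)[names(stats) == "glo_feasible"] <- "glo_feasible_pct"
  structure(list(table = do.call(rbind, rows), taxa = taxa, stats = stats),
            class = "fbd_benchmark")
}

#' @export
print.fbd_benchmark <- function(x, ...) {
  cat("FBD extinction-bound benchmark\n")
  print(x$stats, row.names = FALSE)
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
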