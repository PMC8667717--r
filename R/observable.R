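#' Observable part of a simulated FBD history
#'
#' Prunes a complete history to the part reconstructable from the fossil
#' record and the sampled extant lineages: a lineage is retained iff its
#' subtree contains at least one fossil or a sampled survivor.  Chains of
#' retained lineages with a single retained child are merged into one
#' branch (their fossils are carried over, in age order), so the result is
#' a binary tree whose nodes are speciation events with two observable
#' descendant subtrees.
#'
#' For every extinct observable tip the true extinction time of the clade
#' descending from the tip lineage is stored (the quantity whose
#' conditional distribution the FBD machinery estimates).
#'
#' @param history an \code{"fbd_history"} from \code{\link{fbd_simulate}}.
#' @param rho extant-sampling probability used to thin survivors
#'   (default 1: every survivor is sampled).
#' @return An \code{"fbd_tree"} (see Details), or \code{NULL} when nothing
#'   is observable.  Components: \code{$tree} (ape \code{phylo}; \code{NULL}
#'   when the observable part is a single lineage), \code{$T} (present time,
#'   forward axis, = horizon), \code{$tip_fate} (named, \code{"extant"} or
#'   \code{"extinct"}), \code{$fossils} (data frame \code{occ},
#'   \code{edge_node} = child-node index of the branch carrying the fossil,
#'   0 for the stem above the root, \code{t_min}, \code{t_max} forward
#'   times, equal for exactly dated finds), \code{$truth} (named forward
#'   extinction times of extinct tips), \code{$n_nodes} (tips + internal
#'   nodes of the observable tree).
#' @export
fbd_observable <- function(history, rho = 1) {
  lin <- history$lineages
  fos <- history$fossils
  n <- nrow(lin)
  horizon <- history$horizon
  nfos <- tabulate(fos$lineage, nbins = n)
  sampled <- lin$fate == "present"
  if (rho < 1) sampled <- sampled & (stats::runif(n) < rho)
  obs <- nfos > 0 | sampled
  ord <- order(lin$birth, decreasing = TRUE)   # children before parents
  for (i in ord) {
    if (obs[i] && lin$parent[i] > 0L) obs[lin$parent[i]] <- TRUE
  }
  if (!any(obs)) return(NULL)

  nobschild <- tabulate(lin$parent[obs & lin$parent > 0L], nbins = n)
  kept_tip <- which(obs & nobschild == 0L)
  kept_int <- which(obs & lin$fate == "speciation" & nobschild == 2L)

  # true extinction time of the clade descending from each lineage
  submax <- lin$death
  for (i in ord) {
    p <- lin$parent[i]
    if (p > 0L && submax[i] > submax[p]) submax[p] <- submax[i]
  }

  ntip <- length(kept_tip)
  tip_lab <- paste0("t", seq_len(ntip))
  tip_fate <- ifelse(sampled[kept_tip], "extant", "extinct")
  names(tip_fate) <- tip_lab
  truth <- submax[kept_tip]
  names(truth) <- tip_lab
  truth <- truth[tip_fate == "extinct"]

  kept <- logical(n)
  kept[kept_tip] <- TRUE
  kept[kept_int] <- TRUE

  # phylo node numbering: tips 1..ntip; internals in birth order (root first)
  kept_int <- kept_int[order(lin$birth[kept_int])]
  node_num <- integer(n)
  node_num[kept_tip] <- seq_len(ntip)
  node_num[kept_int] <- ntip + seq_along(kept_int)

  # nearest kept ancestor + fossils on the merged branch
  elems <- c(kept_tip, kept_int)
  anc <- integer(n)
  fos_edge <- integer(nrow(fos))   # phylo child-node index per fossil, 0 = stem
  fos_by_lin <- split(seq_len(nrow(fos)), factor(fos$lineage, levels = seq_len(n)))
  for (e in elems) {
    rows <- e
    cur <- lin$parent[e]
    while (cur > 0L && !kept[cur]) {
      rows <- c(rows, cur)
      cur <- lin$parent[cur]
    }
    anc[e] <- cur
    idx <- unlist(fos_by_lin[rows], use.names = FALSE)
    if (length(idx)) fos_edge[idx] <- node_num[e]
  }

  fossils <- data.frame(
    occ = paste0("f", seq_len(nrow(fos))),
    edge_node = fos_edge,
    t_min = fos$time, t_max = fos$time,
    stringsAsFactors = FALSE)
  # drop fossils on unobservable lineages (none should exist: a fossil makes
  # its lineage observable), keep the check for safety
  stopifnot(all(obs[fos$lineage]))

  if (ntip == 1L) {
    out <- list(tree = NULL, T = horizon, tip_fate = tip_fate,
                fossils = fossils, truth = truth,
                n_nodes = 1L, node_time = numeric(0))
    # single observable lineage: all fossils sit on the sole pendant branch
    out$fossils$edge_node <- 1L
    class(out) <- "fbd_tree"
    return(out)
  }

  root_row <- elems[anc[elems] == 0L]
  edge <- cbind(node_num[anc[setdiff(elems, root_row)]],
                node_num[setdiff(elems, root_row)])
  phy <- structure(list(edge = edge, Nnode = length(kept_int),
                        tip.label = tip_lab), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  node_time <- lin$death[kept_int]            # speciation times (diagnostics)
  names(node_time) <- as.character(ntip + seq_along(kept_int))

  structure(list(tree = phy, T = horizon, tip_fate = tip_fate,
                 fossils = fossils, truth = truth,
                 n_nodes = ntip + length(kept_int),
                 node_time = node_time),
            class = "fbd_tree")
}

#' @export
print.fbd_tree <- function(x, ...) {
  ntip <- if (is.null(x$tree)) 1L else length(x$tree$tip.label)
  cat("Observable FBD tree:", ntip, "tips (",
      sum(x$tip_fate == "extinct"), "extinct ),",
      nrow(x$fossils), "fossil occurrences, present T =", x$T, "My\n")
  invisible(x)
}

#' Realize fossil ages from their stratigraphic intervals
#'
#' Draws one age per occurrence, independently and uniformly within its
#' interval; point ages are returned unchanged.  All times are on the
#' internal forward axis (origin = 0).
#'
#' @param ages data frame with columns \code{occ}, \code{t_min},
#'   \code{t_max} (forward times), e.g. the \code{$fossils} table of an
#'   \code{"fbd_tree"} or the \code{$ages} table of a forest.
#' @param seed optional integer seed.
#' @return Named numeric vector of realized forward ages.
#' @export
fbd_sample_fossil_ages <- function(ages, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("occ", "t_min", "t_max") %in% names(ages)))
  f <- ages$t_min + stats::runif(nrow(ages)) * (ages$t_max - ages$t_min)
  names(f) <- ages$occ
  f
}

# Most recent realized fossil age on the pendant branch of each extinct tip.
tip_last_fossil <- function(tree, f) {
  ext <- names(tree$tip_fate)[tree$tip_fate == "extinct"]
  tipnum <- match(ext, if (is.null(tree$tree)) "t1" else tree$tree$tip.label)
  vapply(seq_along(ext), function(i) {
    idx <- tree$fossils$edge_node == tipnum[i]
    if (!any(idx)) stop("extinct tip '", ext[i],
                        "' carries no fossil on its terminal branch")
    max(f[tree$fossils$occ[idx]])
  }, numeric(1), USE.NAMES = FALSE) -> l
  names(l) <- ext
  l
}
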