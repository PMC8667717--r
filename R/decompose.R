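#' Decompose an observable tree into basic trees at its fossil finds
#'
#' The probability density of a tree topology with dated fossils
#' factorizes, by the Markov property, over the "basic trees" obtained by
#' cutting the tree at every fossil find: one piece starts at the origin
#' and one at each fossil.  Each piece runs from its start point to the
#' next fossil find on every descending path, to the sampled extant tips,
#' or -- for the piece hanging below the most recent fossil of an extinct
#' tip -- to an entirely unobservable pendant history.
#'
#' @param tree an \code{"fbd_tree"}.
#' @param f named vector of realized forward fossil ages (see
#'   \code{\link{fbd_sample_fossil_ages}}).
#' @return An object of class \code{"fbd_basic_trees"}: a list of pieces,
#'   each with \code{$start} (forward time), \code{$occ} (occurrence id at
#'   the cut, \code{NA} for the origin piece) and \code{$struct}, a nested
#'   description of the piece with leaf kinds \code{"fossil"},
#'   \code{"extant"} and \code{"hidden"}.  The number of pieces equals the
#'   number of fossils plus one.
#' @export
fbd_decompose <- function(tree, f) {
  stopifnot(inherits(tree, "fbd_tree"))
  fos <- tree$fossils
  miss <- setdiff(fos$occ, names(f))
  if (length(miss)) stop("realized ages missing for occurrences: ",
                         paste(miss, collapse = ", "))
  ft <- unname(f[fos$occ])
  if (any(ft < 0 | ft > tree$T))
    stop("realized fossil ages must lie in [0, T]")

  single <- is.null(tree$tree)
  if (single) {
    ntip <- 1L
    children <- list()
    tip_lab <- names(tree$tip_fate)
  } else {
    phy <- tree$tree
    ntip <- length(phy$tip.label)
    children <- split(phy$edge[, 2L], factor(phy$edge[, 1L],
                                             levels = seq_len(ntip + phy$Nnode)))
    tip_lab <- phy$tip.label
  }

  # per-edge fossils sorted by realized age (edge keyed by child node; 0 = stem)
  ef <- split(seq_len(nrow(fos)), factor(fos$edge_node,
                                         levels = 0:(if (single) 1L else ntip + tree$tree$Nnode)))
  ef <- lapply(ef, function(idx) idx[order(ft[idx])])

  # consistency: fossil ages must not decrease from an edge to its descendants
  check_order <- function(v, low) {
    idx <- ef[[as.character(v)]]
    if (length(idx)) {
      if (ft[idx[1L]] < low)
        stop("fossil ages inconsistent with topology on branch below node ", v)
      low <- ft[idx[length(idx)]]
    }
    for (w in children[[as.character(v)]]) check_order(w, low)
    invisible(NULL)
  }

  # observable continuation below the bottom of edge v (first fossils cut off)
  descend <- function(v) {
    idx <- ef[[as.character(v)]]
    if (length(idx))
      return(list(kind = "fossil", time = ft[idx[1L]], occ = fos$occ[idx[1L]]))
    if (v <= ntip) {
      if (tree$tip_fate[[tip_lab[v]]] == "extant")
        return(list(kind = "extant", tip = tip_lab[v]))
      stop("extinct tip '", tip_lab[v],
           "' has no fossil on its terminal branch")
    }
    ch <- children[[as.character(v)]]
    list(kind = "node", children = list(descend(ch[1L]), descend(ch[2L])))
  }

  # piece starting on edge v below its i-th fossil (i = 0: from edge top)
  piece_from <- function(v, i, start, occ) {
    idx <- ef[[as.character(v)]]
    struct <- if (i < length(idx)) {
      list(kind = "fossil", time = ft[idx[i + 1L]], occ = fos$occ[idx[i + 1L]])
    } else if (v == 0L) {
      rt <- if (single) 1L else ntip + 1L
      if (rt <= ntip) descend_tip_bottom(rt) else
        list(kind = "node",
             children = lapply(children[[as.character(rt)]], descend))
    } else if (v <= ntip) {
      descend_tip_bottom(v)
    } else {
      list(kind = "node",
           children = lapply(children[[as.character(v)]], descend))
    }
    list(start = start, occ = occ, struct = struct)
  }
  descend_tip_bottom <- function(v) {
    if (tree$tip_fate[[tip_lab[v]]] == "extant")
      list(kind = "extant", tip = tip_lab[v])
    else
      list(kind = "hidden", tip = tip_lab[v])
  }

  if (single) {
    # all fossils on the sole pendant branch; the stem is that branch
    root_edge <- 1L
  } else root_edge <- 0L
  check_start <- if (single) 1L else 0L
  if (!single) check_order(ntip + 1L,
                           if (length(ef[["0"]])) ft[ef[["0"]][length(ef[["0"]])]] else 0)
  if (single && length(ef[["1"]]) == 0L && tree$tip_fate[[1L]] == "extinct")
    stop("extinct tip '", tip_lab[1L], "' has no fossil on its terminal branch")

  pieces <- list(piece_from(root_edge, 0L, 0, NA_character_))
  all_edges <- if (single) 1L else 0:(ntip + tree$tree$Nnode)
  for (v in all_edges) {
    idx <- ef[[as.character(v)]]
    if (length(idx)) {
      if (!single && v > 0L) {
        # fossils on edge v must postdate those on the stem/ancestral edges:
        # covered by check_order above
      }
      for (i in seq_along(idx))
        pieces[[length(pieces) + 1L]] <-
          piece_from(v, i, ft[idx[i]], fos$occ[idx[i]])
    }
  }
  structure(pieces, class = "fbd_basic_trees")
}

#' @export
print.fbd_basic_trees <- function(x, ...) {
  kinds <- vapply(x, function(p) p$struct$kind, character(1))
  cat("Basic-tree decomposition:", length(x), "pieces (",
      sum(kinds == "hidden"), "pendant,",
      sum(kinds == "fossil"), "chain-to-fossil,",
      sum(kinds == "extant"), "chain-to-tip,",
      sum(kinds == "node"), "branching )\n")
  invisible(x)
}
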