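#' Read a forest of trees with interval-dated fossil occurrences
#'
#' Reads one or more Newick topologies (branch lengths are ignored: only
#' the topology is used) together with a fossil-occurrence table, and
#' returns validated \code{"fbd_tree"} objects sharing one occurrence set.
#' Ages in the files are in Ma before the present; internally everything
#' is converted to a forward axis with the origin at 0 and the present at
#' \code{T = origin_age - present_age}.
#'
#' The fossil table is delimited text (comma or tab, auto-detected) with
#' columns \code{occurrence_id}, \code{taxon_or_clade}, \code{age_min},
#' \code{age_max} (Ma; \code{age_min <= age_max}).  \code{taxon_or_clade}
#' is a tip label (the occurrence sits on that terminal branch), a
#' \code{"tipA+tipB"} pair (on the branch subtending the most recent
#' common ancestor of the two tips) or \code{"root"} (on the stem above
#' the root).  Distinct fossiliferous horizons are distinct occurrences
#' even when their age intervals coincide.
#'
#' @param newick path to a Newick file (one tree per line) or a character
#'   vector of Newick strings.
#' @param fossils path to the occurrence table, or a data frame with the
#'   columns above.
#' @param origin_age age of the process origin, Ma (must predate all
#'   occurrences).
#' @param present_age age of the "present" of the model, Ma (default 0).
#' @param extant_tips labels of extant, sampled tips (default none: a
#'   fully extinct dataset).
#' @return An object of class \code{"fbd_forest"}: \code{$trees} (list of
#'   \code{"fbd_tree"}), \code{$ages} (occurrence table, forward times),
#'   \code{$origin_age}, \code{$present_age}.
#' @export
fbd_read_forest <- function(newick, fossils, origin_age,
                            present_age = 0, extant_tips = character()) {
  txt <- if (length(newick) == 1L && file.exists(newick))
    readLines(newick) else newick
  txt <- txt[nzchar(trimws(txt))]
  trees <- lapply(txt, function(s) ape::read.tree(text = s))
  if (any(vapply(trees, is.null, logical(1))))
    stop("could not parse all Newick strings")

  tab <- if (is.character(fossils)) {
    first <- readLines(fossils, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(fossils, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  } else as.data.frame(fossils)
  need <- c("occurrence_id", "taxon_or_clade", "age_min", "age_max")
  if (!all(need %in% names(tab)))
    stop("fossil table must have columns ", paste(need, collapse = ", "))

  errs <- character()
  bad <- which(tab$age_min > tab$age_max)
  for (i in bad) errs <- c(errs, paste0("row ", i, ": age_min > age_max"))
  bad <- which(tab$age_min < present_age)
  for (i in bad)
    errs <- c(errs, paste0("row ", i, ": occurrence younger than the present"))
  bad <- which(tab$age_max > origin_age)
  for (i in bad)
    errs <- c(errs, paste0("row ", i, ": occurrence predates the origin"))
  if (anyDuplicated(tab$occurrence_id))
    errs <- c(errs, "duplicated occurrence_id values")

  tip_sets <- lapply(trees, function(p) sort(p$tip.label))
  if (length(unique(tip_sets)) != 1L)
    errs <- c(errs, "trees of the forest have different tip sets")
  tips <- trees[[1L]]$tip.label
  unknown <- setdiff(extant_tips, tips)
  if (length(unknown))
    errs <- c(errs, paste("unknown extant tips:", paste(unknown, collapse = ", ")))

  resolve <- function(phy, spec, row) {
    if (identical(spec, "root")) return(0L)
    parts <- strsplit(spec, "+", fixed = TRUE)[[1L]]
    idx <- match(parts, phy$tip.label)
    if (anyNA(idx)) {
      errs <<- c(errs, paste0("row ", row, ": unmatched taxon label '",
                              spec, "'"))
      return(NA_integer_)
    }
    if (length(idx) == 1L) return(idx)
    node <- ape::getMRCA(phy, idx)
    if (node == length(phy$tip.label) + 1L) 0L else node
  }

  Tp <- origin_age - present_age
  ages <- data.frame(occ = as.character(tab$occurrence_id),
                     t_min = origin_age - tab$age_max,
                     t_max = origin_age - tab$age_min,
                     stringsAsFactors = FALSE)

  fbd_trees <- lapply(trees, function(phy) {
    if (!ape::is.binary.phylo(phy) || !ape::is.rooted(phy))
      errs <<- c(errs, "trees must be rooted and binary (no polytomies)")
    edge_node <- vapply(seq_len(nrow(tab)), function(i)
      resolve(phy, tab$taxon_or_clade[i], i), integer(1))
    fate <- ifelse(phy$tip.label %in% extant_tips, "extant", "extinct")
    names(fate) <- phy$tip.label
    # every extinct tip needs a fossil on its terminal branch
    for (tp in phy$tip.label[fate == "extinct"]) {
      if (!any(edge_node == match(tp, phy$tip.label), na.rm = TRUE))
        errs <<- c(errs, paste0("extinct tip '", tp,
                                "' has no fossil on its terminal branch"))
    }
    structure(list(tree = phy, T = Tp, tip_fate = fate,
                   fossils = data.frame(occ = ages$occ,
                                        edge_node = edge_node,
                                        t_min = ages$t_min,
                                        t_max = ages$t_max,
                                        stringsAsFactors = FALSE),
                   truth = NULL,
                   n_nodes = length(phy$tip.label) + phy$Nnode,
                   origin_age = origin_age),
              class = "fbd_tree")
  })
  if (length(errs)) stop("invalid forest input:\n  ",
                         paste(unique(errs), collapse = "\n  "))
  structure(list(trees = fbd_trees, ages = ages,
                 origin_age = origin_age, present_age = present_age),
            class = "fbd_forest")
}

#' @export
print.fbd_forest <- function(x, ...) {
  cat("FBD forest:", length(x$trees), "tree(s),",
      nrow(x$ages), "fossil occurrences, origin", x$origin_age,
      "Ma, present", x$present_age, "Ma\n")
  invisible(x)
}

# leftmost descendant tip label of a node (deterministic clade spec)
first_tip <- function(phy, node) {
  while (node > length(phy$tip.label))
    node <- phy$edge[phy$edge[, 1L] == node, 2L][1L]
  phy$tip.label[node]
}

#' Write a forest back to Newick and a fossil table
#'
#' Inverse of \code{\link{fbd_read_forest}}: Newick text (one topology per
#' line) and a comma-separated occurrence table with ages in Ma.  A
#' written forest reads back identically (round trip).
#'
#' @param forest an \code{"fbd_forest"}.
#' @param newick_file,fossil_file output paths (either may be NULL to skip).
#' @return Invisibly, a list with the Newick lines and the fossil table.
#' @export
fbd_write_forest <- function(forest, newick_file = NULL, fossil_file = NULL) {
  nwk <- vapply(forest$trees, function(tr)
    ape::write.tree(tr$tree), character(1))
  tr1 <- forest$trees[[1L]]
  phy <- tr1$tree
  spec <- vapply(tr1$fossils$edge_node, function(v) {
    if (v == 0L) return("root")
    if (v <= length(phy$tip.label)) return(phy$tip.label[v])
    ch <- phy$edge[phy$edge[, 1L] == v, 2L]
    paste(first_tip(phy, ch[1L]), first_tip(phy, ch[2L]), sep = "+")
  }, character(1))
  tab <- data.frame(occurrence_id = tr1$fossils$occ,
                    taxon_or_clade = spec,
                    age_min = forest$origin_age - tr1$fossils$t_max,
                    age_max = forest$origin_age - tr1$fossils$t_min,
                    stringsAsFactors = FALSE)
  if (!is.null(newick_file)) writeLines(nwk, newick_file)
  if (!is.null(fossil_file))
    utils::write.csv(tab, fossil_file, row.names = FALSE, quote = FALSE)
  invisible(list(newick = nwk, fossils = tab))
}

#' Read taxon-subset definitions from JSON
#'
#' A JSON object mapping subset names (e.g. clade names) to arrays of tip
#' labels.
#'
#' @param path JSON file path (or JSON text).
#' @param forest optionally, an \code{"fbd_forest"} to validate against:
#'   every member must be a tip, and extinct.
#' @return Named list of character vectors.
#' @export
fbd_read_subsets <- function(path, forest = NULL) {
  subs <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  subs <- lapply(subs, as.character)
  if (any(!nzchar(names(subs))) || is.null(names(subs)))
    stop("subsets must be a named JSON object")
  if (any(vapply(subs, length, integer(1)) == 0L))
    stop("subsets must be nonempty")
  if (!is.null(forest)) {
    fate <- forest$trees[[1L]]$tip_fate
    for (nm in names(subs)) {
      miss <- setdiff(subs[[nm]], names(fate))
      if (length(miss)) stop("subset '", nm, "': unknown tips ",
                             paste(miss, collapse = ", "))
      notext <- subs[[nm]][fate[subs[[nm]]] != "extinct"]
      if (length(notext)) stop("subset '", nm, "': tips not extinct: ",
                               paste(notext, collapse = ", "))
    }
  }
  subs
}
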