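# Hand-built observable trees used across the suite (forward time axis,
# origin 0, present Tp).

# single extinct tip with fossils at forward times `a`
mk_tip_tree <- function(a, Tp) {
  structure(list(
    tree = NULL, T = Tp, tip_fate = c(t1 = "extinct"),
    fossils = data.frame(occ = paste0("f", seq_along(a)), edge_node = 1L,
                         t_min = a, t_max = a, stringsAsFactors = FALSE),
    truth = NULL, n_nodes = 1L), class = "fbd_tree")
}

# two-tip cherry; one fossil on each pendant branch, optional stem fossils
mk_cherry_tree <- function(a1, a2, Tp, stem = numeric(0),
                           fate = c("extinct", "extinct")) {
  phy <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)), Nnode = 1L,
                        tip.label = c("t1", "t2")), class = "phylo")
  k <- length(stem)
  structure(list(
    tree = phy, T = Tp,
    tip_fate = stats::setNames(fate, c("t1", "t2")),
    fossils = data.frame(
      occ = paste0("f", seq_len(2L + k)),
      edge_node = c(1L, 2L, rep(0L, k)),
      t_min = c(a1, a2, stem), t_max = c(a1, a2, stem),
      stringsAsFactors = FALSE),
    truth = NULL, n_nodes = 3L), class = "fbd_tree")
}

# balanced 4-tip tree ((t1,t2),(t3,t4)) with one pendant fossil per tip
mk_quartet_tree <- function(a, Tp) {
  stopifnot(length(a) == 4)
  phy <- structure(list(
    edge = rbind(c(5L, 6L), c(6L, 1L), c(6L, 2L), c(5L, 7L), c(7L, 3L), c(7L, 4L)),
    Nnode = 3L, tip.label = paste0("t", 1:4)), class = "phylo")
  structure(list(
    tree = phy, T = Tp,
    tip_fate = stats::setNames(rep("extinct", 4), paste0("t", 1:4)),
    fossils = data.frame(occ = paste0("f", 1:4),
                         edge_node = 1:4, t_min = a, t_max = a,
                         stringsAsFactors = FALSE),
    truth = NULL, n_nodes = 7L), class = "fbd_tree")
}

point_ages <- function(tree) fbd_sample_fossil_ages(tree$fossils)

# two-topology forest on four extinct taxa with interval ages (text files)
mk_forest_files <- function(dir) {
  nwk <- c("((tA,tB),(tC,tD));", "(((tA,tB),tC),tD);")
  writeLines(nwk, file.path(dir, "forest.nwk"))
  tab <- data.frame(
    occurrence_id = paste0("o", 1:6),
    taxon_or_clade = c("tA", "tB", "tC", "tD", "tA+tB", "tD"),
    age_min = c(280, 282, 279, 270, 291, 284),
    age_max = c(285, 286, 284, 276, 295, 288))
  utils::write.csv(tab, file.path(dir, "fossils.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines('{"AB": ["tA", "tB"], "CD": ["tC", "tD"]}',
             file.path(dir, "subsets.json"))
  list(newick = file.path(dir, "forest.nwk"),
       fossils = file.path(dir, "fossils.csv"),
       subsets = file.path(dir, "subsets.json"))
}
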