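# closed-form building blocks used as independent oracles
oracle_fns <- function(r, Tp) {
  env <- fbdext:::fbd_env(r)
  list(P0 = function(t) fbd_p(0, t, r),
       P1 = function(t) fbd_p(1, t, r),
       U = function(u, v) exp(fbdext:::fbd_logU(u, v, Tp, env)))
}

test_that("two-piece assembly matches the hand-written expression", {
  r <- fbd_rates(0.3, 0.2, 0.3)
  Tp <- 10; a <- 4
  o <- oracle_fns(r, Tp)
  tr <- mk_tip_tree(a, Tp)
  hand <- log(o$U(0, a) * r$psi) + log(o$P0(Tp - a))
  expect_equal(fbd_tree_logdensity(tr, c(f1 = a), r), hand,
               tolerance = 1e-10)
})

test_that("a lone sampled extant tip has density P(1, T)", {
  r <- fbd_rates(0.3, 0.2, 0.3, rho = 0.8)
  Tp <- 12
  tr <- structure(list(
    tree = NULL, T = Tp, tip_fate = c(t1 = "extant"),
    fossils = data.frame(occ = character(0), edge_node = integer(0),
                         t_min = numeric(0), t_max = numeric(0)),
    truth = NULL, n_nodes = 1L), class = "fbd_tree")
  expect_equal(fbd_tree_logdensity(tr, numeric(0), r),
               fbd_p(1, Tp, r, log = TRUE), tolerance = 1e-12)
})

test_that("branching-piece integration matches independent quadrature", {
  r <- fbd_rates(0.3, 0.2, 0.3)
  Tp <- 10; a1 <- 3; a2 <- 6
  o <- oracle_fns(r, Tp)
  tr <- mk_cherry_tree(a1, a2, Tp)
  num <- integrate(function(x) sapply(x, function(xx)
    o$U(0, xx) * 2 * r$lambda *
      o$U(xx, a1) * r$psi * o$P0(Tp - a1) *
      o$U(xx, a2) * r$psi * o$P0(Tp - a2)),
    0, a1, rel.tol = 1e-12)$value
  ld <- fbd_tree_logdensity(tr, c(f1 = a1, f2 = a2), r)
  expect_equal(exp(ld), num, tolerance = 1e-5)
})

test_that("nested pieces with a stem fossil and an extant tip match quadrature", {
  r <- fbd_rates(0.3, 0.2, 0.3, rho = 0.8)
  Tp <- 10; a0 <- 0.8; a1 <- 3; a1b <- 7; a2 <- 6
  o <- oracle_fns(r, Tp)
  phy <- structure(list(edge = rbind(c(4L, 1L), c(4L, 5L), c(5L, 2L), c(5L, 3L)),
                        Nnode = 2L, tip.label = c("t1", "t2", "t3")),
                   class = "phylo")
  tr <- structure(list(tree = phy, T = Tp,
    tip_fate = c(t1 = "extinct", t2 = "extinct", t3 = "extant"),
    fossils = data.frame(occ = c("f0", "f1", "f1b", "f2"),
                         edge_node = c(0L, 1L, 1L, 2L),
                         t_min = c(a0, a1, a1b, a2),
                         t_max = c(a0, a1, a1b, a2)),
    truth = NULL, n_nodes = 5L), class = "fbd_tree")
  f <- c(f0 = a0, f1 = a1, f1b = a1b, f2 = a2)
  inner <- function(y) o$U(y, a2) * r$psi * o$P1(Tp - y) * 2 * r$lambda
  g5 <- function(x) integrate(function(y)
    sapply(y, function(yy) o$U(x, yy) * inner(yy)), x, a2,
    rel.tol = 1e-10)$value
  groot <- function(x) sapply(x, function(xx)
    2 * r$lambda * o$U(xx, a1) * r$psi * g5(xx))
  piece2 <- integrate(function(x) o$U(a0, x) * groot(x), a0, a1,
                      rel.tol = 1e-9)$value
  hand <- log(o$U(0, a0) * r$psi) + log(piece2) +
    log(o$U(a1, a1b) * r$psi) + log(o$P0(Tp - a1b)) + log(o$P0(Tp - a2))
  expect_equal(fbd_tree_logdensity(tr, f, r), hand, tolerance = 1e-4)
})

test_that("the extinct-before-T constraint is the identity, with equal cost", {
  set.seed(108)
  b <- fbd_simulate_batch(30, fbd_rates(0.2, 0.15, 0.3), horizon = 60)
  checked <- 0
  for (s in 1:30) {
    tr <- fbd_observable(fbdext:::fbd_history_from_batch(b, s))
    if (is.null(tr) || !any(tr$tip_fate == "extinct") ||
        nrow(tr$fossils) == 0) next
    f <- point_ages(tr)
    S <- names(tr$tip_fate)[tr$tip_fate == "extinct"]
    r <- fbd_rates(0.2, 0.15, 0.3)
    dec <- fbd_decompose(tr, f)
    ld <- fbd_tree_logdensity(tr, f, r, decomposition = dec)
    ldT <- fbd_tree_logdensity(tr, f, r, S = S, t = tr$T,
                               decomposition = dec)
    expect_identical(ld, ldT)            # same code path, bit identical
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("constraining before the last fossil gives zero density", {
  tr <- mk_tip_tree(c(2, 7), 10)
  f <- point_ages(tr)
  r <- fbd_rates(0.2, 0.15, 0.3)
  ld <- fbd_tree_logdensity(tr, f, r, S = "t1", t = 5)
  expect_identical(as.numeric(ld), -Inf)
  expect_match(attr(ld, "why"), "precedes")
})

test_that("zero-density configurations return -Inf with a reason", {
  tr <- mk_tip_tree(4, 10)
  ld <- fbd_tree_logdensity(tr, c(f1 = 4), fbd_rates(0.2, 0.15, 0))
  expect_identical(as.numeric(ld), -Inf)
  expect_match(attr(ld, "why"), "psi")
})

test_that("constrained-to-unconstrained ratio cancels to the pendant factors", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  Tp <- 12
  tr <- mk_quartet_tree(c(3, 5, 6, 8), Tp)
  f <- point_ages(tr)
  ld <- fbd_tree_logdensity(tr, f, r)
  for (tq in c(6.5, 9, 11)) {
    lds <- fbd_tree_logdensity(tr, f, r, S = c("t1", "t2"), t = tq)
    want <- (fbd_p(0, tq - 3, r, log = TRUE) - fbd_p(0, Tp - 3, r, log = TRUE)) +
            (fbd_p(0, tq - 5, r, log = TRUE) - fbd_p(0, Tp - 5, r, log = TRUE))
    expect_equal(lds - ld, want, tolerance = 1e-8)
  }
})

test_that("density factorization is invariant to piece evaluation order", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  dec <- fbd_decompose(tr, f)
  ld1 <- fbd_tree_logdensity(tr, f, r, decomposition = dec)
  dec_rev <- structure(rev(unclass(dec)), class = "fbd_basic_trees")
  ld2 <- fbd_tree_logdensity(tr, f, r, decomposition = dec_rev)
  expect_equal(ld1, ld2, tolerance = 1e-12)
})

test_that("grafting a fossil-free extant outgroup changes the likelihood, not the ratio", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  Tp <- 12
  tr <- mk_cherry_tree(3, 6, Tp)
  f <- c(f1 = 3, f2 = 6)
  # same cherry nested under a root with an extant outgroup
  phy <- structure(list(
    edge = rbind(c(4L, 5L), c(5L, 1L), c(5L, 2L), c(4L, 3L)),
    Nnode = 2L, tip.label = c("t1", "t2", "out")), class = "phylo")
  tr2 <- structure(list(tree = phy, T = Tp,
    tip_fate = c(t1 = "extinct", t2 = "extinct", out = "extant"),
    fossils = tr$fossils, truth = NULL, n_nodes = 5L), class = "fbd_tree")
  for (tq in c(7, 10)) {
    r1 <- fbd_tree_logdensity(tr, f, r, S = "t2", t = tq) -
      fbd_tree_logdensity(tr, f, r)
    r2 <- fbd_tree_logdensity(tr2, f, r, S = "t2", t = tq) -
      fbd_tree_logdensity(tr2, f, r)
    expect_equal(r1, r2, tolerance = 1e-9)
    expect_equal(r1, fbd_p(0, tq - 6, r, log = TRUE) -
                   fbd_p(0, Tp - 6, r, log = TRUE), tolerance = 1e-9)
  }
})
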