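mk_rec <- function(times, Tp = 200) {
  structure(list(times = sort(times), n = length(times),
                 range = max(times) - min(times), youngest = max(times),
                 T = Tp), class = "fbd_branch_record")
}

test_that("range extension closed form and limits", {
  rec <- mk_rec(c(9, 10))                     # n = 2, R = 1
  expect_equal(fbd_ss_bound(rec, 0.95) - rec$youngest, 1 / 0.05 - 1)  # 19 My
  expect_equal(fbd_ss_bound(rec, 1e-9), rec$youngest, tolerance = 1e-6)
  expect_true(is.na(fbd_ss_bound(mk_rec(5))))
  o <- c(0.5, 0.75, 0.95, 0.99)
  expect_true(all(diff(vapply(o, function(q) fbd_ss_bound(rec, q),
                              numeric(1))) > 0))
})

test_that("branch-local sighting-rate bound: closed form and scale equivariance", {
  rec <- mk_rec(c(9, 10))
  expect_equal(fbd_mci_bound(rec, 0.95) - rec$youngest, log(20))
  # doubling the estimated rate (same n, half the range) halves the extension
  rec2 <- mk_rec(c(9.5, 10))
  expect_equal(fbd_mci_bound(rec2, 0.95) - 10,
               (fbd_mci_bound(rec, 0.95) - 10) / 2)
  expect_true(is.na(fbd_mci_bound(mk_rec(c(7, 7)), 0.95)))  # R = 0
  expect_true(is.na(fbd_mci_bound(mk_rec(7), 0.95)))
})

test_that("pooled rate reduces to the branch rate under identical gap structure", {
  # every pendant branch has 3 fossils with the same spacing
  tr <- mk_quartet_tree(c(3, 4, 5, 6), 20)
  tr$fossils <- rbind(tr$fossils,
                      data.frame(occ = c("g1", "g2", "g3", "g4",
                                         "h1", "h2", "h3", "h4"),
                                 edge_node = c(1:4, 1:4),
                                 t_min = c(3:6 + 1, 3:6 + 2),
                                 t_max = c(3:6 + 1, 3:6 + 2)))
  f <- point_ages(tr)
  glo <- fbd_glo_bound(tr, f, 0.95)
  for (tp in paste0("t", 1:4)) {
    rec <- fbd_branch_record(tr, f, tp)
    expect_equal(glo[[tp]], fbd_mci_bound(rec, 0.95))
  }
})

test_that("the global method covers single-fossil taxa and needs one rich branch", {
  tr <- mk_quartet_tree(c(3, 4, 5, 6), 20)     # one fossil per branch
  f <- point_ages(tr)
  expect_true(all(is.na(fbd_glo_bound(tr, f, 0.95))))   # no branch with > 2
  # enrich one branch to three fossils: every taxon now gets a finite bound
  tr$fossils <- rbind(tr$fossils,
                      data.frame(occ = c("g1", "g2"), edge_node = c(1L, 1L),
                                 t_min = c(4, 5), t_max = c(4, 5)))
  f <- point_ages(tr)
  glo <- fbd_glo_bound(tr, f, 0.95)
  expect_true(all(is.finite(glo)))
  rec1 <- fbd_branch_record(tr, f, "t2")       # single fossil
  expect_identical(rec1$n, 1L)
  expect_true(is.na(fbd_ss_bound(rec1, 0.95)))
  expect_true(is.na(fbd_mci_bound(rec1, 0.95)))
  expect_true(is.na(fbd_alroy_bound(rec1, 0.95)))
  expect_gt(glo[["t2"]], rec1$youngest)
})

test_that("pooled rate estimator converges to the truth as records richen", {
  # n - 1 gaps over the observed range: unbiased for rich records; the
  # finite-window bias (~ 2 / (psi * lifespan)) vanishes as fossils
  # accumulate on each branch
  set.seed(110)
  rel_err <- vapply(c(0.5, 8), function(psi) {
    nb <- 1000
    lens <- runif(nb, 2, 12)
    ns <- integer(nb); Rs <- numeric(nb)
    for (i in seq_len(nb)) {
      k <- rpois(1, psi * lens[i])
      if (k >= 2) {
        tt <- sort(runif(k, 0, lens[i]))
        ns[i] <- k; Rs[i] <- max(tt) - min(tt)
      }
    }
    use <- ns >= 2
    abs(sum(ns[use] - 1) / sum(Rs[use]) - psi) / psi
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.03)
})

test_that("discrete Bayesian bound: posterior properties and invariances", {
  rec <- mk_rec(c(10, 11.4, 12.1, 16.3), Tp = 60)
  b <- fbd_alroy_bound(rec, 0.95)
  expect_gt(b, rec$youngest)
  o <- c(0.5, 0.75, 0.95)
  bs <- vapply(o, function(q) fbd_alroy_bound(rec, q), numeric(1))
  expect_true(all(diff(bs) >= 0))
  expect_lte(fbd_alroy_bound(rec, 0.999999), rec$T)   # capped at the present
  # the extension depends on the record only through the bin-occupancy
  # pattern: a shifted record with the same occupied bins gets the same
  # extension (up to the negligible truncation at the present)
  recB <- mk_rec(c(20, 21.4, 22.1, 26.3), Tp = 60)
  expect_equal(fbd_alroy_bound(recB, 0.9) - recB$youngest,
               fbd_alroy_bound(rec, 0.9) - rec$youngest, tolerance = 1e-9)
  # symmetric two-bin data: reflection of the record about its midpoint
  # leaves the occupancy pattern, hence the extension, unchanged
  sym <- c(10, 10.3, 11.2, 11.5)
  refl <- sort(10 + 11.5 - sym)
  expect_equal(fbd_alroy_bound(mk_rec(refl, 60), 0.9) - max(refl),
               fbd_alroy_bound(mk_rec(sym, 60), 0.9) - max(sym))
  expect_true(is.na(fbd_alroy_bound(mk_rec(c(5, 5.2), Tp = 60), 0.95)))  # one horizon
})

test_that("all applicable bounds respect the observed record and the order", {
  set.seed(111)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    rec <- mk_rec(sort(runif(k, 5, 30)), Tp = 100)
    for (fn in list(fbd_ss_bound, fbd_mci_bound, fbd_alroy_bound)) {
      b1 <- fn(rec, 0.5); b2 <- fn(rec, 0.95)
      if (is.na(b1)) next
      expect_gte(b1, rec$youngest)
      expect_lte(b1, b2)
    }
  }
})
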