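test_that("the extinction CDF is a proper distribution on [max l, T]", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  d <- fbd_extinction_cdf(tr, f, r, c("t1", "t2"))
  expect_equal(d$support, c(5, 12))
  expect_equal(d$cdf(12), 1)
  expect_equal(d$cdf(4.9), 0)
  t <- seq(5, 12, length.out = 200)
  expect_true(all(diff(d$cdf(t)) >= 0))
  # density integrates back to the CDF increments
  for (iv in list(c(5.5, 7), c(7, 11))) {
    m <- integrate(d$pdf, iv[1], iv[2], rel.tol = 1e-10)$value
    expect_equal(m, d$cdf(iv[2]) - d$cdf(iv[1]), tolerance = 1e-6)
  }
  expect_error(fbd_extinction_cdf(tr, f, r, "nope"), "extinct")
})

test_that("a singleton distribution is the closed-form pendant ratio", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  Tp <- 12; l <- 6
  tr <- mk_quartet_tree(c(3, 5, l, 8), Tp)
  f <- point_ages(tr)
  d <- fbd_extinction_cdf(tr, f, r, "t3")
  for (tq in c(6.5, 8, 11))
    expect_equal(d$cdf(tq), fbd_p(0, tq - l, r) / fbd_p(0, Tp - l, r),
                 tolerance = 1e-12)
})

test_that("a two-taxon CDF is the product of the singleton CDFs", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  d12 <- fbd_extinction_cdf(tr, f, r, c("t1", "t2"))
  d1 <- fbd_extinction_cdf(tr, f, r, "t1")
  d2 <- fbd_extinction_cdf(tr, f, r, "t2")
  for (tq in c(5.5, 7, 10))
    expect_equal(d12$cdf(tq), d1$cdf(tq) * d2$cdf(tq), tolerance = 1e-12)
})

test_that("both routes to the CDF agree: pendant ratio vs full densities", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  S <- c("t2", "t4")
  d <- fbd_extinction_cdf(tr, f, r, S)
  ld <- fbd_tree_logdensity(tr, f, r)
  for (tq in c(8.5, 10, 11.5)) {
    lds <- fbd_tree_logdensity(tr, f, r, S = S, t = tq)
    expect_equal(d$cdf(tq), exp(lds - ld), tolerance = 1e-8)
  }
})

test_that("quantiles invert the CDF and are monotone in the order", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  d <- fbd_extinction_cdf(tr, f, r, c("t1", "t3"))
  q <- fbd_quantile(d, c(0.25, 0.5, 0.75, 0.95))
  expect_true(all(diff(q) > 0))
  expect_equal(d$cdf(q), c(0.25, 0.5, 0.75, 0.95), tolerance = 1e-6)
  expect_equal(quantile(d, 0.5), q[2])
  expect_error(fbd_quantile(d, 1), "order")
})

test_that("singleton quantiles match the analytic inversion", {
  # at rho = 1, P(0, x) = alpha beta (1 - e^{omega x}) / (beta - alpha e^{omega x})
  # can be inverted in closed form for the quantile of the pendant ratio
  r <- fbd_rates(0.25, 0.2, 0.4)
  Tp <- 12; l <- 6
  tr <- mk_quartet_tree(c(3, 5, l, 8), Tp)
  d <- fbd_extinction_cdf(tr, point_ages(tr), r, "t3")
  ro <- fbd_roots(r)
  for (ord in c(0.5, 0.95)) {
    cstar <- ord * fbd_p(0, Tp - l, r)
    z <- (ro$alpha * ro$beta - cstar * ro$beta) /
         (ro$alpha * ro$beta - cstar * ro$alpha)
    expect_equal(fbd_quantile(d, ord), l + log(z) / ro$omega,
                 tolerance = 1e-5)
  }
})

test_that("extinction-order probabilities are complementary and symmetric", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  pAB <- fbd_prob_extinct_before(tr, f, r, c("t1", "t2"), c("t3", "t4"))
  pBA <- fbd_prob_extinct_before(tr, f, r, c("t3", "t4"), c("t1", "t2"))
  expect_equal(pAB + pBA, 1, tolerance = 1e-8)
  # mirrored fossil configurations are exchangeable
  trm <- mk_quartet_tree(c(3, 6, 3, 6), 12)
  fm <- point_ages(trm)
  p <- fbd_prob_extinct_before(trm, fm, r, c("t1", "t2"), c("t3", "t4"))
  expect_equal(p, 0.5, tolerance = 1e-8)
  expect_error(fbd_prob_extinct_before(tr, f, r, c("t1", "t2"), c("t2")),
               "disjoint")
})

test_that("order probabilities match direct sampling from the singleton laws", {
  set.seed(109)
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  f <- point_ages(tr)
  A <- c("t1", "t4"); B <- c("t2", "t3")
  p <- fbd_prob_extinct_before(tr, f, r, A, B)
  n <- 2e5
  ro <- fbd_roots(r); Tp <- 12
  draw <- function(l) {
    # closed-form inverse of the pendant ratio CDF at rho = 1
    cstar <- runif(n) * fbd_p(0, Tp - l, r)
    z <- (ro$alpha * ro$beta - cstar * ro$beta) /
         (ro$alpha * ro$beta - cstar * ro$alpha)
    l + log(z) / ro$omega
  }
  # inverse-CDF sampling of each taxon; set time = max over members
  tA <- pmax(draw(3), draw(8))
  tB <- pmax(draw(5), draw(6))
  phat <- mean(tA < tB)
  expect_lt(abs(p - phat), 3 * sqrt(phat * (1 - phat) / n))
})

test_that("distribution export is a well-formed two-column curve", {
  r <- fbd_rates(0.25, 0.2, 0.4)
  tr <- mk_quartet_tree(c(3, 5, 6, 8), 12)
  d <- fbd_extinction_cdf(tr, point_ages(tr), r, "t2")
  path <- tempfile(fileext = ".csv")
  out <- fbd_export_distribution(d, origin_age = 300, n = 101, file = path)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(back, as.data.frame(out), tolerance = 1e-12)
  expect_true(all(diff(out$age_ma) < 0))        # ages decrease toward present
  expect_true(all(diff(out$cdf) >= 0))
})
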