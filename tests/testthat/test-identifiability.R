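# TSF / FIM / GSF machinery on analytic toys and the windkessel fixtures.

# toy sensitivity model: h(t) = f(theta) on a trivial grid
toy_model <- function(fn, theta0, N = 9) {
  times <- seq(0, 1, length.out = N)
  sensitivity_model(function(th) matrix(fn(th, times), ncol = 1,
                                        dimnames = list(NULL, "h")),
                    theta0, times, "h")
}

test_that("finite differences recover analytic gradients", {
  lin <- toy_model(function(th, t) 3 * th[["a"]] + 0 * t, c(a = 2))
  g <- finite_diff_gradients(lin)
  expect_equal(unname(g[, 1, "a"]), rep(3, 9), tolerance = 1e-8)
  quad <- toy_model(function(th, t) th[["a"]]^2 + 0 * t, c(a = 2))
  g2 <- finite_diff_gradients(quad, rel_step = 1e-4)
  expect_equal(unname(g2[1, 1, "a"]), 4, tolerance = 1e-6)
})

test_that("TSF is zero for disconnected parameters and unit invariant", {
  m <- toy_model(function(th, t) th[["a"]] * sin(2 * pi * t) + 5,
                 c(a = 1.5, dead = 7))
  t_res <- tsf(m)
  expect_equal(unname(t_res$aggregate["dead"]), 0)
  expect_equal(t_res$ranking[1], "a")
  # rescaling a parameter (and its reference) leaves S unchanged
  c_scale <- 1000
  m2 <- toy_model(function(th, t) th[["a"]] / c_scale * sin(2 * pi * t) + 5,
                  c(a = 1.5 * c_scale, dead = 7))
  expect_equal(tsf(m2)$S[, , "a"], t_res$S[, , "a"], tolerance = 1e-9)
})

test_that("FIM matches the scalar closed form and flags collinearity", {
  # constant gradient a, noise sigma, N points -> F = N a^2 / sigma^2
  N <- 11; a <- 3; sigma <- 0.5
  grad <- array(a, c(N, 1, 1), dimnames = list(NULL, "h", "p"))
  F <- fim(grad, sigma)
  expect_equal(F[1, 1], N * a^2 / sigma^2)
  expect_equal(attr(F, "rank"), 1L)
  # duplicated parameter -> rank deficient
  grad2 <- array(rep(rnorm(N), 2), c(N, 1, 2),
                 dimnames = list(NULL, "h", c("p", "p2")))
  F2 <- fim(grad2, sigma)
  expect_lt(attr(F2, "rank"), 2L)
  expect_equal(F2, t(F2))
  ev <- eigen(F2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10 * max(ev)))
})

test_that("RCR fixture: invertible FIM, terminal identity, near-monotone", {
  m <- rcr_fixture()
  g <- gsf(m)
  expect_false(g$singular)
  expect_lt(max(abs(utils::tail(g$g, 1) - 1)), 1e-6)
  expect_equal(unname(g$g[1, ] >= -1e-6), rep(TRUE, 3))
  # near-monotone: dips no larger than a few percent of the biggest step
  rel_dip <- apply(g$increments, 2, function(x) min(x) / max(abs(x)))
  expect_true(all(rel_dip > -0.05))
})

test_that("splitting the distal resistor creates anti-correlated GSF", {
  for (sc in c(1, 0.6, 1.4)) {          # +/-40% element sweep
    m_rcr <- rcr_fixture(R2 = 0.05 * sc, C1 = 1.0 * sc, R3 = 1.0 * sc)
    m_rcrr <- rcrr_fixture(R2 = 0.05 * sc, C1 = 1.0 * sc, R3 = 1.0 * sc)
    expect_equal(sum(m_rcrr$theta0[c("R3", "R4")]),
                 unname(m_rcr$theta0["R3"]))
    g <- suppressWarnings(gsf(m_rcrr))
    expect_lt(g$increment_correlation["R3", "R4"], -0.5)
    # unsplit circuit shows no strongly anti-correlated pair
    g0 <- gsf(m_rcr)
    off <- g0$increment_correlation[upper.tri(diag(3))]
    expect_true(all(off > -0.5))
    # inlet-flow traces agree (series-resistance equivalence)
    s1 <- cardiolpm:::simulate_windkessel(0.05 * sc, 1 * sc, 1 * sc)
    s2 <- cardiolpm:::simulate_windkessel(0.05 * sc, 1 * sc,
                                          c(0.5, 0.5) * sc, C_mid = 0.005)
    expect_lt(max(abs(s1$q_in - s2$q_in)) / diff(range(s1$q_in)), 0.01)
  }
})

test_that("driving pressure of the fixtures has a 0.8 s period", {
  t <- seq(0, 5, by = 0.01)
  expect_equal(windkessel_inlet_pressure(t + 0.8),
               windkessel_inlet_pressure(t), tolerance = 1e-12)
})

test_that("the screen retains all parameters of the healthy fixture", {
  # the unsplit windkessel has no identifiability issue: with N covering
  # the whole set and nothing flagged, selection is the identity
  rep <- select_parameters(rcr_fixture(), N = 3)
  expect_identical(sort(rep$selected), c("C1", "R2", "R3"))
  expect_equal(nrow(rep$flagged), 0L)
  expect_identical(sort(rep$candidates), c("C1", "R2", "R3"))
})

test_that("gsf falls back to a pseudo-inverse on an exactly singular FIM", {
  m <- toy_model(function(th, t)
    (th[["a"]] + th[["b"]]) * sin(2 * pi * t) + 5,
    c(a = 0.5, b = 0.5), N = 15)
  expect_warning(g <- gsf(m), "singular")
  expect_true(g$singular)
})
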