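test_that("tolerance maps alpha to the expansion factor delta", {
  expect_equal(tolerance(0)$delta, 1)
  expect_equal(tolerance(1)$delta, Inf)
  alphas <- seq(0, 0.99, by = 0.01)
  deltas <- vapply(alphas, function(a) tolerance(a)$delta, numeric(1))
  expect_true(all(diff(deltas) > 0))    # monotone nondecreasing in alpha
  expect_error(tolerance(1.5), "0, 1")
  expect_error(tolerance(-0.1), "0, 1")
})

test_that("compatibility matches the band criterion at its boundaries", {
  expect_true(compatible(1.0, 1.0, 0))
  expect_false(compatible(1.0, 1.0000001, 0))
  # delta = 1/(1 - 0.1) = 1.111...: 1.2/1.0 exceeds it, 2.0/1.9 does not
  expect_false(compatible(1.0, 1.2, 0.1))
  expect_true(compatible(2.0, 1.9, 0.1))
  expect_true(compatible(0.001, 5000, 1))
  expect_error(compatible(-1, 2, 0.1), "positive")
})

test_that("forward-compatibility is one-sided and implies compatibility", {
  expect_true(forward_compatible(1.0, 1.05, 0.1))
  expect_false(forward_compatible(1.05, 1.0, 0.1))
  expect_true(forward_compatible(2.7, 2.7, 0))
  expect_false(forward_compatible(1.0, 1.2, 0.1))

  set.seed(31)
  for (rep in 1:200) {
    a <- stats::runif(1)
    r <- stats::rlnorm(3)
    tol <- tolerance(a)
    # antisymmetric except at equality
    if (r[1] != r[2]) {
      expect_false(forward_compatible(r[1], r[2], tol) &&
                     forward_compatible(r[2], r[1], tol))
    }
    # forward => pairwise (the lemma the sweep relies on): both edges in
    # the band around the minimum are mutually compatible
    if (forward_compatible(r[1], r[2], tol) &&
        forward_compatible(r[1], r[3], tol)) {
      expect_true(compatible(r[2], r[3], tol))
      expect_true(compatible(r[1], r[2], tol))
    }
  }
})

test_that("compatibility is symmetric, reciprocal-invariant and alpha-monotone", {
  set.seed(17)
  r1 <- stats::rlnorm(300); r2 <- stats::rlnorm(300)
  alpha <- stats::runif(300)
  c12 <- mapply(function(a, b, al) compatible(a, b, al), r1, r2, alpha)
  c21 <- mapply(function(a, b, al) compatible(a, b, al), r2, r1, alpha)
  crec <- mapply(function(a, b, al) compatible(1 / a, 1 / b, al), r1, r2, alpha)
  expect_identical(c12, c21)
  expect_identical(c12, crec)
  alpha2 <- pmin(1, alpha + stats::runif(300, 0, 0.3))
  c_up <- mapply(function(a, b, al) compatible(a, b, al), r1, r2, alpha2)
  expect_true(all(c_up[c12]))           # true at alpha stays true above
})

test_that("rpd returns the A/B distance quotient and NA on zero distances", {
  va <- matrix(c(0, 2, 2, 0), 2); vb <- matrix(c(0, 1, 1, 0), 2)
  ma <- mmm_dist(va, c("a1", "a2")); mb <- mmm_dist(vb, c("b1", "b2"))
  expect_equal(rpd(ma, mb, c(1, 1), c(2, 2)), 2.0)
  mb0 <- mmm_dist(matrix(0, 2, 2), c("b1", "b2"))
  expect_true(is.na(rpd(ma, mb0, c(1, 1), c(2, 2))))
  ma0 <- mmm_dist(matrix(0, 2, 2), c("a1", "a2"))
  expect_true(is.na(rpd(ma0, mb, c(1, 1), c(2, 2))))
  expect_error(rpd(ma, mb, c(1, 1), c(1, 2)), "sharing a row")
  expect_error(rpd(ma, mb, c(1, 1), c(3, 2)), "out of range")
})

test_that("graph construction honours species, row/column and zero rules", {
  va <- matrix(c(0, .4, .4, 0), 2); vb <- matrix(c(0, .8, .8, 0), 2)
  sp <- c("s1", "s2")
  ga <- build_compatibility_graph(mmm_dist(va, c("a1", "a2"), species = sp),
                                  mmm_dist(vb, c("b1", "b2"), species = sp))
  expect_equal(nrow(ga$vertices), 2)    # species kills cross pairings
  expect_equal(ga$n_edges, 1)

  g <- build_compatibility_graph(mmm_dist(va, c("a1", "a2")),
                                 mmm_dist(vb, c("b1", "b2")))
  expect_equal(nrow(g$vertices), 4)
  expect_equal(g$n_edges, 2)            # only the two row/column-disjoint pairs
  expect_true(g$adj[1, 4] && g$adj[2, 3])
  expect_equal(g$rpd[1, 4], 0.5)

  va0 <- va; va0[1, 2] <- va0[2, 1] <- 0
  g0 <- build_compatibility_graph(mmm_dist(va0, c("a1", "a2")),
                                  mmm_dist(vb, c("b1", "b2")))
  expect_equal(g0$n_edges, 0)           # zero distance removes the edge
})

test_that("stored RPDs are finite positive and the adjacency is symmetric", {
  set.seed(23)
  for (rep in 1:20) {
    inst <- random_instance()
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    expect_identical(g$adj, t(g$adj))
    expect_false(any(diag(g$adj)))
    rs <- g$rpd[g$adj]
    expect_true(all(is.finite(rs) & rs > 0))
    expect_true(all(is.na(g$rpd[!g$adj])))
    # same row/column never adjacent
    same <- outer(g$vertices$a, g$vertices$a, "==") |
      outer(g$vertices$b, g$vertices$b, "==")
    expect_false(any(g$adj & same))
  }
})

test_that("edge count is invariant under uniform rescaling of family B", {
  set.seed(29)
  for (rep in 1:10) {
    inst <- random_instance()
    g1 <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    scaled <- mmm_dist(inst$mat_b$values * 3.7, inst$mat_b$labels,
                       species = inst$mat_b$species)
    g2 <- build_compatibility_graph(inst$mat_a, scaled)
    expect_identical(g1$adj, g2$adj)
  }
})
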